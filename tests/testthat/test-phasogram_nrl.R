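test_that("phasogram counts ordered same-chromosome pairs by distance", {
  fs <- fs_from_centres(c(0, 190, 380))
  p <- compute_phasogram(fs, d_max = 500)
  expect_equal(p$counts[p$d == 190], 2)
  expect_equal(p$counts[p$d == 380], 1)
  expect_equal(p$n_pairs, 3)
  expect_equal(sum(p$counts), p$n_pairs)
  expect_equal(sum(p$norm), 1, tolerance = 1e-12)

  expect_warning(p1 <- compute_phasogram(fs_from_centres(100), 500),
                 "fewer than 2")
  expect_equal(sum(p1$counts), 0)
})

test_that("sliding-window phasogram equals the all-pairs oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(100:1500, 1)
    fs <- fs_from_centres(sort(sample.int(2e5, n, replace = TRUE)))
    p <- compute_phasogram(fs, d_max = 2000)
    expect_identical(p$counts, brute_phasogram(fs, 2000))
  }
})

test_that("pooling chromosomes never creates cross-chromosome pairs", {
  set.seed(17)
  c1 <- sort(sample.int(5e4, 300))
  c2 <- sort(sample.int(5e4, 200))
  both <- fragment_set(c(rep("a", 300), rep("b", 200)), c(c1, c2),
                       c(c1, c2) + 1)
  pa <- compute_phasogram(fs_from_centres(c1, "a"), 1000)
  pb <- compute_phasogram(fs_from_centres(c2, "b"), 1000)
  pc <- compute_phasogram(both, 1000)
  expect_equal(pc$counts, pa$counts + pb$counts)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and keeps peaks", {
  d <- 0:1500
  const <- phasogram_from_signal(rep(0.3, length(d)))
  s1 <- smooth_phasogram(const, 51, 3)
  expect_equal(s1$smoothed, s1$norm, tolerance = 1e-9)

  ramp <- phasogram_from_signal(0.001 * d)
  ramp$norm <- 0.001 * d  # prescribe an exact linear signal
  s2 <- smooth_phasogram(ramp, 51, 3)
  expect_equal(s2$smoothed, ramp$norm, tolerance = 1e-9)

  cosine <- phasogram_from_signal(0.5 + 0.4 * cos(2 * pi * d / 190))
  cosine$norm <- 0.5 + 0.4 * cos(2 * pi * d / 190)
  s3 <- smooth_phasogram(cosine, 51, 3)
  ## compare interior peaks only (the filter has boundary transients)
  interior <- function(x) {
    pk <- d[which(diff(sign(diff(x))) == -2) + 1]
    pk[pk > 100 & pk < 1400]
  }
  raw_peaks <- interior(cosine$norm)
  sm_peaks <- interior(s3$smoothed)
  expect_equal(length(raw_peaks), length(sm_peaks))
  expect_true(all(abs(raw_peaks - sm_peaks) < 2))

  expect_error(smooth_phasogram(phasogram_from_signal(rep(1, 20)), 51, 3),
               "exceeds signal length")
  expect_error(smooth_phasogram(const, 50, 3))
})

test_that("peak detection assigns nucleosome orders, tolerating gaps", {
  d <- 0:800
  gauss <- function(mu) exp(-(d - mu)^2 / (2 * 20^2))
  p <- phasogram_from_signal(gauss(190) + gauss(380) + gauss(570))
  pk <- detect_peaks(p, d_min_fit = 120)
  expect_equal(pk$k, c(1, 2, 3))
  expect_equal(pk$position, c(190, 380, 570), tolerance = 0.5)

  expect_error(detect_peaks(phasogram_from_signal(rep(1, 800))),
               "insufficient peaks")

  d <- 0:1000
  gauss <- function(mu) exp(-(d - mu)^2 / (2 * 20^2))
  p2 <- phasogram_from_signal(gauss(185) + gauss(370) + gauss(740))
  pk2 <- detect_peaks(p2, d_min_fit = 120)
  expect_equal(pk2$k, c(1, 2, 4))  # third harmonic missing
})

test_that("NRL is the OLS slope of peak position on order", {
  mk_peaks <- function(k, pos)
    structure(data.frame(k = k, position = pos,
                         prominence = rep(1, length(k))),
              class = c("peak_set", "data.frame"))
  est <- estimate_nrl(mk_peaks(1:4, c(190, 380, 570, 760)))
  expect_equal(est$nrl, 190, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-10)
  expect_true(est$reliable)

  ## closed-form OLS oracle
  k <- 1:4; y <- c(185, 372, 558, 744)
  slope <- sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
  est2 <- estimate_nrl(mk_peaks(k, y))
  expect_equal(est2$nrl, slope, tolerance = 1e-10)
  expect_equal(slope, 186.3, tolerance = 0.05)

  expect_error(estimate_nrl(mk_peaks(1:2, c(190, 380))), "3 peaks")
})

test_that("NRL is recovered within 1 bp on a simulated subject", {
  spec <- nrl_subject_spec(185, seed = 404)
  fs <- generate_subject(spec, 50, 1)
  est <- sample_nrl(fs)
  expect_lt(abs(est$nrl - attr(fs, "true_nrl")), 1.0)
  expect_true(est$reliable)
})

test_that("cohort NRL tables isolate per-sample failures", {
  spec <- trend_cohort_spec(3, n_subjects = 4)
  co <- generate_cohort(spec)
  broken <- fs_from_centres(c(1, 2), id = "broken")
  tab <- nrl_cohort_table(c(co$samples, list(broken)),
                          group = c("a", "a", "b", "b", "b"))
  expect_equal(nrow(tab), 5)
  expect_equal(sum(tab$flag == "failed"), 1)
  expect_equal(tab$sample_id[tab$flag == "failed"], "broken")
  gs <- attr(tab, "group_stats")
  expect_equal(sort(gs$group), c("a", "b"))
  expect_equal(gs$n[gs$group == "b"], 2)  # failed sample excluded
  ## identical samples: group mean equals the sample NRL
  tab2 <- nrl_cohort_table(list(co$samples[[1]], co$samples[[1]]),
                           group = c("g", "g"))
  expect_equal(attr(tab2, "group_stats")$mean, tab2$nrl[1])
})

test_that("NRL-age statistics match analytic and permutation references", {
  ages <- seq(20, 90, length.out = 12)
  expect_equal(nrl_age_stats(180 + 0.05 * ages, ages)$pearson_r, 1,
               tolerance = 1e-12)
  ## identical paired groups: t = 0, p = 1
  nrls <- c(188, 189, 190, 188, 189, 190)
  st <- nrl_age_stats(nrls, c(25, 25, 25, 100, 100, 100),
                      pairing = c("y", "y", "y", "o", "o", "o"))
  expect_equal(st$paired_t$statistic, 0)
  expect_equal(st$paired_t$p_value, 1)
  ## permutation p agrees with the analytic t-based p
  set.seed(202)
  ages <- runif(30, 25, 100)
  nrls <- 185 + 0.02 * ages + rnorm(30, 0, 0.5)
  st2 <- nrl_age_stats(nrls, ages)
  r_obs <- abs(st2$pearson_r)
  perm <- replicate(1000, abs(cor(nrls, sample(ages))))
  p_perm <- (1 + sum(perm >= r_obs)) / 1001
  mc_err <- 3 * sqrt(st2$p_value * (1 - st2$p_value) / 1000)
  expect_lt(abs(p_perm - st2$p_value), mc_err + 2 / 1000)
  expect_error(nrl_age_stats(rep(190, 5), 1:5), "zero variance")
})
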