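#' @keywords internal
"_PACKAGE"

## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Deterministic per-subject substream seed.  Kept below 2^31 and exact in
## double arithmetic (product < 2^53).
derive_seed <- function(seed, index) {
  ((seed %% 2147483647) * 1000003 + index * 7919 + 1) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
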