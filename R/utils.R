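#' @importFrom rlang .data abort
#' @importFrom stats pnorm rnorm runif rbinom sd nlminb lm anova coef pt qnorm
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so callers' randomness is unaffected.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a master seed and stream indices.
derive_seed <- function(master, i, j = 0L) {
  (as.double(master) * 7919 + i * 104729 + j * 131) %% 2147483587
}

`%||%` <- function(x, y) if (is.null(x)) y else x
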