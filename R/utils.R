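# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generation is a pure function of
# (arguments, seed) and never perturbs the session RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' Each pipeline stage (scheduling, noise synthesis, balancing, fold
#' assignment, ...) draws its randomness from a seed derived
#' deterministically from the single master seed and the stage name, so a
#' whole experiment is reproducible from one integer without per-stage
#' seed bookkeeping.
#'
#' @param master integer master seed.
#' @param stage character tag naming the stage (and any indices, e.g.
#'   `"noise/p3/day2"`).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (v in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + v) %% 2147483647
  }
  as.integer(h)
}

stopInvalid <- function(...) stop(sprintf(...), call. = FALSE)

# factor with the package-wide label convention
errpFactor <- function(x) factor(x, levels = c("NonErrP", "ErrP"))
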