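#' Scaled conjugate gradient minimization
#'
#' Full-batch scaled-conjugate-gradient descent (Moller 1993): conjugate
#' direction updates with a trust-region-style scalar damping `lambda`
#' in place of a line search. Second-order curvature information along
#' the search direction is approximated by a finite difference of the
#' gradient with step `sigma0 / |p|`. Non-positive curvature raises
#' `lambda`; a step is accepted only when the comparison ratio
#' `Delta > 0` (so the objective over accepted iterates is
#' non-increasing), and `lambda` is lowered again when the quadratic
#' approximation is good (`Delta >= 0.75`).
#'
#' @param fn objective: function of the parameter vector, returning a
#'   finite scalar.
#' @param gr gradient of `fn`.
#' @param w0 initial parameter vector.
#' @param maxIterations maximum accepted-or-rejected iteration count
#'   (default 200).
#' @param sigma0 finite-difference scale (default 1e-5).
#' @param lambda0 initial damping (default 1e-7).
#' @param tolerance stop when the gradient norm falls below this
#'   (default 1e-8).
#' @return list with `w` (final point), `value`, `record` (data.frame of
#'   iteration and objective at accepted steps), `termination` (one of
#'   "gradient", "max-iterations", "step-size").
#' @examples
#' res <- scgMinimize(function(w) sum((w - 3)^2),
#'                    function(w) 2 * (w - 3), c(0, 0))
#' res$w  # converges to (3, 3)
#' @export
scgMinimize <- function(fn, gr, w0, maxIterations = 200L, sigma0 = 1e-5,
                        lambda0 = 1e-7, tolerance = 1e-8) {
  w <- as.numeric(w0)
  fw <- fn(w)
  if (!is.finite(fw)) stopInvalid("objective is not finite at w0")
  r <- -gr(w)
  if (!all(is.finite(r))) stopInvalid("gradient is not finite at w0")
  p <- r
  lambda <- lambda0
  lambdaBar <- 0
  success <- TRUE
  delta <- 0
  losses <- fw
  iters <- 0L
  termination <- "max-iterations"
  for (k in seq_len(maxIterations)) {
    p2 <- sum(p * p)
    normP <- sqrt(p2)
    if (normP < .Machine$double.eps) { termination <- "step-size"; break }
    if (success) {
      sigma <- sigma0 / normP
      s <- (gr(w + sigma * p) - gr(w)) / sigma   # Hessian-vector approx
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambdaBar) * p2
    if (delta_k <= 0) {                          # make Hessian PD along p
      lambdaBar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    fNew <- fn(w + alpha * p)
    Delta <- 2 * delta_k * (fw - fNew) / mu^2    # comparison ratio
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      fw <- fNew
      rNew <- -gr(w)
      if (!all(is.finite(rNew)) || !is.finite(fw))
        stop("non-finite objective or gradient during SCG", call. = FALSE)
      lambdaBar <- 0
      success <- TRUE
      losses <- c(losses, fw)
      iters <- iters + 1L
      if (k %% length(w) == 0L) {
        p <- rNew                                # periodic restart
      } else {
        beta <- (sum(rNew * rNew) - sum(rNew * r)) / mu
        p <- rNew + beta * p
      }
      r <- rNew
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambdaBar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (!is.finite(lambda)) lambda <- .Machine$double.xmax / 1e10
    if (sqrt(sum(r * r)) < tolerance) { termination <- "gradient"; break }
  }
  list(w = w, value = fw,
       record = data.frame(iteration = seq_along(losses) - 1L,
                           loss = losses),
       termination = termination)
}
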