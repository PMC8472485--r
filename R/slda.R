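#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Analytic shrinkage of the sample covariance toward the scaled
#' identity: `Sigma(gamma) = (1 - gamma) S + gamma (tr(S)/d) I`, with
#' the optimal intensity estimated from the data (Ledoit-Wolf) and
#' clipped to [0, 1]. For d >> n the result is positive definite even
#' when `S` is singular. `X` is assumed already centered (for the pooled
#' within-class covariance, center each class by its own mean first).
#'
#' @param X centered numeric matrix, samples x features.
#' @param gamma optional manual shrinkage intensity in [0, 1]; when NULL
#'   (default) the analytic optimum is used.
#' @return list with `sigma` (d x d shrunk covariance) and `gamma`.
#' @export
estimateShrunkCovariance <- function(X, gamma = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stopInvalid("need at least 2 samples")
  S <- crossprod(X) / n
  m <- sum(diag(S)) / d
  if (is.null(gamma)) {
    d2 <- sum((S - diag(m, d))^2) / d
    if (d2 < .Machine$double.eps) {
      gamma <- 0
    } else {
      # mean squared distance of the rank-1 terms x_k x_k' from S:
      # sum_k ||x_k x_k' - S||_F^2 = sum_k ||x_k||^4 - n ||S||_F^2
      b2bar <- (sum(rowSums(X^2)^2) - n * sum(S^2)) / (n^2 * d)
      gamma <- min(b2bar, d2) / d2
    }
  }
  if (gamma < 0 || gamma > 1) stopInvalid("gamma must lie in [0, 1]")
  sigma <- (1 - gamma) * S + diag(gamma * m, d)
  list(sigma = sigma, gamma = gamma)
}

#' Train a shrinkage LDA classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance
#' regularized by [estimateShrunkCovariance()]. The projection is
#' `w = Sigma^-1 (mu_ErrP - mu_NonErrP)` with threshold
#' `b = w' (mu_ErrP + mu_NonErrP) / 2 + log(pi_NonErrP / pi_ErrP)`;
#' with the enforced class balance the priors are equal and the log term
#' vanishes.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param labels optional labels (factor with ErrP as positive class, or
#'   0/1); defaults to the FeatureMatrix labels.
#' @param gamma optional manual shrinkage intensity (NULL = analytic).
#' @param priors class priors (NonErrP, ErrP); default equal.
#' @return an [SLDAModel-class].
#' @export
trainSlda <- function(features, labels = NULL, gamma = NULL,
                      priors = c(0.5, 0.5)) {
  X <- if (is(features, "FeatureMatrix")) features@X else as.matrix(features)
  if (is.null(labels)) {
    if (!is(features, "FeatureMatrix"))
      stopInvalid("labels are required for a plain matrix input")
    labels <- features@labels
  }
  y <- if (is.factor(labels)) as.numeric(labels == "ErrP") else as.numeric(labels)
  if (length(unique(y)) < 2L)
    stopInvalid("training labels contain a single class")
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  Xc <- X
  Xc[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2L, mu0)
  Xc[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2L, mu1)
  est <- estimateShrunkCovariance(Xc, gamma = gamma)
  w <- solve(est$sigma, mu1 - mu0)
  b <- sum(w * (mu1 + mu0)) / 2 + log(priors[1L] / priors[2L])
  new("SLDAModel", means = rbind(NonErrP = mu0, ErrP = mu1),
      w = as.numeric(w), b = b, gamma = est$gamma, priors = priors)
}

#' Predict with a shrinkage LDA model
#'
#' Labels by the sign of the projected score `w'x - b`; a point exactly
#' on the boundary is assigned to NonErrP (deterministic tie-break).
#'
#' @param model an [SLDAModel-class].
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @return list with `scores` (signed discriminant values) and `labels`
#'   (factor with levels NonErrP, ErrP).
#' @export
predictSlda <- function(model, features) {
  stopifnot(is(model, "SLDAModel"))
  X <- if (is(features, "FeatureMatrix")) features@X else as.matrix(features)
  if (ncol(X) != length(model@w))
    stopInvalid("feature dimension (%d) does not match the model (%d)",
                ncol(X), length(model@w))
  s <- as.numeric(X %*% model@w) - model@b
  list(scores = s, labels = errpFactor(ifelse(s > 0, "ErrP", "NonErrP")))
}
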