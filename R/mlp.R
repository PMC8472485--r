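#' MLP architecture specification
#'
#' The 5-layer pattern network used for single-trial decoding: an input
#' layer the size of the feature vector, three hidden layers (default
#' 100-50-25) and a single sigmoid output unit. Training is full-batch
#' scaled conjugate gradient on the mean binary cross-entropy, for at
#' most `maxIterations` epochs. `validationChecks` equal to
#' `maxIterations` (the default) disables early stopping: no validation
#' split is carved from the training data.
#'
#' @param inputSize number of input features.
#' @param hiddenSizes integer vector of hidden-layer widths.
#' @param hiddenActivation `"tanh"` (default) or `"logistic"`.
#' @param maxIterations maximum SCG iterations (default 200).
#' @param validationChecks early-stopping patience; kept equal to
#'   `maxIterations` to disable early stopping.
#' @param seed integer seed for weight initialization.
#' @return named list describing the architecture.
#' @export
mlpArchitecture <- function(inputSize, hiddenSizes = c(100L, 50L, 25L),
                            hiddenActivation = c("tanh", "logistic"),
                            maxIterations = 200L,
                            validationChecks = maxIterations, seed = 1L) {
  if (any(hiddenSizes < 1L)) stopInvalid("hiddenSizes must all be >= 1")
  if (maxIterations < 1L) stopInvalid("maxIterations must be >= 1")
  list(inputSize = as.integer(inputSize),
       hiddenSizes = as.integer(hiddenSizes),
       hiddenActivation = match.arg(hiddenActivation),
       maxIterations = as.integer(maxIterations),
       validationChecks = as.integer(validationChecks),
       seed = as.integer(seed))
}

mlpLayerSizes <- function(arch) c(arch$inputSize, arch$hiddenSizes, 1L)

# Glorot-style uniform initialization, seeded
mlpInitWeights <- function(arch) {
  sizes <- mlpLayerSizes(arch)
  withSeed(arch$seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fanIn <- sizes[l]; fanOut <- sizes[l + 1L]
      lim <- sqrt(6 / (fanIn + fanOut))
      list(W = matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut),
           b = numeric(fanOut))
    })
  })
}

packWeights <- function(weights)
  unlist(lapply(weights, function(l) c(l$W, l$b)), use.names = FALSE)

unpackWeights <- function(v, arch) {
  sizes <- mlpLayerSizes(arch)
  out <- vector("list", length(sizes) - 1L)
  off <- 0L
  for (l in seq_along(out)) {
    nW <- sizes[l] * sizes[l + 1L]
    out[[l]] <- list(W = matrix(v[off + seq_len(nW)], sizes[l], sizes[l + 1L]),
                     b = v[off + nW + seq_len(sizes[l + 1L])])
    off <- off + nW + sizes[l + 1L]
  }
  out
}

hiddenAct <- function(z, kind) if (kind == "tanh") tanh(z) else 1 / (1 + exp(-z))
hiddenActGrad <- function(a, kind) if (kind == "tanh") 1 - a^2 else a * (1 - a)

# forward pass; returns list of activations per layer (last = sigmoid prob)
mlpForward <- function(weights, X, kind) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- X
  nL <- length(weights)
  for (l in seq_len(nL)) {
    z <- acts[[l]] %*% weights[[l]]$W
    z <- sweep(z, 2L, weights[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < nL) hiddenAct(z, kind) else 1 / (1 + exp(-z))
  }
  acts
}

# mean binary cross-entropy and its gradient w.r.t. the packed weights
mlpObjective <- function(v, arch, X, y) {
  weights <- unpackWeights(v, arch)
  p <- mlpForward(weights, X, arch$hiddenActivation)[[length(weights) + 1L]]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

mlpGradient <- function(v, arch, X, y) {
  weights <- unpackWeights(v, arch)
  kind <- arch$hiddenActivation
  acts <- mlpForward(weights, X, kind)
  n <- nrow(X)
  nL <- length(weights)
  grads <- vector("list", nL)
  # output layer: dL/dz = (p - y)/n for sigmoid + cross-entropy
  delta <- (acts[[nL + 1L]] - y) / n
  for (l in rev(seq_len(nL))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(weights[[l]]$W)) *
        hiddenActGrad(acts[[l]], kind)
  }
  packWeights(grads)
}

#' Train the MLP classifier
#'
#' Fits the 5-layer pattern network of [mlpArchitecture()] by full-batch
#' scaled conjugate gradient ([scgMinimize()]) on the mean binary
#' cross-entropy, with seeded Glorot-uniform initialization. Inputs are
#' used on their native microvolt scale (no rescaling).
#'
#' @param features a [FeatureMatrix-class], or a plain numeric matrix.
#' @param labels optional factor/vector of labels; defaults to the
#'   FeatureMatrix labels. `ErrP` (or 1) is the positive class.
#' @param arch architecture from [mlpArchitecture()]; defaults to the
#'   standard 100-50-25 network sized to the input.
#' @return an [MLPModel-class].
#' @export
trainMlp <- function(features, labels = NULL, arch = NULL) {
  X <- if (is(features, "FeatureMatrix")) features@X else as.matrix(features)
  if (is.null(labels)) {
    if (!is(features, "FeatureMatrix"))
      stopInvalid("labels are required for a plain matrix input")
    labels <- features@labels
  }
  y <- if (is.factor(labels)) as.numeric(labels == "ErrP") else as.numeric(labels)
  if (length(unique(y)) < 2L)
    stopInvalid("training labels contain a single class")
  if (min(table(y)) < 2L)
    stopInvalid("need at least 2 examples per class")
  if (is.null(arch)) arch <- mlpArchitecture(ncol(X))
  if (arch$inputSize != ncol(X))
    stopInvalid("feature count (%d) does not match arch$inputSize (%d)",
                ncol(X), arch$inputSize)
  w0 <- packWeights(mlpInitWeights(arch))
  res <- scgMinimize(function(v) mlpObjective(v, arch, X, y),
                     function(v) mlpGradient(v, arch, X, y),
                     w0, maxIterations = arch$maxIterations)
  new("MLPModel", architecture = arch,
      weights = unpackWeights(res$w, arch),
      record = res$record, termination = res$termination)
}

#' Predict with a trained MLP
#'
#' @param model an [MLPModel-class].
#' @param features a [FeatureMatrix-class] or numeric matrix with the
#'   same feature dimension the model was trained on.
#' @return list with `probabilities` (sigmoid outputs in (0, 1)) and
#'   `labels` (factor; `ErrP` iff probability >= 0.5).
#' @export
predictMlp <- function(model, features) {
  stopifnot(is(model, "MLPModel"))
  X <- if (is(features, "FeatureMatrix")) features@X else as.matrix(features)
  if (ncol(X) != model@architecture$inputSize)
    stopInvalid("feature dimension (%d) does not match the model (%d)",
                ncol(X), model@architecture$inputSize)
  p <- as.numeric(mlpForward(model@weights, X,
                             model@architecture$hiddenActivation)[[
                               length(model@weights) + 1L]])
  list(probabilities = p,
       labels = errpFactor(ifelse(p >= 0.5, "ErrP", "NonErrP")))
}
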