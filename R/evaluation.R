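#' Classifier/representation specification
#'
#' The three method arms of the decoding comparison: waveform features
#' (downsampled to 50 Hz) classified with the MLP (`"mlp-features"`),
#' the entire epoch classified with the MLP (`"mlp-epoch"`), and
#' waveform features classified with shrinkage LDA (`"slda-features"`).
#'
#' @param method one of "mlp-features", "mlp-epoch", "slda-features".
#' @param targetHz decimation target for the feature representations
#'   (default 50).
#' @param hiddenSizes,maxIterations MLP settings (see
#'   [mlpArchitecture()]); ignored for sLDA.
#' @param gamma manual sLDA shrinkage intensity (NULL = analytic).
#' @param seed integer seed for MLP initialization.
#' @return named list.
#' @export
classifierSpec <- function(method = c("slda-features", "mlp-features",
                                      "mlp-epoch"),
                           targetHz = 50, hiddenSizes = c(100L, 50L, 25L),
                           maxIterations = 200L, gamma = NULL, seed = 1L) {
  list(method = match.arg(method), targetHz = targetHz,
       hiddenSizes = as.integer(hiddenSizes),
       maxIterations = as.integer(maxIterations), gamma = gamma,
       seed = as.integer(seed))
}

#' Build the feature representation an evaluation method requires
#'
#' @param epochs an [EpochSet-class].
#' @param spec a [classifierSpec()].
#' @return a [FeatureMatrix-class].
#' @export
buildFeatures <- function(epochs, spec) {
  if (spec$method == "mlp-epoch") flattenEpochs(epochs)
  else downsampleFeatures(epochs, spec$targetHz)
}

fitSpec <- function(fm, spec) {
  if (spec$method == "slda-features") {
    trainSlda(fm, gamma = spec$gamma)
  } else {
    trainMlp(fm, arch = mlpArchitecture(
      ncol(fm@X), hiddenSizes = spec$hiddenSizes,
      maxIterations = spec$maxIterations, seed = spec$seed))
  }
}

predictSpec <- function(model, fm) {
  if (is(model, "SLDAModel")) predictSlda(model, fm)$labels
  else predictMlp(model, fm)$labels
}

# stratified fold assignment: per class, shuffled indices dealt
# round-robin over k folds
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

evalResult <- function(scheme, method, acc, nTest, alpha = 0.05) {
  chance <- vapply(nTest, chanceLevel, numeric(1L), nClasses = 2L,
                   alpha = alpha)
  new("EvalResult", scheme = scheme, method = method, accuracies = acc,
      nTest = nTest, chance = chance)
}

#' Within-day calibration: stratified k-fold cross-validation
#'
#' Splits one session's (balanced) epochs into `k` stratified folds;
#' for each fold the classifier is trained on the remaining folds and
#' tested on the held-out fold. Features are built per the method spec.
#'
#' @param epochs an [EpochSet-class] for one session.
#' @param spec a [classifierSpec()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return an [EvalResult-class] with one accuracy per fold.
#' @export
withinDayCV <- function(epochs, spec = classifierSpec(), k = 10L,
                        seed = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  n <- nTrials(epochs)
  if (k < 2L || n < k) stopInvalid("need k >= 2 and at least k epochs")
  fm <- buildFeatures(epochs, spec)
  fold <- stratifiedFolds(fm@labels, k, seed)
  acc <- nTest <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    model <- fitSpec(subsetFeatures(fm, tr), spec)
    pred <- predictSpec(model, subsetFeatures(fm, te))
    acc[f] <- mean(pred == fm@labels[te])
    nTest[f] <- sum(te)
  }
  names(acc) <- names(nTest) <- sprintf("fold%d", seq_len(k))
  evalResult("within-day", spec$method, acc, nTest)
}

subsetFeatures <- function(fm, idx) {
  new("FeatureMatrix", X = fm@X[idx, , drop = FALSE],
      labels = fm@labels[idx], map = fm@map,
      representation_ = fm@representation_, sourceFs = fm@sourceFs,
      fs = fm@fs)
}

#' Between-day calibration: train on one day, test on the other
#'
#' Trains once on all epochs of each day and tests on all epochs of the
#' other, reporting the two transfer directions separately. When the two
#' sessions retain different channel sets (different bad channels), the
#' channel intersection is used, with a message.
#'
#' @param epochsDay1,epochsDay2 [EpochSet-class] objects for the two
#'   sessions of one participant.
#' @param spec a [classifierSpec()].
#' @return an [EvalResult-class] with accuracies `day1->day2` and
#'   `day2->day1`.
#' @export
betweenDay <- function(epochsDay1, epochsDay2, spec = classifierSpec()) {
  stopifnot(is(epochsDay1, "EpochSet"), is(epochsDay2, "EpochSet"))
  if (nTrials(epochsDay1) == 0L || nTrials(epochsDay2) == 0L)
    stopInvalid("both sessions must contain epochs")
  common <- intersect(epochsDay1@channels, epochsDay2@channels)
  if (length(common) == 0L) stopInvalid("no common channels across days")
  if (length(common) < max(length(epochsDay1@channels),
                           length(epochsDay2@channels)))
    message(sprintf("between-day: using %d common channels", length(common)))
  e1 <- subsetEpochs(epochsDay1, channels = common)
  e2 <- subsetEpochs(epochsDay2, channels = common)
  oneWay <- function(train, test) {
    fmTr <- buildFeatures(train, spec)
    fmTe <- buildFeatures(test, spec)
    model <- fitSpec(fmTr, spec)
    mean(predictSpec(model, fmTe) == fmTe@labels)
  }
  acc <- c("day1->day2" = oneWay(e1, e2), "day2->day1" = oneWay(e2, e1))
  nTest <- c("day1->day2" = nTrials(e2), "day2->day1" = nTrials(e1))
  evalResult("between-day", spec$method, acc, nTest)
}

#' Across-participant calibration: leave-one-participant-out
#'
#' For each participant, trains on the pooled (per-participant balanced)
#' epochs of all other participants and tests on the held-out
#' participant, using the channel intersection of the cohort.
#'
#' @param epochSets list of [EpochSet-class], one per participant (same
#'   day).
#' @param spec a [classifierSpec()].
#' @return an [EvalResult-class] with one accuracy per participant.
#' @export
acrossParticipantLopo <- function(epochSets, spec = classifierSpec()) {
  if (length(epochSets) < 2L)
    stopInvalid("need at least 2 participants")
  common <- Reduce(intersect, lapply(epochSets, channelLabels))
  if (length(common) == 0L) stopInvalid("no common channels in cohort")
  sets <- lapply(epochSets, subsetEpochs, channels = common)
  fms <- lapply(sets, buildFeatures, spec = spec)
  ids <- names(epochSets)
  if (is.null(ids)) ids <- sprintf("p%d", seq_along(epochSets))
  acc <- nTest <- numeric(length(sets))
  for (i in seq_along(sets)) {
    Xtr <- do.call(rbind, lapply(fms[-i], function(f) f@X))
    ytr <- errpFactor(unlist(lapply(fms[-i],
                                    function(f) as.character(f@labels))))
    fmTr <- new("FeatureMatrix", X = Xtr, labels = ytr, map = fms[[i]]@map,
                representation_ = fms[[i]]@representation_,
                sourceFs = fms[[i]]@sourceFs, fs = fms[[i]]@fs)
    model <- fitSpec(fmTr, spec)
    acc[i] <- mean(predictSpec(model, fms[[i]]) == fms[[i]]@labels)
    nTest[i] <- nTrials(fms[[i]])
  }
  names(acc) <- names(nTest) <- ids
  evalResult("across-participant", spec$method, acc, nTest)
}

#' Binomial chance level of a classification accuracy
#'
#' The smallest accuracy `k / nTest` whose probability under random
#' guessing (`Binomial(nTest, 1/nClasses)`) of being reached or exceeded
#' is at most `alpha`. Accuracies above this threshold are better than
#' chance at significance level `alpha`.
#'
#' @param nTest number of test trials.
#' @param nClasses number of classes (default 2).
#' @param alpha significance level (default 0.05).
#' @return accuracy threshold in (0, 1]; if even a perfect score is not
#'   significant, 1.0 with a warning.
#' @examples
#' chanceLevel(20)  # 0.75
#' @export
chanceLevel <- function(nTest, nClasses = 2L, alpha = 0.05) {
  if (nTest < 1L || nClasses < 2L || alpha <= 0 || alpha >= 1)
    stopInvalid("need nTest >= 1, nClasses >= 2, alpha in (0, 1)")
  p <- 1 / nClasses
  # smallest k with P(X >= k) <= alpha
  tail <- 1 - stats::pbinom(0:nTest - 1L, nTest, p)
  k <- which(tail <= alpha)[1L]
  if (is.na(k)) {
    warning("no achievable accuracy is significant at this alpha; returning 1",
            call. = FALSE)
    return(1)
  }
  (k - 1L) / nTest
}

#' Grand-average waveform across participants
#'
#' Averages, per participant, all epochs of the requested class at one
#' channel, then returns the mean and standard error across the
#' participant averages at every sample. Participants lacking the
#' channel are skipped with a message.
#'
#' @param epochSets list of [EpochSet-class], one per participant.
#' @param channel channel label (e.g. `"FCz"`).
#' @param class `"ErrP"` or `"NonErrP"`.
#' @return list with `mean`, `se` (microvolts per sample), `time_ms`,
#'   and `nParticipants`.
#' @export
grandAverage <- function(epochSets, channel = "FCz",
                         class = c("ErrP", "NonErrP")) {
  class <- match.arg(class)
  rows <- list()
  for (i in seq_along(epochSets)) {
    e <- epochSets[[i]]
    ci <- match(channel, e@channels)
    if (is.na(ci)) {
      message(sprintf("grandAverage: participant %d lacks channel %s; skipped",
                      i, channel))
      next
    }
    sel <- which(e@labels == class)
    if (!length(sel)) next
    rows[[length(rows) + 1L]] <-
      rowMeans(matrix(e@data[ci, , sel], ncol = length(sel)))
  }
  if (!length(rows)) stopInvalid("no participant provides channel %s", channel)
  M <- do.call(rbind, rows)
  e1 <- epochSets[[1L]]
  t_ms <- e1@window[1L] + (seq_len(ncol(M)) - 1L) / e1@fs * 1000
  se <- if (nrow(M) > 1L) apply(M, 2L, stats::sd) / sqrt(nrow(M))
        else numeric(ncol(M))
  list(mean = colMeans(M), se = se, time_ms = t_ms, nParticipants = nrow(M))
}

#' Correlation between per-participant quantities
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) with a two-sided p-value from the t approximation; used for the
#' test-retest reliability of within-day accuracies across days and for
#' the association between accuracy and clinical impairment scores.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate` and `p.value`.
#' @export
correlateAccuracies <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stopInvalid("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopInvalid("correlation undefined: zero variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}
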