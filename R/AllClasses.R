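#' @import methods
#' @importFrom stats rnorm runif sd var dbinom pbinom qnorm cor.test fft
#' @importFrom utils write.csv read.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib ErrPDecode, .registration = TRUE
NULL

#' TrialSchedule: ordered sham-feedback trial plan for one session
#'
#' Holds the randomized order of attempted movements, the predetermined
#' (sham) feedback outcome of every trial, and the trial timing derived
#' from the phase structure of the task (idle, preparation, attempted
#' movement, feedback delay).
#'
#' @slot trials data.frame with columns `movement` (one of
#'   left-hand/right-hand/left-foot/right-foot), `feedback`
#'   ("correct"/"error") and `start_s` (trial onset, seconds).
#' @slot phases named numeric: durations in seconds of `idle`,
#'   `preparation`, `feedback_delay`, and `post` (time kept after
#'   feedback onset before the next trial may start).
#' @slot ratioCorrect configured fraction of correct-feedback trials.
#' @export
setClass("TrialSchedule",
  representation(trials = "data.frame", phases = "numeric",
                 ratioCorrect = "numeric"))

setValidity("TrialSchedule", function(object) {
  tr <- object@trials
  msg <- character()
  if (!all(c("movement", "feedback", "start_s") %in% names(tr)))
    msg <- c(msg, "trials must have columns movement, feedback, start_s")
  else {
    if (is.unsorted(tr$start_s, strictly = TRUE))
      msg <- c(msg, "trial start times must be strictly increasing")
    if (length(unique(table(tr$movement))) > 1L)
      msg <- c(msg, "equal trial count required per movement type")
    if (!all(tr$feedback %in% c("correct", "error")))
      msg <- c(msg, "feedback must be 'correct' or 'error'")
  }
  need <- c("idle", "preparation", "feedback_delay", "post")
  if (!all(need %in% names(object@phases)))
    msg <- c(msg, "phases must name idle, preparation, feedback_delay, post")
  if (length(msg)) msg else TRUE
})

#' Recording: continuous multi-channel EEG with event markers
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot channels character vector of 10-10 electrode labels (unique).
#' @slot fs sampling rate in Hz.
#' @slot events data.frame with columns `sample` (1-based sample index)
#'   and `code` (one of "cue", "feedback-correct", "feedback-error").
#' @slot participant participant identifier.
#' @slot day recording-day identifier (integer).
#' @export
setClass("Recording",
  representation(signal = "matrix", channels = "character", fs = "numeric",
                 events = "data.frame", participant = "character",
                 day = "integer"))

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@signal) != length(object@channels))
    msg <- c(msg, "signal rows must match channel labels")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("sample", "code") %in% names(ev)))
      msg <- c(msg, "events must have columns sample, code")
    else if (any(ev$sample < 1L | ev$sample > ncol(object@signal)))
      msg <- c(msg, "event sample indices must lie within the signal")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: feedback-locked epochs with class labels
#'
#' The central container of the preprocessing chain: a channels x samples
#' x trials tensor of feedback-locked EEG, one label per trial, and the
#' provenance needed to trace each retained epoch back to its original
#' trial in the continuous recording.
#'
#' @slot data numeric array, channels x samples x trials (microvolts).
#' @slot labels factor with levels `NonErrP`, `ErrP`, one per trial.
#' @slot window numeric length-2: epoch window in ms relative to feedback
#'   onset, half-open `[start, end)`.
#' @slot fs sampling rate in Hz.
#' @slot channels retained channel labels (bad channels removed).
#' @slot provenance data.frame with columns `participant`, `day`, `trial`
#'   (original trial index in the session).
#' @export
setClass("EpochSet",
  representation(data = "array", labels = "factor", window = "numeric",
                 fs = "numeric", channels = "character",
                 provenance = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x samples x trials)")
  else {
    if (d[1L] != length(object@channels))
      msg <- c(msg, "first dimension must match channel labels")
    if (d[3L] != length(object@labels))
      msg <- c(msg, "third dimension must match labels")
    if (nrow(object@provenance) != d[3L])
      msg <- c(msg, "provenance must have one row per trial")
    expected <- round(diff(object@window) / 1000 * object@fs)
    if (d[3L] > 0L && d[2L] != expected)
      msg <- c(msg, sprintf("window implies %d samples, data has %d",
                            expected, d[2L]))
  }
  if (!identical(levels(object@labels), c("NonErrP", "ErrP")))
    msg <- c(msg, "labels must be a factor with levels NonErrP, ErrP")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: per-trial classifier inputs with provenance map
#'
#' @slot X numeric matrix, trials x features (microvolts).
#' @slot labels factor with levels `NonErrP`, `ErrP`.
#' @slot map data.frame, one row per column of `X`, with `channel` and
#'   `time_ms` (feature latency relative to feedback onset).
#' @slot representation_ either `"downsampled"` or `"full-epoch"`.
#' @slot sourceFs sampling rate of the source epochs (Hz).
#' @slot fs effective sampling rate of the feature time axis (Hz).
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", labels = "factor", map = "data.frame",
                 representation_ = "character", sourceFs = "numeric",
                 fs = "numeric"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@X) != nrow(object@map))
    msg <- c(msg, "map must have one row per feature column")
  if (nrow(object@X) != length(object@labels))
    msg <- c(msg, "labels must match rows of X")
  if (!object@representation_ %in% c("downsampled", "full-epoch"))
    msg <- c(msg, "representation_ must be 'downsampled' or 'full-epoch'")
  if (length(msg)) msg else TRUE
})

#' MLPModel: trained multi-layer perceptron
#'
#' @slot architecture list as produced by [mlpArchitecture()].
#' @slot weights list with one element per layer, each a list `W`
#'   (in x out matrix) and `b` (length-out bias).
#' @slot record data.frame of the optimization trace (iteration, loss).
#' @slot termination character: why training stopped.
#' @export
setClass("MLPModel",
  representation(architecture = "list", weights = "list",
                 record = "data.frame", termination = "character"))

setValidity("MLPModel", function(object) {
  if (nrow(object@record) && !all(is.finite(object@record$loss)))
    return("training record contains non-finite losses")
  sizes <- c(object@architecture$inputSize, object@architecture$hiddenSizes, 1L)
  for (l in seq_along(object@weights)) {
    W <- object@weights[[l]]$W
    if (!all(dim(W) == c(sizes[l], sizes[l + 1L])))
      return(sprintf("layer %d weight dimensions inconsistent with architecture", l))
  }
  TRUE
})

#' SLDAModel: shrinkage linear discriminant classifier
#'
#' @slot means 2 x d matrix of class means (rows: NonErrP, ErrP).
#' @slot w projection vector, `solve(Sigma_shrunk, mu_ErrP - mu_NonErrP)`.
#' @slot b decision threshold on the projected score.
#' @slot gamma Ledoit-Wolf shrinkage intensity in [0, 1].
#' @slot priors class priors (NonErrP, ErrP).
#' @export
setClass("SLDAModel",
  representation(means = "matrix", w = "numeric", b = "numeric",
                 gamma = "numeric", priors = "numeric"))

setValidity("SLDAModel", function(object) {
  msg <- character()
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0, 1]")
  if (nrow(object@means) != 2L)
    msg <- c(msg, "means must have two rows (NonErrP, ErrP)")
  if (length(object@w) != ncol(object@means))
    msg <- c(msg, "w must match the feature dimension")
  if (length(msg)) msg else TRUE
})

#' EvalResult: outcome of one calibration-scheme evaluation
#'
#' @slot scheme one of "within-day", "between-day", "across-participant".
#' @slot method classifier/representation combination evaluated.
#' @slot accuracies named numeric vector, one accuracy in [0, 1] per unit
#'   (CV fold, transfer direction, or held-out participant).
#' @slot nTest named numeric: test-set size per unit.
#' @slot chance named numeric: binomial chance level per unit.
#' @export
setClass("EvalResult",
  representation(scheme = "character", method = "character",
                 accuracies = "numeric", nTest = "numeric",
                 chance = "numeric"))

setValidity("EvalResult", function(object) {
  msg <- character()
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(object@nTest) != length(object@accuracies))
    msg <- c(msg, "nTest must match accuracies")
  if (length(msg)) msg else TRUE
})
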