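#' Number of trials/epochs in an object
#' @param x a TrialSchedule, Recording, EpochSet or FeatureMatrix
#' @return integer count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Channel labels of an object
#' @param x a Recording or EpochSet
#' @return character vector of electrode labels
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Sampling rate in Hz
#' @param x a Recording, EpochSet or FeatureMatrix
#' @return numeric scalar (Hz)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Per-trial class labels
#' @param x an EpochSet or FeatureMatrix
#' @return factor with levels NonErrP, ErrP
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @export
setMethod("nTrials", "TrialSchedule", function(x) nrow(x@trials))
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[3L])
#' @export
setMethod("nTrials", "FeatureMatrix", function(x) nrow(x@X))

#' @export
setMethod("channelLabels", "Recording", function(x) x@channels)
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channels)

#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @export
setMethod("samplingRate", "FeatureMatrix", function(x) x@fs)

#' @export
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @export
setMethod("trialLabels", "FeatureMatrix", function(x) x@labels)

#' Trial table of a schedule
#' @param x a TrialSchedule
#' @return data.frame with movement, feedback and start_s per trial
#' @export
scheduleTrials <- function(x) {
  stopifnot(is(x, "TrialSchedule"))
  x@trials
}

#' Event table of a recording
#' @param x a Recording
#' @return data.frame with sample and code columns
#' @export
recordingEvents <- function(x) {
  stopifnot(is(x, "Recording"))
  x@events
}

#' Signal matrix of a recording (channels x samples, microvolts)
#' @param x a Recording
#' @return numeric matrix
#' @export
recordingSignal <- function(x) {
  stopifnot(is(x, "Recording"))
  x@signal
}

#' Epoch tensor (channels x samples x trials, microvolts)
#' @param x an EpochSet
#' @return 3-d numeric array
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

#' Epoch window in ms relative to feedback onset, half-open [start, end)
#' @param x an EpochSet
#' @return numeric length-2
#' @export
epochWindow <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@window
}

#' Provenance table mapping epochs back to original trials
#' @param x an EpochSet
#' @return data.frame with participant, day, trial columns
#' @export
epochProvenance <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@provenance
}

#' Feature matrix (trials x features)
#' @param x a FeatureMatrix
#' @return numeric matrix
#' @export
featureData <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@X
}

#' Per-column provenance of a FeatureMatrix
#' @param x a FeatureMatrix
#' @return data.frame with channel and time_ms per feature column
#' @export
featureMap <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@map
}

#' Per-unit accuracies of an evaluation result
#' @param x an EvalResult
#' @return named numeric vector of accuracies in [0, 1]
#' @export
accuracies <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@accuracies
}

#' Mean accuracy of an evaluation result
#' @param x an EvalResult
#' @return numeric scalar
#' @export
meanAccuracy <- function(x) {
  stopifnot(is(x, "EvalResult"))
  mean(x@accuracies)
}

#' Standard error of the mean accuracy across units
#' @param x an EvalResult
#' @return numeric scalar (0 for a single unit)
#' @export
seAccuracy <- function(x) {
  stopifnot(is(x, "EvalResult"))
  if (length(x@accuracies) < 2L) return(0)
  stats::sd(x@accuracies) / sqrt(length(x@accuracies))
}

#' Per-unit binomial chance levels of an evaluation result
#' @param x an EvalResult
#' @return named numeric vector
#' @export
chanceLevels <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@chance
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: participant %s, day %d\n",
              object@participant, object@day))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@fs,
              ncol(object@signal) / object@fs))
  fb <- grepl("^feedback", object@events$code)
  cat(sprintf("  %d events (%d feedback)\n", nrow(object@events), sum(fb)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[3L], d[1L], d[2L], object@fs))
  cat(sprintf("  window [%g, %g) ms; labels: %s\n",
              object@window[1L], object@window[2L],
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels, 2L)), collapse = ", ")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d trials x %d features @ %g Hz\n",
              object@representation_, nrow(object@X), ncol(object@X),
              object@fs))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: %s / %s over %d units\n", object@scheme,
              object@method, length(object@accuracies)))
  cat(sprintf("  accuracy %.3f +/- %.3f (SE); mean chance level %.3f\n",
              meanAccuracy(object), seAccuracy(object),
              mean(object@chance)))
})

setMethod("show", "MLPModel", function(object) {
  a <- object@architecture
  cat(sprintf("MLPModel: %d-%s-1 (%s hidden, sigmoid output)\n",
              a$inputSize, paste(a$hiddenSizes, collapse = "-"),
              a$hiddenActivation))
  cat(sprintf("  trained %d iterations, final loss %.6g (%s)\n",
              nrow(object@record), object@record$loss[nrow(object@record)],
              object@termination))
})

setMethod("show", "SLDAModel", function(object) {
  cat(sprintf("SLDAModel: %d features, shrinkage gamma = %.4f\n",
              length(object@w), object@gamma))
})
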