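#' Preprocessing configuration
#'
#' Bundles the thresholds of the preprocessing chain: band edges and
#' order of the zero-phase Butterworth band-pass, the bad-channel
#' criterion (mean absolute amplitude more than `badChannelSdK` standard
#' deviations above the across-channel mean), the feedback-locked epoch
#' window, the absolute-amplitude epoch-rejection threshold, and whether
#' classes are balanced.
#'
#' @param band_hz band edges in Hz.
#' @param filterOrder Butterworth band-pass order (even).
#' @param badChannelSdK SD multiplier of the bad-channel rule.
#' @param epochWindow_ms half-open `[start, end)` window in ms relative
#'   to feedback onset.
#' @param rejectAmp_uV epoch rejection threshold (strictly exceeding).
#' @param balance logical: subsample the majority class after rejection.
#' @return named list of validated settings.
#' @export
preprocessConfig <- function(band_hz = c(0.05, 10), filterOrder = 8L,
                             badChannelSdK = 3, epochWindow_ms = c(100, 500),
                             rejectAmp_uV = 150, balance = TRUE) {
  if (!(band_hz[1L] > 0 && band_hz[1L] < band_hz[2L]))
    stopInvalid("band_hz must satisfy 0 < low < high")
  if (filterOrder < 2L || filterOrder %% 2L != 0L)
    stopInvalid("filterOrder must be even and >= 2")
  if (badChannelSdK <= 0) stopInvalid("badChannelSdK must be positive")
  if (rejectAmp_uV <= 0) stopInvalid("rejectAmp_uV must be positive")
  list(band_hz = band_hz, filterOrder = as.integer(filterOrder),
       badChannelSdK = badChannelSdK, epochWindow_ms = epochWindow_ms,
       rejectAmp_uV = rejectAmp_uV, balance = isTRUE(balance))
}

#' Detect bad channels by the across-channel amplitude rule
#'
#' A channel is bad when its mean absolute amplitude over the whole
#' recording exceeds the across-channel mean of that statistic by more
#' than `k` standard deviations. (A signed mean of band-passed EEG is
#' approximately zero for every channel, so the absolute amplitude is the
#' discriminating statistic.)
#'
#' @param recording a (typically band-pass filtered) [Recording-class].
#' @param k SD multiplier (default 3).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detectBadChannels <- function(recording, k = 3) {
  stopifnot(is(recording, "Recording"))
  if (length(recording@channels) < 3L)
    stopInvalid("bad-channel detection needs at least 3 channels")
  stat <- rowMeans(abs(recording@signal))
  bound <- mean(stat) + k * stats::sd(stat)
  recording@channels[stat > bound]
}

#' Extract feedback-locked epochs
#'
#' Cuts one epoch per feedback event from the continuous recording, using
#' the half-open window `[start, end)` ms relative to feedback onset, and
#' labels it `ErrP` for error feedback and `NonErrP` for correct
#' feedback. Channels listed in `excludeChannels` (e.g. from
#' [detectBadChannels()]) are dropped from the channel axis. Events whose
#' window does not fit inside the recording are dropped with a warning.
#'
#' @param recording a [Recording-class].
#' @param window_ms epoch window in ms (default `c(100, 500)`).
#' @param excludeChannels channel labels to exclude.
#' @return an [EpochSet-class].
#' @export
extractEpochs <- function(recording, window_ms = c(100, 500),
                          excludeChannels = character()) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@fs
  keepCh <- setdiff(recording@channels, excludeChannels)
  if (length(keepCh) == 0L) stopInvalid("all channels excluded")
  ev <- recording@events
  fb <- ev[grepl("^feedback", ev$code), , drop = FALSE]
  nSampEp <- as.integer(round(diff(window_ms) / 1000 * fs))
  startOff <- as.integer(round(window_ms[1L] / 1000 * fs))
  first <- fb$sample + startOff
  ok <- first >= 1L & (first + nSampEp - 1L) <= ncol(recording@signal)
  if (any(!ok))
    warning(sprintf("%d feedback event(s) dropped: epoch window out of bounds",
                    sum(!ok)), call. = FALSE)
  fb <- fb[ok, , drop = FALSE]
  chIdx <- match(keepCh, recording@channels)
  dat <- array(0, dim = c(length(keepCh), nSampEp, nrow(fb)))
  for (i in seq_len(nrow(fb))) {
    idx <- fb$sample[i] + startOff + seq_len(nSampEp) - 1L
    dat[, , i] <- recording@signal[chIdx, idx]
  }
  labels <- errpFactor(ifelse(fb$code == "feedback-error", "ErrP", "NonErrP"))
  prov <- data.frame(participant = rep(recording@participant, nrow(fb)),
                     day = rep(recording@day, nrow(fb)),
                     trial = which(ok), stringsAsFactors = FALSE)
  new("EpochSet", data = dat, labels = labels, window = window_ms,
      fs = fs, channels = keepCh, provenance = prov)
}

# subset an EpochSet by trial indices and/or channel labels
subsetEpochs <- function(epochs, trials = NULL, channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(trials)) trials <- seq_len(nTrials(epochs))
  chIdx <- if (is.null(channels)) seq_along(epochs@channels)
           else match(channels, epochs@channels)
  if (anyNA(chIdx)) stopInvalid("unknown channel in subset")
  new("EpochSet",
      data = epochs@data[chIdx, , trials, drop = FALSE],
      labels = epochs@labels[trials],
      window = epochs@window, fs = epochs@fs,
      channels = epochs@channels[chIdx],
      provenance = epochs@provenance[trials, , drop = FALSE])
}

#' Reject high-amplitude artifact epochs
#'
#' Drops every epoch whose maximum absolute amplitude across retained
#' channels and samples strictly exceeds `threshold_uV`. Provenance of
#' the retained epochs is preserved.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold_uV rejection threshold in microvolts (default 150).
#' @return the pruned [EpochSet-class], with attribute `nRejected`.
#' @export
rejectArtifactEpochs <- function(epochs, threshold_uV = 150) {
  stopifnot(is(epochs, "EpochSet"))
  n <- nTrials(epochs)
  peak <- vapply(seq_len(n), function(i) max(abs(epochs@data[, , i])),
                 numeric(1L))
  keep <- which(!(peak > threshold_uV))
  out <- subsetEpochs(epochs, trials = keep)
  attr(out, "nRejected") <- n - length(keep)
  out
}

#' Baseline-normalize epochs by their within-epoch mean
#'
#' Subtracts, per epoch and per channel, that channel's mean over the
#' epoch from every sample, so all channel-wise epoch means are zero.
#' Idempotent.
#'
#' @param epochs an [EpochSet-class].
#' @return the normalized [EpochSet-class].
#' @export
normalizeEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  d <- epochs@data
  mu <- apply(d, c(1L, 3L), mean)              # channels x trials
  for (i in seq_len(dim(d)[3L]))
    d[, , i] <- d[, , i] - mu[, i]
  initialize(epochs, data = d)
}

#' Balance ErrP and NonErrP class counts
#'
#' All epochs of the minority class (normally ErrP, given the 70/30
#' feedback ratio) are kept; the majority class is subsampled uniformly
#' without replacement down to the minority count, and the retained
#' epochs are returned in randomized order. Drawn once per session, not
#' per cross-validation fold.
#'
#' @param epochs an [EpochSet-class] containing both classes.
#' @param seed integer seed for the subsample and ordering.
#' @return the balanced [EpochSet-class].
#' @export
balanceClasses <- function(epochs, seed = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  counts <- tabulate(epochs@labels, 2L)
  if (any(counts == 0L))
    stopInvalid("both classes must be present for balancing")
  nKeep <- min(counts)
  idxErr <- which(epochs@labels == "ErrP")
  idxNon <- which(epochs@labels == "NonErrP")
  keep <- withSeed(seed, {
    sel <- c(if (length(idxErr) > nKeep) sample(idxErr, nKeep) else idxErr,
             if (length(idxNon) > nKeep) sample(idxNon, nKeep) else idxNon)
    sample(sel)
  })
  subsetEpochs(epochs, trials = keep)
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass filter, bad-channel exclusion, feedback-locked epoching,
#' amplitude-based artifact rejection, per-epoch baseline normalization,
#' and (optionally) class balancing, in that order. Artifact rejection is
#' applied to the filtered, un-normalized signal.
#'
#' @param recording a [Recording-class].
#' @param config settings from [preprocessConfig()].
#' @param seed integer seed (used only by class balancing).
#' @return an [EpochSet-class]; attribute `exclusions` is a named list
#'   with `badChannels` (labels) and `nRejected` (epoch count).
#' @export
preprocessRecording <- function(recording, config = preprocessConfig(),
                                seed = 1L) {
  filtered <- bandpassFilter(recording, config$band_hz, config$filterOrder)
  bad <- detectBadChannels(filtered, config$badChannelSdK)
  epochs <- extractEpochs(filtered, config$epochWindow_ms,
                          excludeChannels = bad)
  epochs <- rejectArtifactEpochs(epochs, config$rejectAmp_uV)
  nRej <- attr(epochs, "nRejected")
  epochs <- normalizeEpochs(epochs)
  if (config$balance)
    epochs <- balanceClasses(epochs, seed = seed)
  attr(epochs, "exclusions") <- list(badChannels = bad, nRejected = nRej)
  epochs
}
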