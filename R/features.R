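# helper shared by both representations: flatten channel-major
flattenTensor <- function(epochs, sampleIdx, fsOut, representation) {
  d <- epochs@data[, sampleIdx, , drop = FALSE]
  nCh <- dim(d)[1L]; nS <- dim(d)[2L]; nTr <- dim(d)[3L]
  X <- matrix(0, nrow = nTr, ncol = nCh * nS)
  for (i in seq_len(nTr))
    X[i, ] <- as.numeric(t(d[, , i]))      # channel-major blocks
  t_ms <- epochs@window[1L] + (sampleIdx - 1L) / epochs@fs * 1000
  map <- data.frame(channel = rep(epochs@channels, each = nS),
                    time_ms = rep(t_ms, nCh), stringsAsFactors = FALSE)
  colnames(X) <- sprintf("%s_%gms", map$channel, map$time_ms)
  new("FeatureMatrix", X = X, labels = epochs@labels, map = map,
      representation_ = representation, sourceFs = epochs@fs, fs = fsOut)
}

#' Temporal waveform features by decimation
#'
#' Downsamples each epoch to `target_hz` by keeping every
#' `fs/target_hz`-th sample (starting at the configurable phase offset),
#' then concatenates channels in montage order into one feature row per
#' trial. No additional anti-alias filter is applied: with the standard
#' 10 Hz band-pass upper edge the signal carries no energy near the
#' 25 Hz post-decimation Nyquist, so plain sample-picking is alias-free.
#' A warning is issued if the source epochs were not low-passed below
#' `target_hz / 2`.
#'
#' @param epochs an [EpochSet-class].
#' @param target_hz target rate in Hz (default 50); `fs` must be an
#'   integer multiple.
#' @param phase decimation offset in samples, `0 <= phase < fs/target_hz`
#'   (default 0).
#' @param lowpass_hz the upper band edge the epochs were filtered to,
#'   used only for the aliasing warning (default 10).
#' @return a [FeatureMatrix-class] with `channels x samples` columns.
#' @examples
#' # 480-sample epochs at 1200 Hz -> 20 samples/channel at 50 Hz
#' @export
downsampleFeatures <- function(epochs, target_hz = 50, phase = 0L,
                               lowpass_hz = 10) {
  stopifnot(is(epochs, "EpochSet"))
  fac <- epochs@fs / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stopInvalid("sampling rate (%g Hz) must be an integer multiple of target_hz (%g Hz)",
                epochs@fs, target_hz)
  fac <- as.integer(round(fac))
  if (phase < 0L || phase >= fac)
    stopInvalid("phase must lie in [0, %d)", fac)
  if (lowpass_hz > target_hz / 2)
    warning("epochs are not band-limited below target_hz/2; decimation may alias",
            call. = FALSE)
  idx <- seq(1L + phase, dim(epochs@data)[2L], by = fac)
  flattenTensor(epochs, idx, target_hz, "downsampled")
}

#' Entire-epoch features
#'
#' Flattens each epoch's full channels x samples tensor (no resampling)
#' into one feature row per trial, channels concatenated in montage
#' order.
#'
#' @param epochs an [EpochSet-class].
#' @return a [FeatureMatrix-class].
#' @export
flattenEpochs <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  flattenTensor(epochs, seq_len(dim(epochs@data)[2L]), epochs@fs,
                "full-epoch")
}

#' Reconstruct the epoch tensor from a FeatureMatrix
#'
#' Inverts the channel-major flattening using the feature map, returning
#' the channels x samples x trials array (at the feature rate).
#'
#' @param fm a [FeatureMatrix-class].
#' @return 3-d numeric array.
#' @export
unflattenFeatures <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  ch <- unique(fm@map$channel)
  nS <- nrow(fm@map) / length(ch)
  arr <- array(0, dim = c(length(ch), nS, nrow(fm@X)))
  for (i in seq_len(nrow(fm@X)))
    arr[, , i] <- matrix(fm@X[i, ], nrow = length(ch), ncol = nS,
                         byrow = TRUE)
  dimnames(arr) <- list(ch, NULL, NULL)
  arr
}
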