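#' Design a Butterworth band-pass as second-order sections
#'
#' Direct zero-pole-gain design: analog Butterworth low-pass prototype of
#' order `order/2`, low-pass-to-band-pass transform, bilinear transform
#' with edge pre-warping, then grouping of conjugate pole pairs into
#' biquad sections (each with one zero at z = 1 and one at z = -1), and
#' unit gain at the band's geometric center. The cascaded-biquad form
#' stays numerically stable even for very narrow normalized bands such as
#' 0.05-10 Hz at 1200 Hz, where the expanded transfer-function
#' (polynomial) form of the same filter has poles pushed outside the unit
#' circle by rounding and is unusable.
#'
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order band-pass filter order (even; the default 8 means an
#'   order-4 low-pass prototype, i.e. an 8th-order band-pass).
#' @return a `sosFilter` object: list with `sos` (sections x 6 matrix of
#'   b0 b1 b2 a0 a1 a2 coefficients), `low`, `high`, `fs`, `order`.
#' @export
designButterBandpass <- function(low, high, fs, order = 8L) {
  if (order < 2L || order %% 2L != 0L)
    stopInvalid("order must be a positive even integer")
  if (!(low > 0 && low < high && high < fs / 2))
    stopInvalid("band edges must satisfy 0 < low < high < fs/2")
  n <- order / 2L                          # prototype order
  fs2 <- 2 * fs
  wa1 <- fs2 * tan(pi * low / fs)          # pre-warped analog edges
  wa2 <- fs2 * tan(pi * high / fs)
  bw <- wa2 - wa1
  w0sq <- wa1 * wa2
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # unit-circle LHP poles
  poles <- complex(0)
  for (p in proto) {
    disc <- sqrt((p * bw)^2 - 4 * w0sq + 0i)
    poles <- c(poles, (p * bw + disc) / 2, (p * bw - disc) / 2)
  }
  zp <- (fs2 + poles) / (fs2 - poles)      # bilinear transform
  # pair conjugate poles into biquads; zeros at z = +1 and z = -1 each
  used <- rep(FALSE, length(zp))
  sos <- matrix(0, nrow = n, ncol = 6L)
  s <- 0L
  for (i in seq_along(zp)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & Mod(zp - Conj(zp[i])) < 1e-8)[1L]
    if (is.na(j)) stopInvalid("failed to pair conjugate poles")
    used[j] <- TRUE
    s <- s + 1L
    sos[s, ] <- c(1, 0, -1, 1, -2 * Re(zp[i]), Re(zp[i] * Conj(zp[i])))
  }
  filt <- structure(list(sos = sos, low = low, high = high, fs = fs,
                         order = order), class = "sosFilter")
  # normalize to unit gain at the digital center frequency
  f0 <- atan(sqrt(w0sq) / fs2) * fs / pi
  g <- Mod(sosResponse(filt, f0))
  filt$sos[1L, 1:3] <- filt$sos[1L, 1:3] / g
  filt
}

#' Complex frequency response of an SOS filter (single pass)
#'
#' @param filt an `sosFilter` from [designButterBandpass()].
#' @param f frequencies in Hz.
#' @return complex vector `H(f)`; the forward-backward (zero-phase)
#'   magnitude is `Mod(H)^2`.
#' @export
sosResponse <- function(filt, f) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  H <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(filt$sos))) {
    co <- filt$sos[s, ]
    H <- H * (co[1L] + co[2L] * z + co[3L] * z^2) /
             (co[4L] + co[5L] * z + co[6L] * z^2)
  }
  H
}

#' Closed-form Butterworth band-pass magnitude (analog prototype)
#'
#' The textbook magnitude of an order-`order` Butterworth band-pass,
#' `|H| = 1 / sqrt(1 + ((w^2 - w0^2) / (w B))^order)`, evaluated at the
#' bilinear-warped frequencies so it is directly comparable with
#' [sosResponse()] of the digital design.
#'
#' @inheritParams sosResponse
#' @param low,high,fs,order design parameters as in
#'   [designButterBandpass()].
#' @return numeric vector of single-pass magnitudes.
#' @export
butterBandpassGain <- function(f, low, high, fs, order = 8L) {
  fs2 <- 2 * fs
  wa1 <- fs2 * tan(pi * low / fs)
  wa2 <- fs2 * tan(pi * high / fs)
  bw <- wa2 - wa1
  w0sq <- wa1 * wa2
  w <- fs2 * tan(pi * f / fs)
  1 / sqrt(1 + ((w^2 - w0sq) / (w * bw))^order)
}

# steady-state internal state of one DF2T biquad for unit step input,
# used to suppress start-up transients (scaled by the first sample).
sosStepState <- function(co) {
  b0 <- co[1L]; b1 <- co[2L]; b2 <- co[3L]; a1 <- co[5L]; a2 <- co[6L]
  gain <- (b0 + b1 + b2) / (1 + a1 + a2)
  # fixed point of: y = b0 + w1; w1' = b1 - a1 y + w2; w2' = b2 - a2 y
  y <- gain
  w2 <- b2 - a2 * y
  w1 <- b1 - a1 * y + w2
  c(y - b0, w2)
}

sosApply <- function(filt, x, zi = NULL) {
  if (is.null(zi)) zi <- matrix(0, 0L, 0L)
  sosfilt_cpp(filt$sos, as.numeric(x), zi)
}

# zero-phase forward-backward SOS filtering with odd reflection padding
# and step-response initial conditions (scipy filtfilt conventions)
sosFiltFilt <- function(filt, x) {
  n <- length(x)
  # pad by ~1.5 time constants of the low edge so start-up ringing of the
  # slowest pole pair decays outside the returned segment
  npad <- min(n - 1L, as.integer(ceiling(1.5 * filt$fs / filt$low)))
  if (npad >= 1L) {
    ext <- c(2 * x[1L] - x[seq(npad + 1L, 2L)], x,
             2 * x[n] - x[seq(n - 1L, n - npad)])
  } else {
    ext <- x
  }
  nSec <- nrow(filt$sos)
  zi1 <- matrix(0, nSec, 2L)
  dcg <- 1
  for (s in seq_len(nSec)) {
    co <- filt$sos[s, ]
    zi1[s, ] <- sosStepState(co) * dcg       # state for this section's input
    dcg <- dcg * (co[1L] + co[2L] + co[3L]) / (co[4L] + co[5L] + co[6L])
  }
  y <- sosApply(filt, ext, zi1 * ext[1L])
  y <- rev(sosApply(filt, rev(y), zi1 * y[length(y)]))
  if (npad > 0L) y <- y[(npad + 1L):(npad + n)] else y
  y
}

#' Zero-phase Butterworth band-pass filtering of a recording
#'
#' Applies the band-pass forward and backward (zero phase shift) to every
#' channel. The default 0.05-10 Hz, order-8 design retains the slow ERP
#' components while removing drift and higher-frequency activity. Events
#' are unchanged.
#'
#' @param recording a [Recording-class].
#' @param band numeric length-2, band edges in Hz (default `c(0.05, 10)`).
#' @param order Butterworth band-pass order (default 8). The stated order
#'   is that of the designed filter; the forward-backward application
#'   squares its magnitude response.
#' @return the filtered [Recording-class].
#' @export
bandpassFilter <- function(recording, band = c(0.05, 10), order = 8L) {
  stopifnot(is(recording, "Recording"))
  fs <- recording@fs
  if (band[2L] >= fs / 2)
    stopInvalid("upper band edge must lie below the Nyquist frequency")
  if (ncol(recording@signal) < 3L * (order + 1L))
    stopInvalid("signal too short for the filter warm-up")
  filt <- designButterBandpass(band[1L], band[2L], fs, order)
  sig <- recording@signal
  for (c_ in seq_len(nrow(sig)))
    sig[c_, ] <- sosFiltFilt(filt, sig[c_, ])
  initialize(recording, signal = sig)
}
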