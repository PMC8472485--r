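test_that("SOS design matches the closed-form Butterworth magnitude", {
  filt <- designButterBandpass(0.05, 10, 1200, 8)
  f <- c(0.5, 5, 20, 50)
  expect_equal(Mod(sosResponse(filt, f)),
               butterBandpassGain(f, 0.05, 10, 1200, 8),
               tolerance = 1e-8)
  # also at a second rate and across the band
  filt2 <- designButterBandpass(0.05, 10, 200, 8)
  f2 <- c(0.1, 0.5, 1, 5, 9, 12, 20, 50)
  expect_equal(Mod(sosResponse(filt2, f2)),
               butterBandpassGain(f2, 0.05, 10, 200, 8),
               tolerance = 1e-8)
})

test_that("DC input is suppressed below 1% of its amplitude", {
  fs <- 200
  sig <- matrix(5, nrow = 1, ncol = 40 * fs)
  rec <- new("Recording", signal = sig, channels = "Cz", fs = fs,
             events = data.frame(sample = integer(), code = character()),
             participant = "p1", day = 1L)
  out <- recordingSignal(bandpassFilter(rec))
  expect_lt(sqrt(mean(out^2)), 0.05)
})

test_that("mid-band sinusoid passes at the predicted zero-phase gain", {
  fs <- 200
  t <- seq(0, 120, by = 1 / fs)
  rec <- new("Recording", signal = matrix(sin(2 * pi * 5 * t), nrow = 1),
             channels = "Cz", fs = fs,
             events = data.frame(sample = integer(), code = character()),
             participant = "p1", day = 1L)
  y <- recordingSignal(bandpassFilter(rec))[1, ]
  mid <- (40 * fs):(80 * fs)
  # quadrature projection estimates the 5 Hz amplitude; the zero-phase
  # (forward-backward) gain is the squared single-pass magnitude
  S <- sin(2 * pi * 5 * t[mid]); C <- cos(2 * pi * 5 * t[mid])
  amp <- sqrt(sum(y[mid] * S)^2 + sum(y[mid] * C)^2) / (length(mid) / 2)
  expected <- butterBandpassGain(5, 0.05, 10, fs, 8)^2
  expect_equal(amp, expected, tolerance = 0.01)
  # zero phase: peak cross-correlation with the input at lag 0
  lags <- -3:3
  cc <- vapply(lags, function(l) sum(y[mid] * sin(2 * pi * 5 * t[mid + l])),
               numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("out-of-band 50 Hz is attenuated by more than 40 dB", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  rec <- new("Recording", signal = matrix(sin(2 * pi * 50 * t), nrow = 1),
             channels = "Cz", fs = fs,
             events = data.frame(sample = integer(), code = character()),
             participant = "p1", day = 1L)
  y <- recordingSignal(bandpassFilter(rec))[1, ]
  expect_lt(max(abs(y[(20 * fs):(40 * fs)])), 10^(-40 / 20))
})

test_that("filtering is linear", {
  fs <- 200
  set.seed(11)
  x1 <- rnorm(20 * fs); x2 <- rnorm(20 * fs)
  mk <- function(x) new("Recording", signal = matrix(x, nrow = 1),
                        channels = "Cz", fs = fs,
                        events = data.frame(sample = integer(),
                                            code = character()),
                        participant = "p1", day = 1L)
  f <- function(x) recordingSignal(bandpassFilter(mk(x)))[1, ]
  lhs <- f(2 * x1 - 3 * x2)
  rhs <- 2 * f(x1) - 3 * f(x2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("filter preconditions are enforced", {
  rec <- makeTestRecording(seed = 1, nPerMovement = 1L)
  expect_error(bandpassFilter(rec, band = c(0.05, 150)), "Nyquist")
  short <- new("Recording", signal = matrix(rnorm(10), nrow = 1),
               channels = "Cz", fs = 200,
               events = data.frame(sample = integer(), code = character()),
               participant = "p1", day = 1L)
  expect_error(bandpassFilter(short), "short")
  expect_error(designButterBandpass(10, 0.05, 200), "band edges")
  expect_error(designButterBandpass(0.05, 10, 200, order = 7), "even")
})
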