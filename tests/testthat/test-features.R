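test_that("decimation to 50 Hz gives channels x 20 features for 400 ms epochs", {
  dat <- array(rnorm(37 * 480 * 3), dim = c(37, 480, 3))
  ep <- new("EpochSet", data = dat,
            labels = ErrPDecode:::errpFactor(c("ErrP", "NonErrP", "ErrP")),
            window = c(100, 500), fs = 1200, channels = standardMontage(),
            provenance = data.frame(participant = "p", day = 1L, trial = 1:3))
  fm <- downsampleFeatures(ep, 50)
  expect_equal(ncol(featureData(fm)), 740L)        # 37 * 20
  expect_equal(nrow(featureMap(fm)), 740L)
  # offset-0 sample picking: first feature of each channel is sample 1
  expect_equal(unname(featureData(fm)[1, 1]), dat[1, 1, 1])
  expect_equal(unname(featureData(fm)[2, 21]), dat[2, 1, 2])
  expect_equal(unname(featureData(fm)[1, 2]), dat[1, 25, 1])  # stride 24
  expect_equal(featureMap(fm)$time_ms[1:2], c(100, 100 + 24 / 1200 * 1000))
})

test_that("entire-epoch flattening preserves every sample", {
  dat <- array(rnorm(37 * 480 * 2), dim = c(37, 480, 2))
  ep <- new("EpochSet", data = dat,
            labels = ErrPDecode:::errpFactor(c("ErrP", "NonErrP")),
            window = c(100, 500), fs = 1200, channels = standardMontage(),
            provenance = data.frame(participant = "p", day = 1L, trial = 1:2))
  fm <- flattenEpochs(ep)
  expect_equal(ncol(featureData(fm)), 17760L)      # 37 * 480
  # feature-map round trip reconstructs the tensor exactly
  expect_equal(unflattenFeatures(fm), dat, ignore_attr = TRUE)
})

test_that("downsampling at the source rate is the identity", {
  ep <- noiseEpochs(6, nCh = 2, nSamp = 10, fs = 50)
  fm <- downsampleFeatures(ep, 50)
  expect_equal(featureData(fm), featureData(flattenEpochs(ep)),
               ignore_attr = TRUE)
})

test_that("non-integer decimation factors are rejected", {
  ep <- noiseEpochs(4, nCh = 1, nSamp = 12, fs = 80)
  expect_error(downsampleFeatures(ep, 50), "integer multiple")
  expect_error(downsampleFeatures(noiseEpochs(4), 50, phase = 5), "phase")
})

test_that("downsample-then-flatten commutes with flatten-then-select", {
  dat <- array(rnorm(3 * 40 * 5), dim = c(3, 40, 5))
  ep <- new("EpochSet", data = dat,
            labels = ErrPDecode:::errpFactor(rep(c("ErrP", "NonErrP"),
                                                 c(2, 3))),
            window = c(100, 300), fs = 200, channels = c("Fz", "Cz", "Pz"),
            provenance = data.frame(participant = "p", day = 1L, trial = 1:5))
  down <- downsampleFeatures(ep, 50)
  full <- flattenEpochs(ep)
  keep <- which(featureMap(full)$time_ms %in% featureMap(down)$time_ms)
  expect_equal(featureData(down), featureData(full)[, keep],
               ignore_attr = TRUE)
  expect_equal(featureMap(down), featureMap(full)[keep, ],
               ignore_attr = TRUE)
})

test_that("band-limited epochs decimate without aliasing", {
  # 0.05-10 Hz filtered noise decimated to 50 Hz: spectral power above
  # the 10 Hz band edge stays at the filter's stop-band floor
  rec <- makeTestRecording(seed = 17, nPerMovement = 25L,
                           profile = quietProfile())
  ep <- extractEpochs(bandpassFilter(rec))
  fm <- downsampleFeatures(ep, 50)
  arr <- unflattenFeatures(fm)                  # channels x 20 x trials
  x <- arr[1, , ]                               # 20-sample sequences
  P <- abs(mvfft(x))^2
  f <- (seq_len(nrow(P)) - 1) * 50 / nrow(P)
  hi <- f > 10 & f <= 25
  lo <- f > 0 & f <= 10
  expect_lt(sum(P[hi, ]) / sum(P[lo, ]), 0.05)
})
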