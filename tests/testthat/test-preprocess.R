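mkRecording <- function(sig, channels, fs = 200,
                        events = data.frame(sample = integer(),
                                            code = character())) {
  new("Recording", signal = sig, channels = channels, fs = fs,
      events = events, participant = "p1", day = 1L)
}

test_that("bad-channel rule flags nothing when channels are identical", {
  sig <- matrix(rep(sin(seq_len(2000) / 10), 5), nrow = 5, byrow = TRUE)
  rec <- mkRecording(sig, paste0("ch", 1:5))
  expect_identical(detectBadChannels(rec), character(0))
})

test_that("a single 50x channel among 37 unit-RMS channels is flagged exactly", {
  set.seed(21)
  n <- 5000
  sig <- matrix(rnorm(37 * n), nrow = 37)
  sig <- sig / sqrt(rowMeans(sig^2))           # exactly unit RMS
  sig[17, ] <- sig[17, ] * 50
  rec <- mkRecording(sig, standardMontage())
  # independent oracle: compute the mean + 3 SD bound by hand
  stat <- rowMeans(abs(sig))
  expected <- standardMontage()[stat > mean(stat) + 3 * sd(stat)]
  expect_identical(detectBadChannels(rec), expected)
  expect_identical(detectBadChannels(rec), standardMontage()[17])
})

test_that("simulated inflated channels are flagged in nearly all seeds", {
  hits <- vapply(1:60, function(s) {
    rec <- makeTestRecording(seed = s, nPerMovement = 2L,
                             profile = quietProfile(),
                             montage = standardMontage(),
                             forceBadChannels = "C3")
    "C3" %in% detectBadChannels(bandpassFilter(rec))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("bad-channel detection needs at least three channels", {
  rec <- mkRecording(matrix(rnorm(400), nrow = 2), c("a", "b"))
  expect_error(detectBadChannels(rec), "3 channels")
})

test_that("epoch extraction yields the specified window geometry", {
  # 400 ms window at 1200 Hz -> 480 samples
  fs <- 1200
  ev <- data.frame(sample = c(2000L, 5000L),
                   code = c("feedback-error", "feedback-correct"))
  rec <- mkRecording(matrix(rnorm(2 * 8000), nrow = 2), c("a", "b"),
                     fs = fs, events = ev)
  ep <- extractEpochs(rec, c(100, 500))
  expect_equal(dim(epochData(ep)), c(2L, 480L, 2L))
  expect_equal(as.character(trialLabels(ep)), c("ErrP", "NonErrP"))
  # half-open window: first sample is exactly event + 120 samples
  expect_equal(epochData(ep)[1, 1, 1], recordingSignal(rec)[1, 2120])
  expect_equal(epochData(ep)[1, 480, 1], recordingSignal(rec)[1, 2599])
})

test_that("a 400-event session gives 400 epochs, 120 of them ErrP", {
  rec <- makeTestRecording(seed = 5, nPerMovement = 100L)
  ep <- extractEpochs(bandpassFilter(rec))
  expect_equal(nTrials(ep), 400L)
  expect_equal(sum(trialLabels(ep) == "ErrP"), 120L)
})

test_that("events without room for the window are dropped with a warning", {
  fs <- 200
  ev <- data.frame(sample = c(500L, 3950L),
                   code = c("feedback-correct", "feedback-correct"))
  rec <- mkRecording(matrix(rnorm(4000), nrow = 1), "Cz", fs = fs,
                     events = ev)
  expect_warning(ep <- extractEpochs(rec, c(100, 500)), "dropped")
  expect_equal(nTrials(ep), 1L)
  expect_equal(epochProvenance(ep)$trial, 1L)
})

test_that("rejection uses a strict 150 uV transition", {
  dat <- array(0, dim = c(1, 4, 3))
  dat[1, 2, ] <- c(149, 150, 151)
  ep <- new("EpochSet", data = dat,
            labels = ErrPDecode:::errpFactor(c("ErrP", "NonErrP", "ErrP")),
            window = c(100, 500), fs = 10, channels = "Cz",
            provenance = data.frame(participant = "p", day = 1L, trial = 1:3))
  out <- rejectArtifactEpochs(ep, 150)
  expect_equal(nTrials(out), 2L)
  expect_equal(attr(out, "nRejected"), 1L)
  expect_equal(epochProvenance(out)$trial, 1:2)
  # all-zero epochs are all retained
  ep0 <- noiseEpochs(10, sd = 0)
  expect_equal(nTrials(rejectArtifactEpochs(ep0)), 10L)
})

test_that("artifact-epoch rejections track the configured rate", {
  # pooled over three simulated sessions: binomial 95% CI around 0.18
  nRej <- 0L; nTot <- 0L
  for (s in 1:3) {
    rec <- makeTestRecording(seed = 100 + s, nPerMovement = 50L,
                             profile = quietProfile())
    ep <- extractEpochs(bandpassFilter(rec))
    nRej <- nRej + attr(rejectArtifactEpochs(ep), "nRejected")
    nTot <- nTot + nTrials(ep)
  }
  ci <- qbinom(c(0.025, 0.975), nTot, 0.18)
  expect_gte(nRej, ci[1]); expect_lte(nRej, ci[2])
})

test_that("normalization zeroes channel means and is idempotent", {
  ep <- noiseEpochs(8, nCh = 4, nSamp = 25)
  # constant epochs become all zeros
  cst <- ep; cst@data[] <- 7.5
  expect_true(all(epochData(normalizeEpochs(cst)) == 0))
  out <- normalizeEpochs(ep)
  mu <- apply(epochData(out), c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-12)
  expect_equal(epochData(normalizeEpochs(out)), epochData(out))
})

test_that("class balancing keeps all minority epochs, seeded", {
  dat <- array(rnorm(400 * 2), dim = c(1, 2, 400))
  ep <- new("EpochSet", data = dat,
            labels = ErrPDecode:::errpFactor(rep(c("NonErrP", "ErrP"),
                                                 c(280, 120))),
            window = c(100, 200), fs = 20, channels = "Cz",
            provenance = data.frame(participant = "p", day = 1L,
                                    trial = 1:400))
  out <- balanceClasses(ep, seed = 3)
  expect_equal(as.integer(table(trialLabels(out))), c(120L, 120L))
  # every original ErrP survives
  expect_setequal(epochProvenance(out)$trial[trialLabels(out) == "ErrP"],
                  which(trialLabels(ep) == "ErrP"))
  expect_identical(epochProvenance(balanceClasses(ep, seed = 3)),
                   epochProvenance(out))
  expect_false(identical(epochProvenance(balanceClasses(ep, seed = 4)),
                         epochProvenance(out)))
  # already balanced input: identity up to ordering
  bal <- balanceClasses(out, seed = 9)
  expect_setequal(epochProvenance(bal)$trial, epochProvenance(out)$trial)
  # single class is an invalid state
  one <- ErrPDecode:::subsetEpochs(ep, which(trialLabels(ep) == "ErrP"))
  expect_error(balanceClasses(one), "both classes")
})

test_that("the preprocessing chain conserves counts and provenance", {
  rec <- makeTestRecording(seed = 31, nPerMovement = 25L)
  cfg <- preprocessConfig()
  filtered <- bandpassFilter(rec, cfg$band_hz, cfg$filterOrder)
  ep <- extractEpochs(filtered, cfg$epochWindow_ms)
  kept <- rejectArtifactEpochs(ep, cfg$rejectAmp_uV)
  expect_equal(nTrials(kept) + attr(kept, "nRejected"), nTrials(ep))
  bal <- balanceClasses(normalizeEpochs(kept), seed = 1)
  expect_balanced(bal)
  # provenance maps back into the original trial indices
  expect_true(all(epochProvenance(bal)$trial %in% epochProvenance(ep)$trial))
  # full chain is a pure function of (recording, config, seed)
  a <- preprocessRecording(rec, cfg, seed = 8)
  b <- preprocessRecording(rec, cfg, seed = 8)
  expect_identical(epochData(a), epochData(b))
  expect_identical(trialLabels(a), trialLabels(b))
})

test_that("preprocess config validates its thresholds", {
  expect_error(preprocessConfig(band_hz = c(0, 10)), "band_hz")
  expect_error(preprocessConfig(filterOrder = 3), "even")
  expect_error(preprocessConfig(badChannelSdK = 0), "positive")
  expect_error(preprocessConfig(rejectAmp_uV = -5), "positive")
})
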