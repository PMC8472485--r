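test_that("a full-design session yields 400 feedback events at 70/30", {
  rec <- makeTestRecording(seed = 5, nPerMovement = 100L)
  ev <- recordingEvents(rec)
  fb <- ev$code[grepl("^feedback", ev$code)]
  expect_length(fb, 400L)
  expect_equal(sum(fb == "feedback-correct"), 280L)
  expect_equal(sum(fb == "feedback-error"), 120L)
  expect_true(all(ev$sample >= 1 & ev$sample <= ncol(recordingSignal(rec))))
})

test_that("noise-free recording reproduces the template times spatial weight", {
  prof <- cleanProfile(noiseRms_uV = 0)
  rec <- makeTestRecording(seed = 2, nPerMovement = 2L, profile = prof)
  w <- ErrPDecode:::spatialWeights(channelLabels(rec))
  tplN <- synthesizeErpTemplate(erpTemplateParams(), "NonErrP",
                                samplingRate(rec), support_ms = c(0, 500))
  tplE <- synthesizeErpTemplate(erpTemplateParams(), "ErrP",
                                samplingRate(rec), support_ms = c(0, 500))
  ep <- extractEpochs(rec, window_ms = c(0, 500))
  for (i in seq_len(nTrials(ep))) {
    tpl <- if (trialLabels(ep)[i] == "ErrP") tplE else tplN
    for (c_ in seq_along(channelLabels(ep))) {
      expect_equal(epochData(ep)[c_, , i], w[[c_]] * as.numeric(tpl),
                   tolerance = 1e-12)
    }
  }
})

test_that("feedback-locked class averages converge on the template", {
  # high-SNR cohort: Monte-Carlo CI from the configured noise RMS
  prof <- cleanProfile(noiseRms_uV = 0.5)
  rec <- makeTestRecording(seed = 9, nPerMovement = 50L, profile = prof)
  ep <- extractEpochs(rec, window_ms = c(0, 500))
  wFCz <- ErrPDecode:::spatialWeights(channelLabels(rec))[["FCz"]]
  ci <- match("FCz", channelLabels(ep))
  for (cls in c("ErrP", "NonErrP")) {
    tpl <- wFCz * as.numeric(synthesizeErpTemplate(
      erpTemplateParams(), cls, samplingRate(rec), support_ms = c(0, 500)))
    sel <- which(trialLabels(ep) == cls)
    avg <- rowMeans(epochData(ep)[ci, , sel])
    # in-band noise RMS is below the broadband 0.5 uV RMS
    sem3 <- 3 * 0.5 / sqrt(length(sel))
    expect_lt(max(abs(avg - tpl)), sem3)
  }
})

test_that("recording synthesis is reproducible and seed-sensitive", {
  a <- makeTestRecording(seed = 7, nPerMovement = 2L)
  b <- makeTestRecording(seed = 7, nPerMovement = 2L)
  expect_identical(recordingSignal(a), recordingSignal(b))
  expect_identical(recordingEvents(a), recordingEvents(b))
  c_ <- makeTestRecording(seed = 8, nPerMovement = 2L)
  expect_false(identical(recordingSignal(a), recordingSignal(c_)))
})

test_that("cohorts have distinct ids and day-0-variance days differ only by noise", {
  prof <- cleanProfile(noiseRms_uV = 0)
  recs <- makeCohort(nParticipants = 3L, nDays = 2L, profile = prof,
                     montage = smallMontage(), fs = 200,
                     nPerMovement = 2L, phases = testPhases(), seed = 4)
  expect_length(recs, 6L)
  ids <- vapply(recs, function(r) sprintf("%s_d%d", r@participant, r@day), "")
  expect_equal(anyDuplicated(ids), 0L)
  # all variability and noise off: the two days of a participant coincide
  expect_identical(recordingSignal(recs[["p2_d1"]]),
                   recordingSignal(recs[["p2_d2"]]))
  # same seed -> identical cohort
  recs2 <- makeCohort(nParticipants = 3L, nDays = 2L, profile = prof,
                      montage = smallMontage(), fs = 200,
                      nPerMovement = 2L, phases = testPhases(), seed = 4)
  expect_identical(recordingSignal(recs[["p3_d2"]]),
                   recordingSignal(recs2[["p3_d2"]]))
})

test_that("degenerate simulator inputs are rejected", {
  sch <- makeSessionSchedule(2, 0.5, seed = 1, phases = testPhases())
  expect_error(synthesizeRecording(sch, montage = character(), fs = 200),
               "montage")
  expect_error(makeCohort(nParticipants = 0L), "positive")
  expect_error(makeCohort(nDays = 0L), "positive")
})
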