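# Shared fixtures: all synthetic, generated in code at test time.
# Scaled-down problem sizes (9 fronto-central channels, 200 Hz, shortened
# inter-trial phases) keep the suite fast; tests that exercise the
# full-size design parameters construct them explicitly.

smallMontage <- function() {
  c("Fz", "FC1", "FCz", "FC2", "C1", "Cz", "C2", "CPz", "Pz")
}

testPhases <- function() {
  c(idle = 1, preparation = 0.5, feedback_delay = 0.5, post = 1)
}

# default-variability profile for small-montage cohorts; the 3-SD
# bad-channel rule needs the full montage to be able to flag anything,
# so random bad channels are disabled at this scale
quietProfile <- function(...) {
  variabilityProfile(badChannelRate = 0, ...)
}

# profile with all nuisance and variability sources off (pure template +
# noise), for tests that need controlled SNR
cleanProfile <- function(noiseRms_uV = 2, ...) {
  variabilityProfile(noiseRms_uV = noiseRms_uV, latencyJitter_ms = 0,
                     participantAmpSigma = 0, participantLatencyShift_ms = 0,
                     dayAmpSigma = 0, dayLatencyShift_ms = 0,
                     artifactEpochRate = 0, badChannelRate = 0,
                     alpha10Hz_uV = 0, ...)
}

makeTestRecording <- function(seed = 1L, nPerMovement = 25L,
                              profile = quietProfile(), fs = 200,
                              template = erpTemplateParams(),
                              montage = smallMontage(), ...) {
  sch <- makeSessionSchedule(nPerMovement, 0.7,
                             seed = deriveSeed(seed, "schedule"),
                             phases = testPhases())
  synthesizeRecording(sch, template = template, profile = profile,
                      montage = montage, fs = fs,
                      seed = deriveSeed(seed, "recording"), ...)
}

makeTestEpochs <- function(seed = 1L, nPerMovement = 25L,
                           profile = quietProfile(), fs = 200,
                           template = erpTemplateParams(), ...) {
  rec <- makeTestRecording(seed, nPerMovement, profile, fs, template, ...)
  preprocessRecording(rec, seed = deriveSeed(seed, "balance"))
}

# an EpochSet of pure label-free noise (no class difference), for null
# and bookkeeping tests; dims channels x samples x trials
noiseEpochs <- function(nTrials = 40L, nCh = 3L, nSamp = 20L, fs = 50,
                        seed = 1L, sd = 1) {
  stopifnot(nTrials %% 2L == 0L)
  dat <- ErrPDecode:::withSeed(seed,
    array(stats::rnorm(nCh * nSamp * nTrials, sd = sd),
          dim = c(nCh, nSamp, nTrials)))
  new("EpochSet", data = dat,
      labels = ErrPDecode:::errpFactor(rep(c("NonErrP", "ErrP"),
                                           each = nTrials / 2L)),
      window = c(100, 100 + nSamp / fs * 1000), fs = fs,
      channels = paste0("ch", seq_len(nCh)),
      provenance = data.frame(participant = "px", day = 1L,
                              trial = seq_len(nTrials)))
}

# cohort of preprocessed sessions, indexed [[participant]][[day]]
makeTestCohortEpochs <- function(seed, nParticipants = 4L, nDays = 2L,
                                 nPerMovement = 50L,
                                 profile = quietProfile(),
                                 template = erpTemplateParams(),
                                 fs = 200) {
  recs <- makeCohort(nParticipants = nParticipants, nDays = nDays,
                     profile = profile, template = template,
                     montage = smallMontage(), fs = fs,
                     nPerMovement = nPerMovement, phases = testPhases(),
                     seed = seed)
  eps <- lapply(seq_along(recs), function(i)
    suppressWarnings(preprocessRecording(
      recs[[i]], seed = deriveSeed(seed, paste0("balance/", i)))))
  names(eps) <- names(recs)
  eps
}

expect_balanced <- function(epochs) {
  counts <- table(trialLabels(epochs))
  expect_equal(unname(counts["ErrP"]), unname(counts["NonErrP"]))
}
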