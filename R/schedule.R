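#' Build a randomized sham-feedback session schedule
#'
#' Generates the trial plan of one session: `nPerMovement` trials of each
#' of the four attempted movements (left/right hand, left/right foot) in
#' randomized order, each assigned a predetermined sham feedback outcome.
#' Feedback labels use an exact-count scheduler: the number of
#' correct-feedback trials is `round(ratioCorrect * nTrials)` exactly
#' (not an i.i.d. draw), then randomly permuted over trials, so the
#' configured class ratio holds exactly in every session.
#'
#' @param nPerMovement trials per movement type (default 100, i.e. 400
#'   trials per session).
#' @param ratioCorrect fraction of correct-feedback trials, in (0, 1)
#'   (default 0.7 for the 70/30 correct/error ratio).
#' @param seed integer seed; the schedule is a pure function of the
#'   arguments and the seed.
#' @param phases named numeric durations in seconds: `idle` (default 5),
#'   `preparation` (3), `feedback_delay` (3, movement attempt included),
#'   and `post` (1, time after feedback onset before the next trial).
#' @return a [TrialSchedule-class].
#' @examples
#' sch <- makeSessionSchedule(100, 0.70, seed = 1)
#' table(scheduleTrials(sch)$feedback)  # 280 correct / 120 error
#' @export
makeSessionSchedule <- function(nPerMovement, ratioCorrect = 0.7, seed = 1L,
                                phases = c(idle = 5, preparation = 3,
                                           feedback_delay = 3, post = 1)) {
  if (length(nPerMovement) != 1L || is.na(nPerMovement) || nPerMovement < 1)
    stopInvalid("nPerMovement must be a positive count")
  if (ratioCorrect <= 0 || ratioCorrect >= 1)
    stopInvalid("ratioCorrect must lie strictly in (0, 1)")
  nPerMovement <- as.integer(nPerMovement)
  movements <- c("left-hand", "right-hand", "left-foot", "right-foot")
  n <- 4L * nPerMovement
  nCorrect <- as.integer(round(ratioCorrect * n))
  nCorrect <- max(1L, min(n - 1L, nCorrect))  # keep both classes present
  withSeed(seed, {
    movement <- sample(rep(movements, nPerMovement))
    feedback <- sample(c(rep("correct", nCorrect),
                         rep("error", n - nCorrect)))
  })
  trialDur <- sum(phases)
  trials <- data.frame(movement = movement, feedback = feedback,
                       start_s = (seq_len(n) - 1L) * trialDur,
                       stringsAsFactors = FALSE)
  new("TrialSchedule", trials = trials, phases = phases,
      ratioCorrect = ratioCorrect)
}

#' Feedback onset times of a schedule (seconds)
#'
#' Feedback is presented after the idle, preparation and feedback-delay
#' phases of each trial.
#'
#' @param schedule a [TrialSchedule-class].
#' @return numeric vector, one onset per trial.
#' @export
feedbackOnsets <- function(schedule) {
  stopifnot(is(schedule, "TrialSchedule"))
  offset <- sum(schedule@phases[c("idle", "preparation", "feedback_delay")])
  schedule@trials$start_s + offset
}

#' Parameters of the two-peak feedback-locked ERP template
#'
#' The feedback-locked potential is modelled as the sum of two
#' Gaussian-shaped deflections: a negative peak (~350 ms) followed by a
#' positive peak (~450 ms). ErrP epochs differ from NonErrP epochs only
#' by `classDelta_uV` added to the negative-peak amplitude (a slightly
#' deeper negativity for errors).
#'
#' @param negLatency_ms,posLatency_ms peak latencies after feedback onset.
#' @param negAmp_uV,posAmp_uV peak amplitudes (negAmp must be negative,
#'   posAmp positive).
#' @param negWidth_ms,posWidth_ms Gaussian SD of each deflection (> 0).
#' @param classDelta_uV extra (negative) amplitude added to the ErrP
#'   negative peak relative to NonErrP.
#' @return named list of validated template parameters.
#' @export
erpTemplateParams <- function(negLatency_ms = 350, posLatency_ms = 450,
                              negAmp_uV = -4, posAmp_uV = 3,
                              negWidth_ms = 25, posWidth_ms = 30,
                              classDelta_uV = -2) {
  if (negWidth_ms <= 0 || posWidth_ms <= 0)
    stopInvalid("peak widths must be positive")
  if (negAmp_uV > 0 || posAmp_uV < 0)
    stopInvalid("negAmp_uV must be <= 0 and posAmp_uV >= 0")
  list(negLatency_ms = negLatency_ms, posLatency_ms = posLatency_ms,
       negAmp_uV = negAmp_uV, posAmp_uV = posAmp_uV,
       negWidth_ms = negWidth_ms, posWidth_ms = posWidth_ms,
       classDelta_uV = classDelta_uV)
}

#' Participant-, day- and trial-level variability profile
#'
#' Controls how much synthesized sessions differ across trials (latency
#' jitter), days (amplitude scaling and latency shift) and participants
#' (amplitude scaling), plus nuisance structure: background-noise RMS,
#' the probability and size of high-amplitude artifact epochs, and the
#' per-channel probability of a globally bad channel.
#'
#' Amplitude scales are lognormal: a sigma of 0.3 means the multiplicative
#' participant factor has a log-SD of 0.3 around 1. Default rates are set
#' so a 400-trial session rejects on the order of 70 epochs and loses at
#' most about one channel, matching typical session attrition in
#' sham-feedback ErrP recordings.
#'
#' @param participantAmpSigma lognormal sigma of the per-participant
#'   amplitude scale.
#' @param participantLatencyShift_ms Gaussian SD of the per-participant
#'   shift of both peak latencies (individual ERP latency differences).
#' @param dayAmpSigma lognormal sigma of the per-day amplitude scale.
#' @param latencyJitter_ms Gaussian SD of per-trial peak-latency jitter.
#' @param dayLatencyShift_ms Gaussian SD of the per-day latency shift.
#' @param noiseRms_uV RMS of the 1/f-shaped background noise per channel.
#' @param artifactEpochRate probability that a trial's feedback epoch
#'   contains a high-amplitude artifact transient.
#' @param artifactAmp_uV minimum peak amplitude of artifact transients.
#' @param badChannelRate per-channel probability of being globally bad
#'   (grossly inflated amplitude for the whole recording).
#' @param alpha10Hz_uV amplitude of an optional ongoing 10 Hz component.
#' @return named list of validated profile parameters.
#' @export
variabilityProfile <- function(participantAmpSigma = 0.3,
                               participantLatencyShift_ms = 20,
                               dayAmpSigma = 0.15,
                               latencyJitter_ms = 20,
                               dayLatencyShift_ms = 15,
                               noiseRms_uV = 2,
                               artifactEpochRate = 0.18,
                               artifactAmp_uV = 300,
                               badChannelRate = 0.008,
                               alpha10Hz_uV = 1) {
  vals <- c(participantAmpSigma, participantLatencyShift_ms, dayAmpSigma,
            latencyJitter_ms,
            dayLatencyShift_ms, noiseRms_uV, artifactAmp_uV, alpha10Hz_uV)
  if (any(vals < 0))
    stopInvalid("sigmas, rates and amplitudes must be non-negative")
  if (artifactEpochRate < 0 || artifactEpochRate > 1 ||
      badChannelRate < 0 || badChannelRate > 1)
    stopInvalid("artifactEpochRate and badChannelRate must lie in [0, 1]")
  list(participantAmpSigma = participantAmpSigma,
       participantLatencyShift_ms = participantLatencyShift_ms,
       dayAmpSigma = dayAmpSigma,
       latencyJitter_ms = latencyJitter_ms,
       dayLatencyShift_ms = dayLatencyShift_ms,
       noiseRms_uV = noiseRms_uV, artifactEpochRate = artifactEpochRate,
       artifactAmp_uV = artifactAmp_uV, badChannelRate = badChannelRate,
       alpha10Hz_uV = alpha10Hz_uV)
}
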