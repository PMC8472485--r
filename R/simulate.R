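#' Synthesize the feedback-locked ERP template
#'
#' Builds the noise-free waveform added at every feedback onset: a
#' negative Gaussian deflection followed by a positive one, each
#' truncated to zero beyond three widths from its latency. For the ErrP
#' class the negative-peak amplitude is `negAmp_uV + classDelta_uV`
#' (a deeper negativity); the positive peak is shared by both classes.
#'
#' @param params template parameters from [erpTemplateParams()].
#' @param class `"ErrP"` or `"NonErrP"`.
#' @param fs sampling rate in Hz.
#' @param support_ms half-open time support `[start, end)` in ms relative
#'   to feedback onset over which the template is sampled.
#' @return numeric vector of `round(diff(support_ms)/1000*fs)` samples
#'   (microvolts), with attribute `time_ms` giving each sample's latency.
#' @export
synthesizeErpTemplate <- function(params, class = c("NonErrP", "ErrP"),
                                  fs, support_ms = c(0, 700)) {
  class <- match.arg(class)
  if (params$negLatency_ms < support_ms[1L] ||
      params$posLatency_ms >= support_ms[2L] ||
      params$negLatency_ms > params$posLatency_ms)
    stopInvalid("peak latencies must be ordered and lie inside the support window")
  n <- round(diff(support_ms) / 1000 * fs)
  t <- support_ms[1L] + (seq_len(n) - 1L) / fs * 1000
  negAmp <- params$negAmp_uV + if (class == "ErrP") params$classDelta_uV else 0
  bump <- function(amp, lat, width) {
    y <- amp * exp(-(t - lat)^2 / (2 * width^2))
    y[abs(t - lat) > 3 * width] <- 0
    y
  }
  w <- bump(negAmp, params$negLatency_ms, params$negWidth_ms) +
       bump(params$posAmp_uV, params$posLatency_ms, params$posWidth_ms)
  attr(w, "time_ms") <- t
  w
}

# 1/f-amplitude-shaped Gaussian noise of target RMS, by spectral shaping
# of white noise (power spectral density ~ 1/f above a 0.1 Hz floor).
pinkNoise <- function(n, fs, rms) {
  if (rms == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(0, seq_len(m - 1L)) * fs / m
  f <- pmin(f, fs - f)                   # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 0.1))
  shape[1L] <- 0                         # no DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y * rms / sqrt(mean(y^2))
}

#' Synthesize one continuous sham-feedback EEG recording
#'
#' Realizes a session schedule as continuous multi-channel EEG: 1/f-shaped
#' Gaussian background noise (plus a weak ongoing 10 Hz component) on
#' every channel, the class-appropriate feedback-locked template added at
#' each feedback onset — scaled by fronto-central spatial weights and an
#' overall amplitude factor, and shifted by per-trial latency jitter —
#' high-amplitude artifact transients in a random subset of feedback
#' epochs, and optional globally bad channels with grossly inflated
#' amplitude. Cue and feedback events are recorded with the feedback code
#' matching the scheduled outcome. Output is a pure function of
#' (arguments, seed).
#'
#' @param schedule a [TrialSchedule-class].
#' @param template parameters from [erpTemplateParams()].
#' @param profile variability/nuisance parameters from
#'   [variabilityProfile()].
#' @param montage character vector of channel labels (default the
#'   37-channel [standardMontage()]).
#' @param fs sampling rate in Hz (default 1200).
#' @param seed integer seed.
#' @param participant,day identifiers stored in the Recording.
#' @param amplitudeScale overall multiplicative scale of the template
#'   (participant x day factor; drawn by [makeCohort()]).
#' @param latencyShift_ms additive shift of both peak latencies (day-level
#'   factor; drawn by [makeCohort()]).
#' @param forceBadChannels optional channel labels forced bad (in addition
#'   to random draws), used to construct deterministic fixtures.
#' @return a [Recording-class].
#' @export
synthesizeRecording <- function(schedule, template = erpTemplateParams(),
                                profile = variabilityProfile(),
                                montage = standardMontage(), fs = 1200,
                                seed = 1L, participant = "p1", day = 1L,
                                amplitudeScale = 1, latencyShift_ms = 0,
                                forceBadChannels = character()) {
  stopifnot(is(schedule, "TrialSchedule"))
  if (nTrials(schedule) == 0L) stopInvalid("schedule has no trials")
  if (length(montage) == 0L) stopInvalid("montage must be non-empty")
  nCh <- length(montage)
  tr <- schedule@trials
  onsets <- feedbackOnsets(schedule)
  postEnd <- max(onsets) + schedule@phases[["post"]]
  nSamp <- as.integer(ceiling(postEnd * fs)) + 1L
  w <- spatialWeights(montage)

  # templates shifted by the day-level latency offset
  shifted <- template
  shifted$negLatency_ms <- shifted$negLatency_ms + latencyShift_ms
  shifted$posLatency_ms <- shifted$posLatency_ms + latencyShift_ms
  supp <- c(0, shifted$posLatency_ms + 3 * shifted$posWidth_ms + 50)
  tplErr <- synthesizeErpTemplate(shifted, "ErrP", fs, supp)
  tplNon <- synthesizeErpTemplate(shifted, "NonErrP", fs, supp)
  nTpl <- length(tplErr)

  withSeed(seed, {
    sig <- matrix(0, nrow = nCh, ncol = nSamp, dimnames = list(montage, NULL))
    for (c_ in seq_len(nCh)) {
      sig[c_, ] <- pinkNoise(nSamp, fs, profile$noiseRms_uV)
      if (profile$alpha10Hz_uV > 0)
        sig[c_, ] <- sig[c_, ] + profile$alpha10Hz_uV *
          sin(2 * pi * 10 * seq_len(nSamp) / fs + stats::runif(1L, 0, 2 * pi))
    }
    jitter <- stats::rnorm(nrow(tr), 0, profile$latencyJitter_ms)
    isArtifact <- stats::runif(nrow(tr)) < profile$artifactEpochRate
    fbSample <- as.integer(round(onsets * fs)) + 1L
    for (i in seq_len(nrow(tr))) {
      tpl <- if (tr$feedback[i] == "error") tplErr else tplNon
      i0 <- fbSample[i] + as.integer(round(jitter[i] / 1000 * fs))
      idx <- i0:(i0 + nTpl - 1L)
      keep <- idx >= 1L & idx <= nSamp
      if (!any(keep)) next
      add <- amplitudeScale * tpl[keep]
      sig[, idx[keep]] <- sig[, idx[keep]] + outer(w, add)
      if (isArtifact[i]) {
        # slow high-amplitude transient inside the analysis window
        aAmp <- profile$artifactAmp_uV * (1 + abs(stats::rnorm(1L, 0, 0.3))) *
          sample(c(-1, 1), 1L)
        aLat <- stats::runif(1L, 150, 450)          # ms after feedback
        aCtr <- fbSample[i] + as.integer(round(aLat / 1000 * fs))
        halfW <- as.integer(round(0.15 * fs))       # +/- 150 ms support
        aOff <- seq(-halfW, halfW)
        aIdx <- aCtr + aOff
        keepA <- aIdx >= 1L & aIdx <= nSamp
        bump <- aAmp * exp(-aOff[keepA]^2 / (2 * (0.05 * fs)^2))
        chW <- stats::runif(nCh, 0.6, 1)
        sig[, aIdx[keepA]] <- sig[, aIdx[keepA]] + outer(chW, bump)
      }
    }
    badDraw <- montage[stats::runif(nCh) < profile$badChannelRate]
    bad <- union(badDraw, intersect(forceBadChannels, montage))
    if (length(bad))
      sig[bad, ] <- sig[bad, , drop = FALSE] * 25
  })

  cueSample <- as.integer(round((tr$start_s +
    sum(schedule@phases[c("idle", "preparation")])) * fs)) + 1L
  events <- data.frame(
    sample = c(cueSample, fbSample),
    code = c(rep("cue", nrow(tr)),
             ifelse(tr$feedback == "error", "feedback-error",
                    "feedback-correct")),
    stringsAsFactors = FALSE)
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  new("Recording", signal = sig, channels = montage, fs = fs,
      events = events, participant = as.character(participant),
      day = as.integer(day))
}

#' Synthesize a multi-participant, multi-day cohort
#'
#' Draws participant-level parameters once per participant (amplitude
#' scale; the trial order of the session schedule is also fixed per
#' participant) and day-level parameters per (participant, day)
#' (amplitude scale and latency shift), then synthesizes one Recording
#' per (participant, day). All randomness derives from `seed` via
#' stage-tagged seeds, so the cohort is fully reproducible.
#'
#' @param nParticipants,nDays cohort dimensions (defaults 25 and 2).
#' @param profile variability profile from [variabilityProfile()].
#' @param template template parameters from [erpTemplateParams()].
#' @param montage channel labels (default [standardMontage()]).
#' @param fs sampling rate in Hz.
#' @param nPerMovement,ratioCorrect,phases schedule parameters passed to
#'   [makeSessionSchedule()].
#' @param seed integer master seed for the cohort.
#' @return list of [Recording-class] objects, named `"p<i>_d<j>"`.
#' @export
makeCohort <- function(nParticipants = 25L, nDays = 2L,
                       profile = variabilityProfile(),
                       template = erpTemplateParams(),
                       montage = standardMontage(), fs = 1200,
                       nPerMovement = 100L, ratioCorrect = 0.7,
                       phases = c(idle = 5, preparation = 3,
                                  feedback_delay = 3, post = 1),
                       seed = 1L) {
  if (nParticipants < 1L || nDays < 1L)
    stopInvalid("nParticipants and nDays must be positive")
  out <- vector("list", nParticipants * nDays)
  nm <- character(length(out))
  k <- 0L
  for (p in seq_len(nParticipants)) {
    pPar <- withSeed(deriveSeed(seed, sprintf("participant/%d", p)), {
      c(exp(stats::rnorm(1L, 0, profile$participantAmpSigma)),
        stats::rnorm(1L, 0, profile$participantLatencyShift_ms))
    })
    sch <- makeSessionSchedule(nPerMovement, ratioCorrect,
                               seed = deriveSeed(seed, sprintf("schedule/%d", p)),
                               phases = phases)
    for (d in seq_len(nDays)) {
      dayPar <- withSeed(deriveSeed(seed, sprintf("day/%d/%d", p, d)), {
        c(exp(stats::rnorm(1L, 0, profile$dayAmpSigma)),
          stats::rnorm(1L, 0, profile$dayLatencyShift_ms))
      })
      k <- k + 1L
      out[[k]] <- synthesizeRecording(
        sch, template = template, profile = profile, montage = montage,
        fs = fs, seed = deriveSeed(seed, sprintf("recording/%d/%d", p, d)),
        participant = sprintf("p%d", p), day = d,
        amplitudeScale = pPar[1L] * dayPar[1L],
        latencyShift_ms = pPar[2L] + dayPar[2L])
      nm[k] <- sprintf("p%d_d%d", p, d)
    }
  }
  names(out) <- nm
  out
}
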