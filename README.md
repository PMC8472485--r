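# ErrPDecode

Single-trial decoding of error-related potentials (ErrPs) from EEG, with
calibration-transfer evaluation and a full synthetic-data path.

## The problem

When a brain–computer interface (BCI) gives its user feedback that the
user perceives as wrong, the EEG shows a characteristic feedback-locked
response — the error-related potential: a fronto-central negativity
roughly 350 ms after feedback onset followed by a positivity near
450 ms. Detecting ErrPs on single trials lets a BCI correct its own
mistakes or label its own training data, which matters most in
populations (e.g. stroke rehabilitation) where collecting calibration
data is expensive. The practical question this package addresses is how
much decoding accuracy survives when the classifier is calibrated on
data from a different day (*between-day*) or from other people
(*across-participant*) instead of the same session (*within-day*).

Because clinical EEG of this kind is rarely shareable, the package
includes a first-class simulator of sham-feedback sessions: a 37-channel
10-10 montage at 1200 Hz, sessions of 400 attempted movements with
sham feedback at a fixed 70/30 correct/error ratio, two-peak
feedback-locked waveforms with controllable trial-, day- and
participant-level variability, 1/f background noise, high-amplitude
artifact epochs, and globally bad channels. Every stage of the pipeline
is testable against known ground truth.

## The pipeline

1. **Preprocessing** — 0.05–10 Hz zero-phase (forward–backward)
   Butterworth band-pass of order 8, applied as cascaded second-order
   sections; exclusion of channels whose mean absolute amplitude exceeds
   the across-channel mean by more than 3 SD; feedback-locked epochs over
   [100, 500) ms; rejection of epochs exceeding 150 µV; per-epoch,
   per-channel mean subtraction; random subsampling of the majority
   class to exact balance.
2. **Features** — the epoch waveform either decimated to 50 Hz
   (`channels x 20` values) or used whole (`channels x samples`).
3. **Classifiers** — both written from first principles:
   - a 5-layer MLP (hidden sizes 100-50-25, tanh; sigmoid output)
     trained full-batch by scaled conjugate gradient on the binary
     cross-entropy, at most 200 iterations, no early stopping;
   - shrinkage LDA: `w = Σ(γ)⁻¹ (μ_ErrP − μ_NonErrP)` with the pooled
     within-class covariance shrunk toward `(tr S / d) I` at the analytic
     Ledoit–Wolf intensity γ.
4. **Evaluation** — stratified 10-fold CV (within-day), day-to-day
   transfer in both directions (between-day), leave-one-participant-out
   (across-participant); exact binomial chance levels
   (smallest k/n with P(Bin(n, ½) ≥ k) ≤ 0.05); grand-average waveforms
   with standard errors; Pearson/Spearman correlation for test–retest
   reliability and clinical-score associations.

## Worked example

```r
library(ErrPDecode)

mont   <- c("Fz","FC1","FCz","FC2","C1","Cz","C2","CPz","Pz")
phases <- c(idle = 1, preparation = 0.5, feedback_delay = 0.5, post = 1)
sch <- makeSessionSchedule(50, 0.7, seed = 1, phases = phases)
rec <- synthesizeRecording(sch, profile = variabilityProfile(badChannelRate = 0),
                           montage = mont, fs = 200, seed = 2)
rec
#> Recording: participant p1, day 1
#>   9 channels x 120001 samples @ 200 Hz (600.0 s)
#>   400 events (200 feedback)

ep <- preprocessRecording(rec, seed = 3)
ep
#> EpochSet: 90 epochs x 9 channels x 80 samples @ 200 Hz
#>   window [100, 500) ms; labels: NonErrP=45, ErrP=45

res <- withinDayCV(ep, classifierSpec("slda-features"), k = 10, seed = 4)
res
#> EvalResult: within-day / slda-features over 10 units
#>   accuracy 0.730 +/- 0.073 (SE); mean chance level 0.887
```

The session of 200 trials (140 correct / 60 error feedback) loses 41
epochs to the 150 µV artifact rule here; balancing the survivors gives
45 per class. Shrinkage LDA on the 50 Hz waveform features then decodes
error vs. correct feedback at 73% under 10-fold cross-validation — well
above the 60% binomial chance level for the 90 pooled test trials
(the 0.887 printed above is the mean per-fold threshold; single 9-trial
folds are individually underpowered).
`betweenDay()` and `acrossParticipantLopo()` evaluate the same session
under the two transfer schemes, and `runExperiment()` orchestrates the
full cohort × scheme × method factorial into a tidy results table.

A command-line front end over the same functions is installed at
`inst/scripts/errp.R` (`simulate`, `run`, `report` subcommands; EDF +
CSV + JSON on disk).

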