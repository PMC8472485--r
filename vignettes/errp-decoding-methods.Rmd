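---
title: "Methods: simulating and decoding error-related potentials"
author: "ErrPDecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding error-related potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the scientific and numerical choices behind
ErrPDecode: what the synthetic sham-feedback EEG emulates and what it
does not, how each preprocessing rule is interpreted, how the two
classifiers are built, and which decisions were genuinely open.

## The task and its data model

A sham-feedback BCI session consists of repeated trials: an idle phase,
a preparation cue, an attempted movement, and — after a fixed delay —
visual feedback that is *predetermined* (sham) at a fixed 70/30
correct/error ratio, independent of the EEG. Error feedback elicits an
error-related potential: at fronto-central sites, a negativity near
350 ms after feedback and a positivity near 450 ms, with the negativity
slightly deeper for errors than for correct feedback. The decoding
problem is binary single-trial classification of the feedback-locked
epoch into ErrP vs. NonErrP.

The package's containers follow that structure: `Recording` (continuous
channels × samples with typed events), `TrialSchedule`, `EpochSet`
(channels × samples × trials with labels, window metadata and trial
provenance), `FeatureMatrix` (trials × features with a per-column
channel/latency map), the two model classes, and `EvalResult`.

## The generator

`makeSessionSchedule()` uses an exact-count feedback scheduler: the
number of correct trials is `round(ratio · n)`, then permuted over
trials. An i.i.d. Bernoulli draw would make every class-balance
computation downstream stochastic; the exact scheduler makes the 70/30
ratio, and everything derived from it, deterministic and testable. Trial
order is drawn once per participant and reused across that participant's
days, so with day-level variance set to zero the two days of a
participant differ only by the noise realization — a useful exact limit
for testing.

`synthesizeErpTemplate()` models the feedback-locked response as two
Gaussian deflections (negative then positive), truncated at ±3 widths.
The published waveforms constrain latencies and rough amplitudes but not
a functional form, so a two-bump parametric family anchored at
350/450 ms was adopted. Defaults: −4 µV at 350 ms (SD 25 ms), +3 µV at
450 ms (SD 30 ms), and an extra −2 µV on the negative peak for ErrP
(`classDelta_uV`), which is the *only* class difference. The widths are
deliberately narrow enough that the overlapping bumps do not displace
each other's extrema by more than one sample at any rate ≥ 200 Hz — an
invariant the tests check; at SDs much above ~40/60 ms the positive
limb's slope under the negativity shifts the waveform minimum by several
milliseconds and the latency-recovery tests would be measuring that
analytic artifact rather than the pipeline.

Spatial structure: each channel receives the template scaled by a
Gaussian in scalp position peaking between FCz and Cz (SD 0.45 head
units). Per-channel ErrP topography is not published for this paradigm;
the fronto-central maximum is the textbook ErrP topography and is
flagged as an assumption.

Background activity is Gaussian noise with 1/f spectral shaping (floor
0.1 Hz, RMS 2 µV per channel by default) plus a 1 µV ongoing 10 Hz
component with random phase per channel — the minimal spectrum that
gives realistic in-band noise after the 0.05–10 Hz filter. Nuisance
structure: with probability 0.18 a trial's analysis window receives a
slow transient of ≥ 300 µV (Gaussian, SD 50 ms), emulating movement/
ocular artifacts; each channel is independently "bad" with probability
0.008, realized as a 25× amplitude inflation of the whole channel.
These rates were chosen so a 400-trial session loses on the order of 70
epochs and at most about one channel — the attrition regime typical of
clinical sham-feedback recordings.

Variability has three levels, all multiplicative-amplitude and/or
latency:

| level | parameter | default |
|---|---|---|
| trial | latency jitter (Gaussian SD) | 20 ms |
| day | amplitude scale (lognormal SD) | 0.15 |
| day | latency shift (Gaussian SD) | 15 ms |
| participant | amplitude scale (lognormal SD) | 0.30 |
| participant | latency shift (Gaussian SD) | 20 ms |

The per-participant latency shift deserves a note: amplitude scaling
alone cannot degrade across-participant transfer for a balanced linear
classifier, because scaling both class means scales the midpoint
identically and leaves the decision boundary correct. Real cross-subject
ERP heterogeneity is dominated by component latency and topography
differences; the generator encodes the latency part, which is what makes
leave-one-participant-out calibration measurably harder than within-day
calibration, as observed in practice. The noise RMS (2 µV against a
4–6 µV template) was fixed so that within-day shrinkage-LDA accuracy on
a single session lands in the 70–90 % band reported across the ErrP
decoding literature; it was chosen once, at design time, and all
structural claims (scheme ordering, null behaviour, monotonicity in
`classDelta_uV`) are then emergent rather than tuned.

What the simulator does **not** model: artifact morphology
(blinks/EMG are amplitude transients only), movement-related cortical
potentials from the attempted movements, topography differences across
participants, impairment-level effects, and any nonstationarity within
a session. Passing tests therefore demonstrate the pipeline's
correctness and its qualitative transfer behaviour — not clinical
performance on real EEG.

## Preprocessing interpretation

* **"8th-order zero-phase Butterworth, 0.05–10 Hz"** — an order-8
  band-pass is designed and applied forward–backward (zero phase,
  squared magnitude). The alternative reading (design order 4 so the
  two passes give order 8) is available via the `order` argument. The
  filter is designed in zero-pole-gain form and applied as cascaded
  biquads: at 1200 Hz this band has normalized corner frequencies down
  to 8·10⁻⁵, where the expanded polynomial transfer function is
  numerically unstable (its roots round to outside the unit circle) —
  we verified output divergence to ~10¹⁷⁷ with a polynomial
  implementation — while the section cascade matches the closed-form
  Butterworth magnitude to ~10⁻¹¹. Forward–backward application uses
  odd reflection padding of 1.5 time constants of the low edge with
  step-response initial conditions per section.
* **Bad channels** ("mean amplitude > 3 SD above the channel average") —
  the statistic is the mean *absolute* amplitude over the whole
  (filtered) recording; a signed mean of band-passed EEG is ≈ 0 for
  every channel and cannot discriminate. A caveat the tests document:
  with a single outlier among m channels the k-SD rule can only fire
  when `1/m + k/√(m−1) < 1`, i.e. for k = 3 only when m ≳ 14. The rule
  behaves as intended on the full 37-channel montage; small sub-montages
  used for fast simulations disable random bad channels instead.
* **Epochs** are half-open [100, 500) ms windows after feedback, so the
  sample count is unambiguous (480 at 1200 Hz). Events too close to the
  recording edge are dropped with a warning, not an error.
* **Rejection** is a strict `> 150 µV` test on the maximum absolute
  value across retained channels and samples, applied to the filtered,
  *un-normalized* epochs (the threshold is a physical amplitude;
  normalizing first would change its meaning).
* **Normalization** subtracts each channel's own within-epoch mean
  (idempotent); pooling channels would mix scalp locations with
  different baseline offsets.
* **Balancing** runs once per session after rejection — not per CV
  fold — keeping every minority-class epoch and subsampling the
  majority uniformly without replacement, order randomized, seeded.

## Classifiers

**Scaled conjugate gradient** (`scgMinimize()`) is implemented from the
standard formulation: conjugate direction updates with an adaptive
damping λ replacing the line search; curvature along the direction from
a finite difference of the gradient (scale σ₀ = 10⁻⁵, λ₀ = 10⁻⁷); λ
raised on non-positive curvature, steps accepted only when the
comparison ratio is positive (so the accepted-step loss sequence is
non-increasing — property-tested), λ relaxed when the local quadratic
model is good; periodic restart every `length(w)` iterations.

The **MLP** is the input–100–50–25–1 pattern network: tanh hidden
units (the conventional default of the pattern-recognition tooling this
architecture comes from; the activation is not otherwise specified and
is configurable), sigmoid output, mean binary cross-entropy, full batch,
at most 200 SCG iterations. "Validation checks = max iterations" is
implemented as *no early stopping and no validation split*. Weights are
Glorot-uniform, seeded, so training is bit-reproducible. Inputs enter in
microvolts without standardization — none is part of the pipeline
specification, and the tests confirm the optimizer copes with the µV
scale.

**Shrinkage LDA** uses the pooled within-class covariance with analytic
Ledoit–Wolf shrinkage toward `(tr S / d) I` — the de-facto standard
"shrinkage LDA" in ERP decoding; γ is also settable manually. The
decision threshold assumes equal priors, which class balancing enforces;
a score of exactly zero is assigned to NonErrP (documented tie-break).
The implementation is verified against a brute-force two-discriminant
Gaussian oracle with loop-computed covariance and shrinkage intensity.

## Evaluation

Cross-validation folds are stratified (preserving the enforced 50/50
balance per fold) and seeded. Between-day transfer trains on all of one
day's epochs and reports both directions separately; mismatched
retained-channel sets are resolved by intersection, logged. The
leave-one-participant-out pool concatenates the per-participant
*balanced* epoch sets unweighted, with no re-balancing after pooling.
Chance level is the exact binomial threshold: the smallest k/n with
P(Bin(n, 1/classes) ≥ k) ≤ α; when even n/n is not significant the
function returns 1 with a warning. Accuracy is the trial-level fraction
correct — no AUC/F1, matching the reporting convention of the paradigm.
Grand averages are means of per-participant averages with the
across-participant standard error. Correlations (Pearson for day-1 vs.
day-2 test–retest reliability, Spearman for accuracy vs. ordinal
clinical scores) use the two-sided t-approximation with average ranks
for ties.

## Problem sizes and reproducibility

The native design — 37 channels at 1200 Hz, 400 trials of 12 s — is the
default everywhere, but a single such session is ~1.7 GB in memory, so
the test suite and the acceptance script run *scaled-down replicas*:
the 9 fronto-central channels of the montage at 200 Hz, 100–400 trials
with shortened idle/preparation phases (template, epoch window and all
thresholds unchanged). Epoch-level statistics are unaffected by the
inter-trial spacing because epochs never overlap at either spacing.
Stochastic acceptance checks use 10 simulated cohorts of 4
participants × 2 days; nulls pool three 2 × 2 cohorts; monotonicity in
`classDelta_uV` uses five single sessions per level.

Every source of randomness flows through a single master seed:
`deriveSeed(master, stage_tag)` hashes the stage name into a 31-bit
seed, and each generator/balancer/fold-assignment call uses its own
derived seed, so whole experiments are byte-reproducible
(`runExperiment()` run twice yields identical CSVs) without per-stage
seed bookkeeping. All generation restores the caller's RNG state.

## Known limitations

* The simulator's participant heterogeneity is latency + amplitude
  only; across-participant accuracies on simulation should be read as
  qualitative (ordering, above-chance), not as predictions of clinical
  transfer rates.
* The EDF writer targets the plain continuous-EDF subset (one physical
  dimension, 1 s records, events in a companion CSV), sufficient for
  round-tripping this package's recordings, not a general EDF+ library.
* The repeated-measures ANOVA machinery used for omnibus significance
  testing in the source study is out of scope by design; `runExperiment()`
  exports the tidy per-unit results table for any external stats tool.
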