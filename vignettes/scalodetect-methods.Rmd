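---
title: "Detection of seizures and spike-wave discharges in chronic rodent EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection of seizures and spike-wave discharges in chronic rodent EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic EEG monitoring of rodents after traumatic brain injury produces
months of continuous single-channel recordings, conventionally stored as
contiguous 0.5 h intervals sampled at 500 Hz. Two event classes dominate
such records and must not be confused:

* **Convulsive seizures** — large-amplitude repetitive spiking with a
  stereotyped phase structure: onset spiking (instantaneous rates of
  1–20 Hz, amplitudes more than twice the preceding background), an
  optional *mid-ictal depression* (MID, a 10–180 s amplitude collapse),
  resumed lower-frequency spiking at seizure end, *post-ictal depression*
  (PID), and occasional trailing multi-spike bursts. Seizures occurring at
  most 5 days post-implant are "early" (surgery-associated); seizures after
  5 days are "late" and define post-traumatic epilepsy (PTE).
* **Spike-wave discharges** (SWDs) — oscillations with a stable 7–12 Hz
  fundamental and spike-wave cycle morphology that reach full amplitude
  within about one cycle, wax and wane, and end abruptly; durations run
  from 3 s to tens of seconds. SWDs occur in injured and uninjured animals
  alike and are the main confound for seizure detection.

`scalodetect` implements the full automated analysis: segmentation of
records into 10 s epochs, conversion to continuous-wavelet-transform (CWT)
scalogram images, binary CNN classification at a fixed confidence
threshold, aggregation of detections into per-interval duration timelines,
and the cross-over training and group-statistics experiments built on top.
Because the original recordings are not publicly deposited, the package
also contains a first-class synthetic cohort generator with exact ground
truth, which is what every quantitative claim in the test suite is
evaluated against.

## The synthetic cohort generator

The generator is the package's definition of the study conditions; its
defaults are fixed and the tests are run against them.

**Background.** Pink (1/f) Gaussian noise band-limited to 0.5–100 Hz,
scaled to a stationary RMS of 50 µV. EEG background spectra are
approximately 1/f over this band; no attempt is made to model state
transitions (sleep spindles, movement artifact).

**Seizures** (`seizure_params()`). A biphasic sharp transient (difference
of Gaussians, σ = 8 and 18 ms) is convolved onto a point process whose
instantaneous rate stays inside the onset band (default 2–18 Hz). Spike
peak amplitudes have a hard floor of `amp_factor` (default 3) times the
background RMS, so the amplitude contract holds for every realization.
Phase durations: onset ~ Gamma(shape 6, mean 38 s); MID present with
probability 26/99 and duration 10 + Exp(36) s truncated at 180 s (mean
≈ 46 s); seizure-end spiking at 1–4 Hz, Gamma mean 15 s; PID Gamma mean
20 s at 0.25× background RMS; a 1.5 s multi-spike burst follows with
probability 0.3. Early and late seizures share morphology but differ in
onset duration (means 36 s vs 67 s), giving total durations near 52 s and
83 s respectively — the duration asymmetry the cross-over experiment
probes.

**SWDs** (`swd_params()`). Fundamental f₀ ~ Uniform(7, 12) Hz plus 2nd and
3rd harmonics with fixed weights (1, 0.45, 0.22) and phases, yielding
asymmetric spike-wave cycles without a printed waveform equation to match.
The amplitude envelope is sinusoidal (depth 0.5, period 2.5 s) for the
waxing/waning character, the onset ramp completes within one cycle, and
the offset is abrupt. Durations are 3 + Exp(9) s truncated at 70 s; the
3 s floor is the shortest reported epoch and the 70 s cap is a choice
("tens of seconds" has no stated upper bound).

**Schedules.** Each subject records `intervals_per_day` half-hour
intervals per simulated day. Early seizures are placed only in intervals
at latency ≤ 5 d, late seizures only after 5 d. SWD seconds per interval
follow a linear ramp from 10 s/interval at day 0 to 100 s/interval at day
90 (then flat); the number of SWDs per interval is Poisson with mean
(target seconds)/(closed-form mean duration), so the expected ground-truth
load equals the schedule. Events never span interval boundaries, and
events within an interval are placed disjointly with exponential-spacing
gaps. The four-group design (FPI/Sham × Stress/noStress) assigns late
seizures (PTE) only to `FPI_Stress` subjects by default, deterministically
from `pte_fraction`, so a planted incidence is exact rather than binomial.

**Reproducibility.** One master seed; per-subject streams derive from a
stable string hash of the subject id, and each event carries its own
waveform seed. Schedules and annotations are therefore identical whether
or not voltages are rendered, and any single interval can be re-rendered
on demand (`render_interval()`) instead of holding a cohort in memory.

## Segmentation and scalograms

Records are cut into non-overlapping, contiguous 10 s epochs (half-open
windows); a 0.5 h interval yields exactly 180. Trailing partial epochs are
dropped and logged; automated durations are therefore multiples of 10 s by
construction.

The CWT uses the analytic Morlet wavelet (ω₀ = 6) evaluated by FFT
convolution on a logarithmic grid of 96 frequencies spanning 1–100 Hz
(48 in the scaled test configuration). Morlet is the standard choice when
the source toolchain's wavelet is unspecified, and its localization is
verified in the tests against an FFT oracle at 2, 9, 20, 50 and 80 Hz
(agreement within one grid step). Cone-of-influence regions are retained
rather than masked: 10 s epochs make low-frequency edge distortion
unavoidable, and the classifier sees it identically in training and test.

Rendering maps the magnitude matrix onto a fixed-size RGB raster
(area-average resize, highest frequency at the top row) through a monotone
colormap ("viridis" by default; "jet" and "gray" are available — the
classifier must not depend on the map, so it is configurable and recorded
with the model). Magnitudes are max-normalized **per image** by default;
the alternative global scaling is exposed because the original pipeline
does not state which was used. Per-image normalization makes detection
invariant to overall gain, at the price of amplifying quiet epochs'
texture; the detection threshold absorbs this in practice.

## The classifier

Two independent binary detectors are trained — seizure-vs-background and
SWD-vs-background — matching how the models are trained and applied in the
source workflow; a three-class mode is deliberately not the default. The
labeled pool is split in half, stratified by class, into training and
validation; the background pool is subsampled to the event pool size.

The backbone is a small convolutional network (three 3×3 conv/ReLU/2×2
max-pool stages of 8, 16 and 32 channels, then a softmax pair) implemented
in base-R matrix operations via im2col, trained with Adam (default 30
epochs, lr 3·10⁻³, batch 8, seeded end to end; identical seed and data
reproduce identical weights). At 32–64 px inputs the model has only a few
thousand parameters and trains in seconds on one CPU. A large pretrained
image backbone would slot into the same `training_set → train_detector →
classify_segments` surface, but the pipeline's claims are about the
workflow, not the backbone, and the small network is the configuration the
tests exercise.

**Training examples.** For each ground-truth event the best-covered grid
epochs are taken (up to `max_per_event`), any epoch with at least 2.5 s of
event content qualifying, plus one off-grid window in which the event
occupies only its latter ~6 s (`augment_partial`). Detection runs on a
fixed grid that events rarely align with, so partial occupancy must be
represented in the pool. Background pools mix quiet epochs with **hard
negatives** — epochs of the *other* event class — because a seizure
detector must treat SWDs as background and vice versa; without them the
two detection sets overlap on SWD-rich late intervals and detection-based
PTE classification collapses.

**Detection rule.** An epoch is flagged as an event iff the softmax
posterior of the event class strictly exceeds the threshold, 0.99 by
default, read as a two-class posterior cutoff. The rule is a pure
threshold: lowering it can only enlarge the detected set.

**Correction loop.** `retrain_with_corrections()` appends reviewed false
positives to the background pool and missed events to the event pool and
retrains from the enlarged pools, recording the loop iteration — the
programmatic form of the review-and-retrain step used on the real data.

## Aggregation and timelines

Every flagged epoch contributes its full 10 s to the interval total, so
ten flagged epochs log 100 s; boundary epochs count fully. Maximal blocks
of consecutive flagged epochs form *runs*; an interval with several
separated runs is a possible seizure cluster (`n_runs ≥ 2`). An undetected
MID epoch splits one seizure into two runs; `merge_gap_epochs = 1`
optionally absorbs a single-gap split and is off by default, since ground
truth resolves event identity in the synthetic setting. Timelines index
interval totals by post-implant latency; the early/late boundary is
exactly 5 days (≤ 5 early). A subject is PTE iff it has at least
`threshold_late` (default 1) late detection runs — the inclusive rule
under which even a single spontaneous late seizure counts — and early runs
alone never confer PTE.

## Experiments and statistics

**Cross-over training.** Detectors are trained on early-only, late-only,
and all seizures, then applied to the *same* cached scalograms of every
seizure-bearing interval; per-interval detection durations are tabulated
by training condition and the interval's latency class, and a two-way
fixed-effects ANOVA tests for a training effect. Because single small
cohorts are noisy, the harness (`crossover_replicates()`) repeats the
experiment on independently generated cohorts and the headline parity
claim is asserted on the replicate aggregate: the training main effect
should reject at no more than the chance rate, while early-class durations
stay below late-class durations under every training condition (the
planted duration asymmetry).

**SWD group comparison.** An SWD detector trained on all subjects' SWDs
and one trained only on PTE subjects' SWDs are applied to the same sampled
intervals; per-subject mean detected seconds per interval are summarized
as group mean ± SEM and compared with pooled-variance t tests (injury and
stress contrasts) and a two-way injury × stress ANOVA. Under the
generator's null — identical SWD parameters in all groups — the
calibration study (`swd_null_calibration()`, classifier-free ground-truth
path over ≥ 200 replicate cohorts) checks that the main-effect tests
reject at about the 5% nominal rate.

**Statistical conventions.** The t test is the classic pooled-variance
two-sample test with df = n₁ + n₂ − 2; both tail conventions are always
computed and the flag only selects which is reported (reported one-tailed
p values in this literature are sometimes inconsistent with either
convention, so nothing is matched to a specific printed p). The ANOVA is
`aov`'s sequential-SS fit of `y ~ A * B`; with one observation per cell
the interaction is untestable and an additive fit is reported with the
interaction row flagged. Alpha is fixed at 0.05 and no multiple-testing
correction is applied, matching the source analysis. All outputs are
verified in the tests against brute-force sum-of-squares formulas at
1e-10 relative tolerance.

## Numerical and scaling choices

* Phase durations and event starts are snapped to the sample grid so
  annotations tile waveforms exactly.
* Scheduling overflow: if an interval cannot hold its drawn events, SWDs
  are dropped before seizures; a seizure set that cannot fit at all is an
  error rather than a silent truncation.
* The test suite and acceptance script run at scaled sizes chosen once:
  250 Hz cohorts, 48-frequency scalograms rendered at 32 px, 2–4 subjects
  per group, 60 training epochs (with pools of only a handful of images,
  posteriors need that many optimizer steps to saturate past the 0.99
  threshold). These keep the full pipeline — cohort
  synthesis through replicate ANOVAs — in the minutes range on a single
  CPU core. The package defaults remain 500 Hz / 96 frequencies / 64 px.
* EDF export writes 16-bit samples in 1 s records with a symmetric
  physical range, exact to one quantization step on read-back.

## What passing tests do and do not show

The generator reproduces the *statistical structure* described for the
real data — phase grammar and durations, amplitude ratios, spectral bands,
schedules, group design — but real chronic EEG contains artifact classes
(chewing, scratching, electrode degradation), state-dependent background,
and waveform diversity that no low-parameter simulator reproduces. Passing
the portability, disjointness and parity checks on synthetic cohorts
demonstrates that the pipeline's logic is correct and internally
consistent at the stated effect sizes; it does not certify real-data
accuracy figures.

Known limits of the scaled configuration:

* Epochs in which an event covers only ~6 s carry high event confidence
  but do not all clear the strict 0.99 threshold with the small backbone
  and ~10-image training pools; event-level sensitivity is unaffected
  because events span several epochs. Reproducing reliable partial-epoch
  flagging likely requires the pretrained-backbone regime.
* With unbalanced designs the sequential-SS ANOVA table depends on term
  order (A before B); the experiment harness produces near-balanced
  layouts where this is immaterial.
* Automated durations are epoch-granular by design; the finer
  visual-review durations of the original workflow exist here only as
  ground-truth annotation durations.
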