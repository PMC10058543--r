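---
title: "ERP and CNV analysis of a cued visuomotor task: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERP and CNV analysis of a cued visuomotor task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experimental paradigm and what the package computes

`erpcnv` analyses EEG from a cue–go visuomotor task. On each trial a visual
cue appears for 2000 ms — either a directional arrow (left, up, right, down;
conditions S1–S4, pooled as "DS") or a non-directional square (S5, "nDS") —
followed by an imperative go stimulus to which the participant responds with
a key press. Two families of brain responses are of interest:

* **Event-related potentials (ERPs)**: the stimulus-locked deflections
  P100, P150, N200, P300 and P400, measured as channel-group peaks on
  1100 ms segments (−100 to +1000 ms around cue or go onset, 100 ms
  pre-stimulus baseline).
* **The contingent negative variation (CNV)**: the slow negative ramp that
  builds up between cue and go at the vertex (Cz), summarised by its mean
  value over a late pre-go window and its least-squares slope — an index of
  motor preparation whose steepness should predict reaction time (RT).

Four analyses tie these to behaviour: DS vs nDS contrasts (paired t-maps per
electrode), fast vs slow *subjects* (median split of per-subject mean RTs,
unpaired t-maps), fast vs slow *trials* within subject (mean ± SD/2 split,
paired t-maps), and the Pearson correlation between mean CNV values and RTs
across subjects. All electrode-wise families are corrected with the
Benjamini–Hochberg step-up procedure, reported — as is conventional for this
paradigm — as a *new threshold*: the largest raw p-value still rejected.

Because no public dataset accompanies this paradigm, the package includes a
first-class synthetic-data generator with known ground truth; every
statistical claim the test suite makes is a claim about recovery of that
ground truth, not about any particular participant sample.

## The synthetic generator

`sim_config()` encodes the study design; its defaults *are* the design:
400 pseudorandomised cues (320 directional split equally over the four
directions — the equal split is an assumption, since only the 320/80
aggregate is part of the design — plus 80 non-directional), 64-channel
10–10 montage, 1000 Hz sampling, 2000 ms cue–go interval and 2000 ms
fixation between trials.

**Components.** Each cue and each go stimulus inserts five Gaussian bumps
(the morphology is a modelling choice; nothing in the paradigm prescribes a
shape). Latencies 100/150/200/300/480 ms, Gaussian SDs 15/15/20/35/40 ms,
peak amplitudes +5/+4/−6/+7/+5 µV. Widths were chosen so the bumps stay
resolvable at 512 Hz: the analytic cross-component contamination at each
peak (sum of the other bumps' tails, scaled by their spatial overlap) is
below 0.5 µV, so peak measurements are attributable to their own component.
Spatial profiles are Gaussians on the 2D layout (early components and N200
centred at POz, P300 at CPz, P400 at Cz, widths 0.3–0.4 disc units). The
N200 carries the only condition effect by default — scaling 1.25 for
directional vs 0.75 for non-directional cues — so DS–nDS contrasts should
light up posterior electrodes and nothing else; effect sizes for such
contrasts are free parameters of the generator, not design constants.

**CNV and reaction times.** A linear ramp runs from 500 ms post-cue
(onset is a modelling choice) to go onset, with per-trial slope drawn from
N(−4, 1.5²) µV/s on a Cz-centred profile, resolving back to baseline over
300 ms after go. RTs follow

RT = 450 ms + 20 ms/µV × M + ε, ε ~ N(0, 50² ms), floored at 150 ms,

where M is the mean ramp voltage over 1500–2000 ms implied by the trial's
slope (M = 1.25 s × slope, so σ_M = 1.875 µV). With these constants the
population correlation between M and RT is
20·1.875 / √((20·1.875)² + 50²) = 0.6 exactly, and its sign is positive:
more negative CNV (stronger preparation) means faster responses. The floor
exists for physiological plausibility and clips essentially no mass under
the defaults.

**Noise.** Independent per-channel white (6 µV) plus 1/f (8 µV) noise —
total SD 10 µV — with the 1/f component synthesised by FFT amplitude
shaping of white noise. What the generator deliberately does *not* emulate:
spatially correlated background (volume conduction), eye-blink/EOG and
muscle artifacts, error trials, between-subject amplitude variability of
the components themselves. Passing recovery tests therefore demonstrates
the correctness of the measurement chain under realistic SNR, not
robustness to every pathology of real recordings; in particular the
artifact-rejection stage is exercised by injected amplitude spikes, not by
realistic ocular topographies.

## Preprocessing

The stage order is resample → filter → epoch → reject → baseline.

* **Resampling to 512 Hz** uses Fourier-domain truncation (the `interpft` /
  `scipy.signal.resample` approach): downsampling discards all energy above
  the new Nyquist, i.e. an ideal anti-alias filter, and preserves duration
  to within one sample. Simulated durations are padded to 2/3/5-smooth
  sample counts so these FFTs stay fast.
* **Band-pass 0.2–30 Hz** with a Hamming-window linear-phase FIR applied
  forward and backward (exactly zero phase; the magnitude response is
  squared). Transition widths default to 0.2 Hz at the low edge and 7.5 Hz
  at the high edge; only the corner frequencies are design constants, the
  transitions are ours. The low edge dominates the filter order
  (≈ 3.3·fs/0.2 ≈ 8400 taps at 512 Hz), so recordings shorter than ~17 s
  are rejected with a pointer to widen the transition. A practical worry
  with any high-pass near the CNV band is ramp attenuation; with this
  design the recovered CNV slope on simulated data is biased by under 1%,
  which is why the default was left at the design's corner rather than
  relaxed.
* **Epochs** are half-open windows [tmin, tmax) with
  `round((tmax−tmin)·sfreq)` samples, time 0 at the locking stimulus; the
  half-open convention avoids double-counting the boundary sample. Go-locked
  epochs inherit the condition of the preceding cue.
* **Artifact rejection** replaces interactive inspection and ICA cleaning —
  which are irreproducible in an automated pipeline — with a peak-to-peak
  threshold (100 µV default) per channel. A condition retaining fewer than
  60 epochs (the design's guard) triggers a warning, never an error, so
  scaled-down cohorts still run while the manifest records the shortfall.
* **Baseline correction** subtracts the per-trial, per-channel mean over
  [−100, 0) ms. It is idempotent by construction.

No re-referencing is performed: the reference of the original recordings is
unspecified, so data are used as recorded — a deliberately conservative
choice that any user can override upstream of the pipeline.

## Component measurement

Search windows (P100 70–140, P150 140–190, N200 180–280, P300 250–450,
P400 400–600 ms) bracket the nominal latencies; they are decisions, not
design constants, and are configurable. Channel groups follow the
paradigm's conventions: parietal/occipital electrodes for the early
sensory components, a central/parietal set for P300, Cz/CPz for P400.

Latency is fixed on the *channel-group mean* time course (argmax for
positive, argmin for negative polarity — equivalent to an exhaustive scan,
which the tests verify against an independent enumeration oracle). The
group amplitude is that extremum. Per-electrode amplitudes over the whole
montage are then read as means over latency ± 20 ms, reconciling a single
latency per component with full-scalp amplitude maps. A perfectly flat
group time course returns the first window sample with a low-prominence
flag rather than an arbitrary interior point.

For parameter-recovery checks, the predicted group amplitude is the signed
peak × condition scaling × mean spatial-profile weight over the group
(`predict_group_amplitude()`), since a group mean is necessarily smaller
than the profile-max electrode's peak.

## CNV measurement

The CNV uses its own baseline, 900–1000 ms post-cue (just before the
default ramp onset window used here), and the extracted range 1000–2900 ms
brackets the go stimulus at 2000 ms. Note one bookkeeping consequence: when
the simulated ramp starts at 500 ms, the 900–1000 ms baseline already sits
0.45 s into the ramp, so the *measured* mean CNV is offset from the
generator's model quantity M by a constant factor — an affine change that
leaves correlations and group contrasts untouched.

The mean-value window (1500–2000 ms) and the slope fit window
(1200–2000 ms, ordinary least squares) target the late CNV immediately
preceding the go — the preparation-sensitive segment; neither window is a
design constant and both are configurable. OLS was chosen because "slope"
without an estimator conventionally means the least-squares line; it is
invariant to constant offsets, hence to the baseline choice.

## Splits and statistics

* **Subject split**: strictly below the median of per-subject mean RTs → F,
  strictly above → S, exactly at the median → excluded (logged). With an
  odd number of distinct means this excludes exactly one subject (9/9/1 at
  n = 19). The strict rule is taken literally rather than arbitrarily
  assigning ties.
* **Trial split**: thresholds mean ± 0.5·SD with the n−1 sample SD (the
  small-sample default; the convention is a choice). Under a symmetric RT
  distribution each tail captures Φ(−0.5) ≈ 30.9% of trials. The
  non-directional condition is excluded from trial splits by default —
  80 trials per subject leave too few epochs per tail group — but the
  selector is a parameter.
* **t-maps**: two-tailed paired or pooled-variance unpaired t per electrode
  (Welch available by flag). Electrodes with zero variance yield p = 1 by
  convention instead of NaN, keeping degenerate synthetic maps stable.
* **FDR**: Benjamini–Hochberg step-up, implemented directly from its
  definition (sort, largest k with p(k) ≤ k·α/m; the new threshold is
  p(k)). The family is *all electrodes of one component × one contrast*,
  matching the per-component thresholds conventionally reported; per-table
  or global families would be defensible alternatives and can be had by
  concatenating p-vectors before `fdr_threshold()`. The test suite verifies
  equivalence with both an enumeration oracle and `p.adjust(·, "BH")`.
* **Latency analyses**: one-way ANOVA between condition/group latency
  samples; a two-sample homogeneity t-test flags (never blocks) component ×
  contrast cells where latencies differ, since amplitude maps are then read
  at different latencies.
* **Correlation**: Pearson r with the exact t-transform p on n−2 df.
* **Topographies**: inverse-distance weighting (power 2) on the unit disc,
  exact at electrode sites, masked outside the disc. IDW was preferred to
  spline interpolation to keep the map free of overshoot outside the data
  range; it is a display device, not an inferential step.

## Numerical and scale choices

Problem sizes used by the automated checks: the oracle equivalences run
1000 random waveforms and 1000 random p-vectors; parameter recovery runs
one full-scale subject (400 trials, 64 channels, 1000 Hz → 512 Hz) and
checks every component amplitude to ±1 µV, latency to ±15 ms and CNV slope
to 15%; null calibration runs 500 replicate 19-subject maps; the coupling
study runs 200 cohorts of 50 subjects. The bundled analysis scripts use a
six-subject, 200-trial cohort so the whole chain (simulate → measure →
four analyses) completes in minutes; all of its thresholds that depend on
the epoch budget (the 60-epoch guard) scale accordingly and say so in the
script headers.

Seeds: every stochastic function takes its seed from `sim_config()`; stage
functions derive fixed offsets from it so that stages rerun in isolation
reproduce the integrated run. Identical config + seed gives bit-identical
output.

## Known limitations

* The generator's spatially independent noise makes electrode-wise tests
  slightly conservative relative to real, spatially correlated EEG.
* Component amplitude is constant across subjects (no between-subject
  amplitude variance beyond noise), so unpaired-group power on synthetic
  cohorts is optimistic.
* No ICA, no channel interpolation, no source analysis, no time-frequency
  measures; the CNV is not decomposed into early/late subcomponents.
* EDF support is minimal (16-bit, uniform rate, plain EDF) — enough for
  interchange, not a general EDF+ implementation.
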