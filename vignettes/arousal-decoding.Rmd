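---
title: "Decoding anticipatory arousal from pre-stimulus EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding anticipatory arousal from pre-stimulus EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegarousal)
```

## The problem

During the interval between a warning cue and an expected stimulus, the
brain is not idle: slow anticipatory potentials (of the contingent negative
variation family) and shifts in oscillatory band power reflect the
expectancy and arousal state of the subject. `eegarousal` asks a concrete
question of such pre-stimulus EEG: *can a classifier tell, from the 1000 ms
interstimulus interval alone, whether the upcoming condition belongs to the
high- or low-arousal class?* — and if so, *when* within that second the
discriminative activity lives.

The pipeline is organised as: epoched EEG → feature extraction (two
families, each in a static and a dynamic variant) → feature reduction by
squared point-biserial correlation → repeated cross-validated
classification against a random benchmark → right-tailed t-tests with
Bonferroni-Holm correction and best-accuracy-point detection.

## Feature families

**Spectral features.** Per epoch and channel, the power spectral density is
estimated by Welch's averaged modified periodogram (Hamming windows, 50%
overlap; 250-point window for whole epochs). The PSD is log-transformed —
raw power values are heavily right-skewed — and the bins falling in theta
(4–6 Hz), alpha (6–13 Hz) and beta (13–30 Hz) are summed into band totals
$\theta_{tot}, \alpha_{tot}, \beta_{tot}$. Each channel contributes the
pair $\beta_{tot}/\alpha_{tot}$ (an index of emotional arousal) and
$\theta_{tot}/\beta_{tot}$ (cognitive arousal), so the feature vector has
$2 \times n_{channels}$ entries — 256 at 128 channels.

**Temporal features.** Each channel is band-pass filtered to 0.05–10 Hz
with a zero-phase 2nd-order Butterworth filter, decimated to 20 Hz and
z-scored with its own temporal mean and standard deviation. The
concatenated traces give $20 \times n_{channels}$ features (2560 at 128
channels) capturing slow-wave morphology, the natural substrate of
CNV-like anticipatory activity.

**Dynamic variants.** A 500 ms window slides across the epoch in one-sample
(4 ms) steps, giving 125 segments with onsets 0–0.496 s (a 250-sample epoch
formally admits a 126th window; the convention here drops it to keep the
125-segment count). Temporal features per segment have
$10 \times n_{channels}$ entries; spectral features keep the static
dimensionality but use a 16-point Hamming window zero-padded to 250 FFT
points so the 1 Hz bin grid — and hence the band definitions — are
unchanged.

## Feature reduction and classification

Features are scored by the squared point-biserial correlation $r^2$ with
the binary label (Pearson correlation against a 0/1 vector, squared) and
selected greedily by descending score until 90% of the total score is
covered. For scalp summaries, each channel receives the mean $r^2$ of its
features (2 for spectral, 20 for temporal), normalised to percent of total.

Four classifiers run inside a repeated stratified cross-validation harness
(10 repetitions × 10 folds): LDA with a pseudo-inverse pooled covariance
(so it stays defined when features outnumber instances), a soft-margin SVM
with RBF kernel and $C = 1$, nearest-neighbour with Euclidean distance and
$k = 1$, and a RANDOM benchmark predicting each class with probability 0.5.
Crucially, **selection is recomputed inside every training fold** — the
selected index set never sees test labels. The leakage regression test in
the suite shows what this discipline buys: on null data with 640 features
and 40 epochs, selecting once on the full data inflates apparent accuracy
to roughly 0.8, while the in-fold variant stays at chance.

Per repetition the harness emits one mean accuracy per classifier (a
10 × 4 matrix with the default battery). Dynamically, the same harness runs
per segment; fold assignments are drawn once per repetition and reused
across segments so per-segment accuracies are paired along the time axis,
mirroring the paired comparison design of the statistics.

## Statistics

Each classifier's ten repetition accuracies are compared against the
benchmark's by a pooled-variance two-sample t-test, right-tailed (the
alternative being "better than random"); with 10 + 10 repetitions the
reference distribution is $t(18)$. Dynamically this yields one p-value per
segment, and each classifier's 125-long sequence is Bonferroni-Holm
corrected as its own family. The *best accuracy point* is the left extreme
of the window with the highest significant (corrected $p < 0.05$) accuracy,
ties resolved to the earliest window.

Treating CV repetition accuracies as independent t-test samples is the
field's convention and is knowingly optimistic (repetitions share data);
the package reproduces it rather than fixing it, and the type-I calibration
test applies to the t-test itself, not to the CV-induced dependence.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes: 128
channels, 250 Hz, 1000 ms epochs, two approximately balanced classes
(imbalance configurable within 0.40–0.60). Each channel trace is
$1/f$-coloured noise (spectral shaping of white noise; exponent 1) at a
background amplitude of 40 µV SD — an EEG-like scale, which matters because
the log-transformed band totals are scale-dependent — plus sinusoidal
oscillators with a random phase per epoch and component (defaults: 10 Hz at
20 µV, 20 Hz at 10 µV, all channels). Class effects, carried only by
high-arousal epochs:

* **spectral** — beta-band oscillator amplitudes on a configurable channel
  subset multiplied by a factor, shifting $\beta/\alpha$ upward on exactly
  those channels;
* **temporal** — a linear ramp from an onset time to the epoch end, with
  endpoint expressed in background-SD units (negative for a CNV-like
  negativity), on a configurable "central-parietal" subset. Topography is
  abstract: channel indices, no electrode geometry, since the analysis
  itself never uses geometry.

All randomness flows from one seed; identical configurations are
bit-identical. What the generator does **not** emulate: volume conduction
and realistic covariance between channels, artifacts (blinks, muscle),
non-stationary background rhythms, electrode geometry. Passing tests on
this data therefore certify the *pipeline machinery* — calibration,
localisation, leakage-freedom, determinism — not performance on real
recordings, whose printed accuracies depend on data the desk-scale suite
does not download.

## Numerical choices and conventions

* **Band edges** are half-open $[low, high)$ by default: 6 Hz and 13 Hz
  would otherwise be double-counted by adjacent bands. A closed convention
  is available as a switch. The log base is natural; band *ratios* make any
  global PSD scaling cancel, so only internal consistency matters.
* **Theta/beta orientation**: the second spectral ratio is
  $\theta_{tot}/\beta_{tot}$; an `invert_theta_beta` flag emits
  $\beta_{tot}/\theta_{tot}$ instead, since both orientations circulate in
  the arousal literature.
* **Welch scaling** is one-sided density normalisation with
  Hamming-window power correction (division by $f_s \sum w_n^2$, doubling
  off DC/Nyquist), verified against a brute-force windowed-DFT oracle to
  1e-10 relative tolerance.
* **Zero-phase filtering** is forward–backward application with odd
  reflection padding and steady-state initial conditions (the classic
  `lfilter_zi` construction via the companion matrix). The initial-state
  handling is essential here: a 0.05 Hz high-pass edge rings for seconds,
  and naive zero initial conditions contaminate a 1 s epoch entirely. Even
  so, a slow high-pass edge on a short epoch leaves small residual
  transients — the filter tests therefore measure gains in the settled
  interior of long series, and the dynamic-localisation tests allow the
  ramp effect to smear slightly before its onset (zero-phase filters are
  non-causal by construction).
* **Decimation** from 250 Hz to 20 Hz is a rational (12.5×) rate change:
  the implementation low-pass filters (zero-phase, 8th-order Butterworth
  magnitude, cutoff $0.8 \times f_{out}/2$) and resamples on the exact
  output grid $k/f_{out}$ by interpolation; integer ratios reduce to
  classical keep-every-q-th decimation. In the temporal feature pipeline
  the 0.05–10 Hz band-pass itself is the anti-alias filter (its upper edge
  equals the 20 Hz output Nyquist), so decimation there interpolates the
  filtered trace directly; for dynamic features the epoch is filtered once
  at the full rate and each 125-sample segment is resampled from it,
  avoiding 125-sample filter transients.
* **z-scoring** uses the $n-1$ standard deviation. Flat channels (zero SD)
  are an error naming the channel, as are non-positive PSD bins under the
  log transform and zero band totals in a ratio denominator.
* **SVM kernel width** defaults to the scale heuristic
  $\gamma = 1/(d \cdot \mathrm{Var}(X))$ (configurable, echoed in the run
  log). **kNN ties** go to the lowest training index. **LDA** uses
  empirical class priors. The **RANDOM** benchmark draws inside the same
  CV harness as the real classifiers so its accuracy distribution shares
  their sampling structure.
* **Degenerate t-tests**: zero pooled variance gives $p = 0.5$ at equal
  means, else $p \in \{0, 1\}$ by the sign of the difference.

## Problem sizes in the test suite

The suite exercises every stage at sizes chosen to be statistically
meaningful per check: feature-geometry constants on one 128-channel epoch;
null calibration on five independent 400-epoch, 16-channel datasets
(dataset-level accuracy of a kernel classifier on a single null draw has an
SD of a few percent, so calibration is judged on the mean over datasets);
static effect recovery on 400 epochs/16 channels; dynamic localisation on
100 epochs/8 channels with the kNN + benchmark pair; scalp localisation
over 20 generator seeds; leakage on 40-epoch/640-feature sets. The spectral
and temporal dimensionality identities are checked for several channel
counts, not just 128 — they hold for any.

## Known limitations

* Synthetic channels are independent given the oscillator phases; real EEG
  has strong spatial correlation from volume conduction, which would lower
  the effective feature dimensionality.
* The FIR preprocessing path (0.1–45 Hz, Hamming windowed sinc, order
  16500 at the original sampling rate) is provided for continuous raw
  recordings but is not part of the synthetic pipeline, which starts from
  epoched data; manual steps on real recordings (component inspection,
  bad-channel reconstruction) are out of scope.
* The baseline-correction window for real data is ambiguous when epochs
  begin before the cue; `baseline_correct()` takes the window as an
  explicit argument rather than fixing one.
* Accuracy is the only metric (defensible for near-balanced classes);
  multiclass arousal levels and neural-network classifiers are out of
  scope.
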