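---
title: "Spatiotemporal analysis of movement-related STN synchronization: models and methods"
author: "stnprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stnprop methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`stnprop` analyses movement-related local field potentials (LFPs) recorded
from 8-contact directional DBS leads in the subthalamic nucleus (STN),
together with forearm EMG, cued-movement event annotations, per-contact
MNI-like coordinates and clinical motor scores. The pipeline estimates
baseline-normalized synchronization (ERS/ERD) in five sub-bands — beta
(13–30 Hz), HG (60–90 Hz), FG (110–140 Hz), SHFO (202–298 Hz), FHFO
(302–390 Hz) — localizes per-band spatial "hotspots" by power-weighted
kernel density estimation over contact coordinates, quantifies how those
hotspots propagate between rest, pre-movement and movement, tests
propagation against random-contact surrogate nulls, and relates magnitude
and propagation features to clinical scores by rank correlation and
stagewise least-squares boosting with leave-one-out cross-validation
(LOOCV).

Patient recordings of this kind are not publicly deposited, so the package
ships a first-class synthetic-cohort generator with planted
spectral-spatial ground truth. Every downstream stage is validated against
that ground truth.

# Signal model and preprocessing

Each synthetic hemisphere is a sum of band-limited sources. A source has a
noise carrier (white noise band-pass filtered with a zero-phase FIR
filter; high-frequency STN activity is broadband, so sinusoids would be
unrealistic), a Gaussian spatial gain `exp(-||pos - center||^2 / (2 sigma^2))`
around a center that can move across behavioural states, and a
movement-locked raised-cosine amplitude envelope whose peak fraction is
exactly interpretable (the raised cosine is smooth and compactly
supported). The beta source has polarity −1: its amplitude dips during
movement (ERD), and the dip begins 0.5 s before EMG onset, reflecting the
well-known pre-movement onset of beta desynchronization; without that
lead-in, the 400 ms analysis windows smear the trough systematically late.
EMG is generated *signed* (carrier × envelope plus a baseline muscle tone)
so that the rectification path is exercised end to end.

Preprocessing mirrors standard intraoperative practice: anti-aliased
resampling to 800 Hz, zero-phase 0.5 Hz high-pass and notch filters at
50 Hz harmonics for LFP; 10 Hz high-pass and rectification for EMG. All
filters are forward–backward (zero phase) so that event timing is not
biased; for this reason decimation is implemented as zero-phase FIR
low-pass followed by interpolation onto the target grid rather than a
polyphase scheme (polyphase filtering is causal and would delay onsets).
At 800 Hz the 8th notch harmonic (400 Hz) coincides with Nyquist and
cannot be realized; harmonics are applied up to just below Nyquist, which
matches the analysis band (≤ 395 Hz).

EMG onset detection is a Hodges–Bui-style threshold rule: the 20 ms
moving-average of the rectified EMG must exceed baseline mean + 3 SD for
at least 50 ms, with the baseline taken from the pre-cue window
(−1.5 to −0.2 s). Two refinements reduce the bias inherent in
thresholding a smooth envelope: the crossing is first walked back to the
0.5 SD level, and then the square root of the above-baseline activity —
locally linear in time for a smoothly (quadratically) rising burst — is
extrapolated to its root. The offset applies the mirror-image procedure to
the descending phase. On generator bursts at realistic SNR the mean
absolute onset error is ~20–25 ms; this is an envelope-shape limit, not a
sampling limit. Trials without a qualifying burst are flagged as
artifacts; trials whose peak LFP amplitude is a robust outlier
(median/MAD z > 5 across trials, per channel) are rejected; segmentation
spans −3 s before onset to 2 s after offset.

The pre-movement window is taken literally as (−1.5, −0.2) s before the
cue even though it is sometimes described as a 1-s window; the interval is
exposed in `preproc_config()`. The intertrial interval defaults to 8 s
(configurable), where sources differ between 8 and ~9 s.

# Spectral estimation and ERS

Multitaper spectrograms use DPSS tapers computed from the symmetric
tridiagonal form of the concentration problem (no external multitaper
dependency). Two ranges are used: 10–50 Hz with 400 ms windows and ±2 Hz
half-bandwidth (2.5 Hz grid), and 50–395 Hz with 200 ms windows and
±10 Hz half-bandwidth (5 Hz grid), both stepped by 10 ms. The taper count
is `max(1, floor(2 TW) − 1)`; note that the low-range parameters give
TW = 0.8, which cannot support two standard DPSS tapers, so the taper
count floors at one — a documented property of that window/bandwidth
combination. Power is calibrated so that the one-sided spectrum sums to
the signal variance (checked against a periodogram oracle).

ERS is the z-score of band power against the (−3, −2) s pre-onset
baseline, with baseline moments pooled across all kept trials of a
hemisphere (per-trial z-scoring is possible in principle; pooling is the
package default because 1-s baselines are short relative to the estimator
variance at 2.5 Hz resolution). Movement-period series are linearly
interpolated onto an inclusive 0–100% grid in 5% steps (21 points), which
makes trials of different durations averageable; the AUC summary is the
plain sum over the 21 grid values. Rest and pre-movement states are
summarized in 100 ms epochs. The EMG timing reference is the trial-mean of
the 100 ms moving-average envelope of the rectified EMG on the same
percent grid (the raw rectified signal is far too noisy for a meaningful
argmax).

Per-hemisphere peak fractions are grid argmaxes. Under low SNR a
per-hemisphere argmax of a flat-topped curve is biased toward the flatter
flank; group-level timing statements in the validation suite are therefore
made on cohort-mean curves, whose argmax recovers the planted envelope
peaks to within one 5% bin. The cross-correlation between percent-grid
series is computed per paired unit and averaged, with the convention that
a positive lag means the first series leads; the summary score (mean
correlation within ±3 bins of lag 0) is standardized against a null
formed by shuffling the unit pairing, and significance uses the
permutation p-value. The shuffling null is the package's construction —
the underlying "standardized difference" statistic is not otherwise
defined operationally.

# Hotspots, propagation, surrogates

For each band and state/time-bin, the inside-STN contact with the highest
event-related power is selected per hemisphere (ties, which can only occur
with degenerate power patterns, go to the lowest contact id and are
deterministic). The hotspot is the per-axis argmax of a weighted Gaussian
KDE over the selected contacts' coordinates, with weights equal to the
state-normalized power (weights are normalized to sum to one within each
state/bin so that overall power scale cannot move a hotspot). "Per axis"
means three 1-D KDEs — this matches how per-axis density profiles are
usually displayed — and a joint 3-D product-kernel mode is available as an
option. The bandwidth follows a per-axis weighted Silverman rule floored
at 0.3 mm (contact spacing would otherwise drive the bandwidth below the
coordinate grid); the density is evaluated on a 0.05 mm grid spanning the
data range ± 3 bandwidths, and the discrete argmax is refined by a
parabolic vertex fit through the argmax and its neighbours, giving peak
positions accurate to ~10⁻³ mm against a brute-force grid search of the
explicit mixture.

Propagation is the difference between a bin/state hotspot and a reference
hotspot (pre-movement by default; rest optionally), reported per axis and
as Euclidean distance. Significance uses random-contact surrogates: each
surrogate replaces every hemisphere's selected contact with a uniformly
random inside-STN contact, *keeping the observed selected power as the
weight*, and recomputes the hotspot and its difference from the reference.
Keeping the observed weights (rather than redrawing weight–contact pairs)
is a deliberate choice: it isolates the spatial claim being tested. The
two-tailed 5% decision is implemented through the permutation p-value
`p = (1 + #{null at least as extreme}) / (n + 1)` per tail, the
order-statistic form of the 2.5/97.5 percentile band; under exchangeable
contacts this is exactly calibrated, and the package verifies ~5%
rejection on 400 null cohorts. FDR (Benjamini–Hochberg throughout) is
applied across movement bins per axis.

Volatility is the percentage of time-bin transitions at which the
maximal-power inside contact changes; it depends only on power ranks, so
it is invariant under strictly monotone transforms, and under i.i.d.
powers over 8 contacts its expectation is exactly 100 × (1 − 1/8) = 87.5%.
Per-hemisphere propagation (the clinical feature) is the displacement of
the power-weighted centroid of inside-contact coordinates between states —
the individual-level analogue of the group hotspot shift, chosen for
robustness because a single-contact jump is hypersensitive to rank flips.
The magnitude–propagation ratio divides AUC and propagation by their
cohort means (across hemispheres and bands) and compares the ratio to 1 by
signed-rank per band.

State-level hotspots average power over a state's epochs before the KDE
(rather than averaging epoch-level hotspot positions); this weighs every
epoch's evidence at the selection stage and is the package's choice where
both readings are defensible.

# Clinical stage

The feature matrix has 4 bands × {power, propagation} × 3 transitions
(rest→premove, rest→move, premove→move) = 24 features per hemisphere.
Correlation uses Spearman's rho with a 5000-resample percentile bootstrap
CI and BH-FDR across the grid per clinical target. The ranking model is
stagewise least-squares boosting: F₀ is the training mean and each cycle
adds a shrunken depth-2 regression tree fit to the residuals; training MSE
is provably non-increasing for learning rates below 2. Feature importance
is the total squared-error (deviance) reduction attributed to splits on
each feature, summed over all trees. LOOCV selects the learning rate
(0.3, 0.45, 0.6) and cycle count (30, 75, 120, 200) per fold by inner
cross-validation on the training fold only — evaluated cheaply from staged
predictions of a single maximal-cycle fit per learning rate, which is
selection-equivalent to refitting every grid cell. Honesty is verified by
a poisoning test: perturbing one row's response does not change that row's
held-out prediction. Importance significance uses 1000 label-shuffle
refits (p = fraction of null importances at or above the observed, BH-FDR
across features); top-rank probabilities are estimated over 100 bootstrap
refits, and the band / feature-type / transition group probabilities each
sum to one by construction.

The comparison battery runs the across-band repeated-measures ANOVA on
AUC as a two-way subject-blocked decomposition (`auc ~ band + hemisphere`)
with Tukey's post hoc on the band effect — sphericity correction is not
applied, which is documented; timing deltas use paired signed-rank tests;
all families are BH-FDR corrected.

# The synthetic cohort as study conditions

Defaults mirror the intraoperative setting: 63 hemispheres, 18 trials,
2048 Hz raw sampling, ~93 s rest block, 8 s intertrial interval, cue→onset
delay 0.43 ± 0.18 s, movement duration 1.54 ± 0.59 s, EMG burst peaking at
29% of the movement, band envelope peaks at 44/48/44/43% (HG/FG/SHFO/FHFO)
with the beta trough at 14%, and band-specific movement shifts: HG
+1.18 mm superior, FG +0.84 mm superior, SHFO 0.4 mm inferior plus a
0.4 mm random-direction x–z component, FHFO a 0.5 mm random-direction x–z
component (propagation without a consistent group direction). Source
amplitudes make beta the dominant rest rhythm and rank movement ERS
magnitude HG > SHFO/FHFO > FG, consistent with the qualitative ordering
such recordings show. Per-hemisphere propagation magnitudes vary through
independent per-band scale factors (mean 1, SD 0.35, truncated at 0.2);
independence across bands is essential — a shared factor would make all
band propagations perfectly collinear and clinical band-specificity
untestable.

Clinical scores are linear in the planted per-band propagation magnitudes
plus Gaussian noise: percentage levodopa improvement uses coefficients
(0, −20, −19, −34) %/mm for (HG, FG, SHFO, FHFO) with intercept 107% and
noise SD 8.5%, clipped to [0, 100]. The coefficients are sized so each
affected band's marginal Spearman correlation is ≈ −0.45 — the magnitude
such clinico-electrophysiological correlations typically reach — with a
population mean improvement of ~63%; MDS-UPDRS III OFF scores are drawn on
the 0–132 scale (39.4 ± 11.4) independent of propagation, and the ON score
is derived from the improvement.

A weights-level generator (`simulate_power_cohort()`) draws per-contact
band powers directly from the same spatial-gain model (power ∝ squared
gain × squared state amplitude, multiplicative log-normal noise with
sdlog 0.4), skipping waveform synthesis. The spatial statistics are
calibrated at this level — 400-replicate surrogate nulls and 20 × 63
hemisphere recovery runs would be unreasonable through full waveform
synthesis — while the signal-level path is validated end to end on
smaller cohorts (8–12 hemispheres); both paths share the geometry, gain
and envelope model, and the validation suite states each run's problem
size.

What the generator does *not* emulate: volume conduction and common-mode
structure beyond a global reference, non-stationary tremor or artifact
regimes (artifacts are planted as amplitude outliers only), phase–amplitude
coupling, spike activity, and nonlinear warps of electrode coordinates
(left hemispheres are mirrored by negating x, with an optional
user-supplied affine). Passing tests therefore demonstrate that the
implementation recovers known structure under this model, not that the
model captures every property of patient recordings.

# Numerical and degenerate-input choices

* KDE: all-zero or negative weights error; a single unique coordinate is
  returned directly; per-axis peaks always lie within the contributing
  coordinate range.
* z-scoring: channels with zero baseline variance are flagged, not
  silently propagated.
* Movement normalization requires at least 2 frames inside the movement;
  shorter movements error.
* Surrogate tests warn below 100 draws (unstable percentiles).
* Boosting rejects non-finite inputs; constant responses yield constant
  predictions and all-zero importances.
* Seeds: every stochastic stage takes an explicit seed; cohort members,
  folds and stages derive sub-seeds from the master seed with a counter
  scheme (kept below 2³¹), so any stage can be re-run independently and
  reproducibly.

# Known limitations

Per-hemisphere argmax timing is biased late at low SNR (documented above);
the EMG onset detector carries an envelope-shape-limited ~20 ms error;
hotspot shift estimates are attenuated (~20%) by selection noise and the
finite contact grid — the planted +1.18 mm HG shift is recovered at
≈ 0.9–1.0 mm on average at 63 hemispheres; and the repeated-measures
ANOVA does not apply sphericity correction. The EDF signal format is not
read or written — bundles use a TSV/JSON layout chosen to be diffable and
language-neutral.
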