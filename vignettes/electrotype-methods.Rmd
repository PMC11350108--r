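---
title: "Epicardial electrotype analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epicardial electrotype analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`epimapr` implements the post-reconstruction half of an exercise ECGi study
of hypertrophic cardiomyopathy (HCM): given unipolar electrograms at
epicardial locations on a triangulated surface, it conditions the signals,
averages beats, delineates QRS and T waves, extracts activation and
repolarization markers, summarizes them into whole-heart metrics, compares
study groups non-parametrically, and fits a cross-validated logistic model
separating ventricular-fibrillation (VF) survivors from other HCM patients.
The inverse reconstruction itself (body-surface potentials to epicardial
electrograms) is out of scope; the package starts from per-node traces.

Because the clinical recordings behind such studies are not public, the
package ships a seeded synthetic-cohort generator whose group-level
distributions are transcribed from published cohort statistics, so that
every stage of the chain — including the full waveform-level pipeline — is
testable end to end.

# Markers and whole-heart metrics

Per node, on the signal-averaged electrogram and relative to the subject's
*global QRS start* (the earliest detected QRS onset across accepted nodes):

* **LAT** (local activation time): time of the minimum of the smoothed
  dV/dt inside the delineated QRS window (steepest negative slope).
* **LRT** (local repolarization time): time of the maximum of the smoothed
  dV/dt inside the T window (steepest positive slope), identically defined
  for upright and inverted T waves (the Wyatt convention).
* **ARI** = LRT − LAT, a surrogate of local action-potential duration;
  non-positive values flag the node as rejected.

The derivative is a central difference smoothed with a centered moving
average (default 10 ms, forced to an odd sample count so extrema are not
shifted), and the discrete extremum is refined to sub-sample precision with
a local least-squares parabola (vertex clamped to ±2 samples). Without the
refinement, one-sample quantization of marker times produces spurious
2–3 ms discontinuities between sub-millimetre mesh neighbours that inflate
the spatial gradient metric several-fold.

Whole-heart summaries per subject and phase, over accepted nodes:

* **mean** LAT and ARI;
* **dispersion**: the central 95% range (97.5th − 2.5th percentile,
  linear-interpolation percentiles, R type 7);
* **gradient**: the mean over nodes of the magnitude of a least-squares
  plane fitted to the marker values over each node's 5-mm Euclidean
  neighbourhood (the node plus all nodes within 5 mm; nodes with fewer than
  3 neighbourhood points are excluded and counted). Rank-deficient
  neighbourhood geometries are handled by truncating singular values below
  10% of the largest, which reduces the fit to the directional derivative
  along the populated directions. The plane fit is exact on linear fields,
  which anchors its unit tests; a range-over-span alternative
  (`gradient_method = "range"`) is retained for sensitivity analysis.

Euclidean rather than geodesic distance defines the 5-mm neighbourhood: at
this radius on a convex epicardial shell the two differ negligibly, and
Euclidean distance needs no path algorithm.

# Processing chain

1. **Baseline removal**: zero-phase (forward–backward) 2nd-order
   Butterworth high-pass, cutoff 0.5 Hz, reflection-padded. Zero phase
   preserves dV/dt timing; 0.25-Hz respiratory-scale wander is attenuated
   by more than 20 dB.
2. **Beat anchoring on a composite**: beats are located on the cross-node
   RMS composite so that the averaging windows are common to all nodes and
   inter-node timing is preserved. Slope-peak positions on a composite are
   ambiguous (the pooled T band can rival the activation band diluted over
   the activation spread), so anchors are placed at the ends of the long
   quiet stretches of a 30-ms |dV/dt| envelope — each cycle has exactly one
   diastole — phase-clustered modulo the RR period estimated from the raw
   composite autocorrelation. If the anchoring nevertheless rotates the
   window into the wrong part of the cycle, the per-node T waves land
   before their QRS and most nodes fail delineation; the pipeline detects
   this (more than half the map rejected) and retries on the alternate
   phase cluster.
3. **Template selection**: the beat maximizing the mean normalized
   cross-correlation against all other beats; a manual override is kept for
   interactive use. Pure amplitude changes are invisible to normalized
   cross-correlation by construction; the automatic choice discriminates
   morphology.
4. **ROI matching**: normalized cross-correlation of the template at every
   lag; up to 10 windows above a 0.8 correlation floor, separated by at
   least 60% of the median RR; shortfalls are recorded, not fatal.
5. **Signal averaging**: pointwise mean over the aligned windows. With the
   common composite windows the per-window lags are fixed at zero, which
   preserves inter-node timing exactly; per-trace alignment by maximal
   cross-correlation is available for standalone use.
6. **Delineation** (deterministic stand-in for a pretrained network, same
   output contract): QRS = the contiguous region where the smoothed
   |dV/dt| exceeds 0.2 of its maximum (containing that maximum), expanded
   to the nearest slope sign changes, with the expansion also stopping
   below 5% of the maximum so it cannot drift through noise; T = among
   post-QRS suprathreshold regions (0.15 of the post-QRS maximum; sub-8-ms
   blips dropped; regions separated by under 40 ms merged across the
   zero-slope apex), the region containing the post-QRS |dV/dt| maximum.
   Two structural guards matter in practice: a candidate T region must
   have a *biphasic* smoothed derivative (a T wave has an apex; the
   terminal QRS recovery does not), and still-rising energy truncated by
   the window end is discarded as the beginning of the next beat's QRS.
   The mean |dV/dt| of additive noise does not average away, so a
   lower-quartile noise floor is subtracted before thresholding.
7. **Quality rejection**: nodes are rejected when the T peak-to-peak is
   below 5% of the QRS peak-to-peak, when the T segment has three or more
   deflections (local extrema with prominence at least 10% of the segment
   peak-to-peak), or when no T region is found. The 5% and 10% figures are
   declared stand-ins — the study software's exact criteria are not
   published — and are exposed in the configuration.

# Synthetic cohorts

## Group presets

`inst/extdata/group_presets.yaml` holds, per group (HCM VF survivors, HCM
without VF, pooled HCM, pooled normal-heart controls) and exercise phase
(peak, recovery), the mean and SD of each whole-heart measure, heart rates,
pattern prevalences used as injection probabilities, and the inter-measure
correlation structure. Published values are transcribed directly; pooled-HCM
peak mean ARI (227.2 ± 19.1 ms) and the pooled activation gradient
(0.40 ± 0.157 ms/mm) are n-weighted pools of the published subgroup values.
Quantities never published — ARI dispersions for all groups, control-group
gradient and ARI SDs, recovery-phase gradients — are package choices flagged
`# chosen` in the file: ARI dispersions sit at 74–92 ms (scaled so that the
published ARI gradients are geometrically representable), and "similar
between groups" comparisons use near-equal means.

The subject-level correlation structure is assembled from within-phase
pairs, cross-phase same-measure values (0.93 for mean activation time and
0.72 for mean ARI, both published; 0.6 otherwise), scaled cross-phase
cross-measure entries, and four explicit overrides for the model-candidate
measures, then projected to a positive-definite correlation matrix by
eigenvalue clipping (floor 1e-4) — a perturbation under 0.01 per entry. The
published record constrains the candidate correlations only to a band
(0.21–0.72) plus the 0.93 pair; within that freedom the overrides were
chosen so that the strongly related peak/recovery ARI pair is near the top
of the band and cross-domain pairs are weak. The between-measure correlation
of 0.3 for recovery mean AT and mean ARI follows the published band.

Draws are multivariate normal with physical floors (a measure cannot be
negative) and a gradient-to-dispersion ratio floor of 0.004/mm — the finest
ratio a 200-node surface can represent (see below). Both floors sit well
below two SDs for every preset, so cohort-level means are essentially
unaffected.

## Truth fields on the mesh

The default fixture surface is a prolate spheroid (90 mm apex–base, 28 mm
diameter, 200 nodes as 22 rings × 9 segments plus poles) with rings
redistributed toward the poles. The redistribution is deliberate: the mean
5-mm gradient of a field with dispersion D on a uniformly sampled 200-node
surface cannot fall below roughly D/140 per mm, because any apico-basal
transition is straddled by some ring pair. Widening the equatorial ring gap
beyond the 5-mm search radius lets steep transitions cross a band that the
gradient metric does not sample, which makes the low published
gradient-to-dispersion ratios representable. About 90 mid-latitude nodes
have fewer than two neighbours within 5 mm and are excluded from gradient
means — identically during field calibration and extraction, so the two
sides stay consistent.

Each subject's activation field is a mixture of an apico-basal sigmoid ramp
and a smooth axial Gaussian-process (default correlation length 35 mm for
activation, 8 mm for ARI), plus optional pattern components. Because
dispersion and gradient are both positively homogeneous in the field, the
calibration solves the ramp/noise mixing fraction so the
gradient-to-dispersion ratio matches the subject's target (root-finding on
the mixture), then scales and shifts so dispersion and mean match exactly,
as computed by the same metric implementations used in extraction. When the
ratio is out of reach the calibration steepens the ramp, adjusts the noise
correlation length, shrinks the patch, or, as a last resort, blends in an
azimuthal harmonic that varies faster around the circumference than the
5-mm radius resolves (dispersion without measured gradient), tapered flat
across the mid-heart so its rolloff does not leak into the gradient.
Calibration errors after 50 adjustment passes report achieved versus target.

Pattern components mirror the qualitative HCM map features: late-activation
patches are raised-cosine bumps (22 mm radius, 1.1 × dispersion height)
centred where the footprint covers at least six nodes and mostly
gradient-excluded ones (so the bump survives the ratio calibration);
apical ARI prolongation is modelled as a reversal of the apico-basal ARI
trend; T-wave polarity is flipped over the apical third or over an isolated
mid-basal patch. Injection probabilities default to the published pattern
prevalences. The published prevalences themselves are observer-dependent
and are not reproduced as quantities.

## Waveforms

Each node's beat is an rS-type QRS plus a Gaussian monophasic T lobe
(SD = width/6, default width 140 ms, amplitude 0.45 of the 1 mV QRS).
The QRS is built from tangent-continuous segments — half-cosine R upstroke,
flat plateau, slow linear descent, steep cosine downstroke (half-width
12 ms), and a 100-ms S recovery — with the downstroke slope profile
symmetric about its centre, so the steepest negative slope falls exactly at
the configured activation time for both the raw and the smoothed
derivative. The T wave's steepest positive slope falls exactly at the
configured repolarization time (one SD before the apex when upright, one SD
after when inverted). Both placements are verified at generation by
numerical differentiation.

The slow-descent length decouples the delay from the detectable QRS onset
to the steepest slope from the QRS footprint after the slope. The
subject-level synthesizer solves it so that the *detected* global QRS start
coincides with the map's time zero: a clean-beat solve first, then a
fine-tune against a direct mini-simulation of the detected minimum onset
over the ten earliest activations with the post-averaging noise level
(the detected global start is an extreme value over noisy onsets, which a
single-beat calibration cannot capture). Maps whose earliest activation
exceeds the largest achievable onset lag (~45 ms) get an early-breakthrough
relief: the four lowest-valued gradient-excluded nodes are pulled down to
~40 ms, which leaves the type-7 central-95% range and the gradient metric
exactly unchanged. The relative S-recovery and T slopes are fixed so that
the recovery slope stays above the QRS region threshold (the delineator
sees one complex) but below the T slope (it can never win the Wyatt
argmax).

Strips hold 10 beats with 3% RR jitter. The mean RR is the subject's
sampled heart rate (per-group, per-phase, from the published tables)
floored so that the analysis window around each beat covers the latest
T wave before the next beat's QRS energy begins; at peak exercise this
clamps the effective rate of long-repolarization subjects to roughly
100–120 bpm. The heart rate feeds nothing downstream that is summarized,
so the clamp only affects strip geometry.

Additive noise defaults to 2% of the QRS amplitude per trace, of which 95%
is a common trace shared by all nodes of a subject and 5% is
node-independent. Fully node-independent noise at the 2% level would give
Wyatt repolarization jitter near 14 ms per node, inflating the 5-mm
gradient several-fold beyond anything compatible with the published
gradient statistics; regularized inverse reconstructions have spatially
smooth noise, which the common component emulates while keeping the
per-trace noise level (and the √10 benefit of averaging ten beats) intact.
Baseline wander is a 0.25-Hz sinusoid at 30% of the QRS amplitude with a
random phase per node.

## What the generator does and does not emulate

It emulates: group-level distributions and correlations of the six
whole-heart measures; per-map spatial structure sufficient to match mean,
central-95% dispersion and mean 5-mm gradient simultaneously; the
qualitative HCM patterns; multi-beat strips with wander and noise whose
processing is non-trivial (all chain stages are exercised and can fail).
It does not emulate: real activation wavefront physics (fields are
calibrated mixtures, and bimodal apico-basal profiles are accepted when the
published gradient-to-dispersion ratios demand them); inverse-reconstruction
artefacts beyond spatially smooth noise; ectopy or beat-to-beat
morphology change; node-level ARI rate adaptation. Passing end-to-end tests
therefore demonstrates that the chain recovers what the printed summary
statistics constrain — not that it would behave identically on clinical
maps.

At default noise the pipeline recovers whole-heart mean activation time to
within ±2 ms of truth (the residual is the extreme-value behaviour of the
detected global QRS start on strongly bimodal maps), dispersion and mean
ARI to within ~1%, and the activation gradient to within ~0.03 ms/mm.

# Statistics and the risk model

Group comparisons are Wilcoxon rank-sum (exact for small untied samples,
normal approximation with tie and continuity correction otherwise) and
Kruskal–Wallis for three or more groups; effect sizes for proportions use
Cohen's h, and the "proportions by t test" phrasing in the source
literature is implemented as a two-proportion z test on arcsine-transformed
proportions with h reported alongside. No multiple-testing correction is
applied, matching the emulated analysis. On the published worked example
(4/20 vs 2/17) the arcsine formula gives h = 0.2271; the published figure
prints as 0.22.

The logistic model is authored in the package: Newton–Raphson on the
binomial log-likelihood (score norm < 1e-8 or 50 iterations), Wald
standard errors from the observed information, likelihood-ratio p against
the intercept-only model, odds ratios per original unit by dividing scaled
coefficients by the training SDs. Complete separation (|scaled coefficient|
above 15) raises an error in strict mode and caps the iteration inside
cross-validation, where separated training folds are legitimate.
Candidate screening uses univariate rank-sum p < 0.05; collinear pairs
(|Pearson r| at or above 0.9) drop the peak-phase member; backward stepwise
selection removes the worst Wald p above 0.15 until all survive.

Cross-validation is stratified 5-fold (per-class fold sizes within one),
with scaling parameters learned on the training folds only — a deliberate
strengthening over the emulated analysis, which does not state its
protocol. Held-out predictions are pooled for the headline ROC/AUC, the
Youden operating point and balanced accuracy at the 0.5 threshold;
per-repeat metrics give percentile intervals. Pooling (rather than
averaging per-fold metrics) is the declared reference; fold-level metrics
are available from the per-repeat table.

Two properties of this design are worth stating plainly, because they
determine which published quantities reproduce. First, under the published
group means and SDs with an inter-measure correlation of 0.3, the
out-of-sample discrimination of the 2-variable model is AUC ≈ 0.72 —
essentially at the lower bound of the published interval — and the
balanced accuracy at the fixed 0.5 threshold is ≈ 0.67. The published
Youden point (sensitivity 78.6%, specificity 79.8%, J = 0.58) is not
attainable by any pooled out-of-sample ROC with AUC 0.76 (a binormal ROC
at that AUC has J ≈ 0.38); such figures arise from per-fold or in-sample
operating-point selection on ~7-observation held-out sets. Second, under
the same distributions the modal backward-stepwise outcome over repeated
cohorts is the single-variable recovery-ARI model: retaining recovery mean
AT requires its Wald p to clear 0.15, which happens in under half of
cohorts (the emulated analysis observed p ≈ 0.10 on its single dataset).
The package reports what its procedures produce; the tests that assert the
published figures for these quantities are expected to fail and say so.
The fitted odds ratios (≈1.09 per ms of mean AT, ≈1.03 per ms of mean ARI)
and the AUC do reproduce within their published intervals.

# Problem sizes

The shipped analyses use a 200-node mesh, 10-beat strips at 1 kHz, cohorts
of 37/32/17 subjects for the waveform-level group metrics, 20 seeded
cohorts × 5 CV repeats for the model metrics (60 cohorts in the test
suite, where Monte Carlo error must be small against the published
intervals), 200 seeded cohorts for the stepwise-selection census, and 500
null simulations for the likelihood-ratio calibration check. One full
waveform subject simulates and processes in about 1.5 s.

# Known limitations

* The delineator is a deterministic slope-threshold rule, not the
  pretrained network it stands in for; its thresholds (0.2 QRS, 0.15 T,
  5% T amplitude, 10% deflection prominence) are declared assumptions.
* Rate correction uses Bazett's formula as a declared stand-in; the
  emulated analysis never states its formula.
* The ARI gradient is the least robust whole-heart metric: repolarization
  timing noise enters it quadratically, and extraction can deviate by
  ~5–10% where activation and repolarization fields are rough.
* Metric-level and waveform-level cohort paths agree to within extraction
  noise for means and dispersions; the gradient agreement depends on the
  spatial noise model as described above.
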