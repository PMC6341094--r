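---
title: "Methods: synthetic ofMRI/ephys pipeline for the DRN serotonin circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ofMRI/ephys pipeline for the DRN serotonin circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raphemap)
```

raphemap implements, as one tested pipeline, the computational chain of a
combined optogenetic-fMRI (ofMRI) and electrophysiology analysis of the
dorsal raphe nucleus (DRN) serotonin system: synthetic data generation with
known ground truth, spike detection and sorting, wavelet LFP analysis,
block-design hemodynamic GLM fitting, permutation-based group inference,
electro-vascular coupling, and structure-function correlation. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic generators do and do not emulate.

## Stimulation protocol and sampling grid

Photostimulation follows a block design: 6 trains of 20 s ON (20 Hz, 5 ms
pulses) separated by 40 s OFF in the 12 min short-block protocol, or 160 s
OFF in the 24 min long-block protocol. One fMRI volume is acquired every
2 s, so a 20 s block spans exactly 10 volumes. The pre-stimulus lead-in is a free
parameter of the acquisition, and we fixed it at 60 s — this gives at least 30 pre-stimulus volumes for percent-change
normalisation, and every preset uses it consistently.

## Hemodynamic model

The response to a stimulation block is a boxcar convolved with a
single-gamma hemodynamic response function (HRF)

$$h(t) \propto t^{\,a-1} e^{-t/s}, \qquad a = 6,\ s = 0.6\ \mathrm{s},$$

peak-normalised to 1, with time-to-peak $(a-1)s = 3$ s as reported for
rodent cerebral-blood-volume (CBV) responses. Activity regressors are
built on a 0.1 s grid, convolved, bin-averaged onto the volume grid and
peak-normalised, so a regression coefficient reads directly in percent
signal change. The synthetic generator and the fitter share this kernel
through one code path: on noiseless matched-HRF data, parameter recovery
is an ordinary-least-squares identity (exact to ~1e-10), which the test
suite asserts. Robustness to a *mismatched* HRF is a property to be
tested, not a promise of the design.

CBV acquisitions use an intravascular iron-oxide contrast agent, so a CBV
increase *lowers* the raw signal. The generator produces raw signals as

$$\mathrm{raw}(t) = B\,(1 + \delta t)\,(1 - r(t)/100) + \varepsilon(t),$$

with baseline $B$ (1000 a.u.), clearance drift $\delta$ (default
-0.1 %/min — iron-oxide blood half-lives are long relative to a 12 min
scan, so the within-scan drift is small but non-zero), signed percent
response $r(t)$, and white Gaussian noise of sd 0.3% per volume (an AR(1)
option exists). Preprocessing then mirrors the analysis convention: linear
detrend with the slope fitted on non-stimulation volumes only, percent
change against the pre-first-block baseline mean, and sign inversion for
CBV contrast — the generator's sign convention deliberately exercises the
inversion step rather than bypassing it. The DRN responds positively;
projection areas respond negatively (their preprocessed responses are
negative-going), and "response amplitude" in all summaries refers to the
magnitude.

Polynomial drift regressors default to order 2 (linear plus quadratic,
orthogonal polynomials plus a constant). The suite verifies that explicit
linear detrending and a linear drift column in the design agree to within
1% on generated data.

## Generator presets as study conditions

The presets encode the experimental conditions the pipeline is tested
against, and they are fixed:

* `adaptation_short` — projection-area block amplitudes decline linearly
  from 2.6% (block 1) to 1.7% (block 6); DRN amplitude constant; noise sd
  0.3% per volume; no between-subject amplitude variability (this
  experiment is defined at the volume-noise level).
* `control` — flat 2% projection / +1.5% DRN amplitudes; between-subject
  amplitude variability 10% (lognormal), a realistic cohort spread.
* `restraint` — control with every amplitude multiplied by 0.5: a globally
  blunted response whose *relative* spatial pattern (functional
  connectivity) is unchanged. DRN-normalised connectivity is therefore
  bit-for-bit identical to control on noiseless data, and the suite
  asserts this scale-invariance end to end.
* `fluoxetine` — control, with the post-drug scans (2 and 3 of each
  session) scaled by 1.5 in prefrontal, cingulate, amygdalar and striatal
  ROIs only. The session contrast (mean of post-drug scans minus pre-drug
  scan) isolates exactly those ROIs.

Session handling follows the study design: three scans per session;
fluoxetine sessions are summarised as `mean(scan2, scan3) - scan1`,
restraint and control sessions as the mean of all three scans.

## Electrophysiology generator

The probe generator is phenomenological — no biophysical neuron or balloon
models. Each channel carries white noise (8 µV), a delta-band oscillation
(2.2 Hz, 60 µV) whose amplitude is multiplied by a suppression factor
(default 0.5) during stimulation epochs shifted by a 5 s lag (the reported
latency of LFP power changes), a small unmodulated gamma component, and
spikes. Network bursts are an inhomogeneous Poisson process (0.4 /s
baseline) thinned to half rate in the same lag-shifted epochs; each burst
adds a packet of spikes (~6 per unit over 100 ms) across units. Tonic
spiking is Poisson (10 Hz per unit) with an enforced 2 ms refractory.
Units take one of three waveform families (narrow, broad, triphasic), and
alternate units appear on two adjacent channels at a fixed 0.6 amplitude
ratio to emulate stereotrode observability.

## Spike detection, sorting, typing

Spikes are detected on the MUA band (0.3–3 kHz zero-phase Butterworth) as
excursions below −5 standard deviations of the noise. The noise sd is
estimated robustly as `median(|x|)/0.6745` because the raw sd is inflated
by the spikes themselves. After each detection, a dead time of one snippet
window (1.6 ms, 40 samples at 25 kHz) prevents multiphasic waveforms from
being counted twice. Events on adjacent channels within ±0.4 ms are
treated as one two-channel event; sorting handles stereotrode events
first and the residual single-channel events second, and the coincidence
window is configurable.

Five waveform metrics are computed per event — trough amplitude, peak
amplitude, trough-to-peak width, half-width, peak/trough ratio — and
z-scored. The sorter over-clusters with k-means
(`k = min(20, floor(n/50))`, guaranteeing mergeable granularity at ~50
events per initial cluster) and then repeatedly merges the closest
centroid pair while the Euclidean inter-centroid distance is < 2.5 *and*
the merged cluster's fraction of inter-spike intervals below 2 ms does
not exceed 0.5%. An exact-zero violation rule would be untestable under
chance coincidence, so the ceiling is small, explicit and configurable;
only merge products are certified by it — an unmerged cluster can carry a
chance coincidence. Clusters with strictly more than 50 spikes are
flagged included. This procedure is conservative by construction: it
prefers split units over contaminated ones, and the suite asserts < 2%
cross-unit contamination on two-unit ground-truth data.

Waveform types come from k-means on cluster centroids (seeded,
deterministic, ties broken by the seed). Stimulus-locked spiking is
compared across types with a Kruskal–Wallis test (tie-corrected, via
`stats::kruskal.test`) followed by Dunn's pairwise z tests, Holm-adjusted
across pairs.

## LFP analysis

Raw traces are low-pass filtered at 1.9 kHz and decimated by exactly 8
(25 kHz → 3125 Hz). That cutoff slightly exceeds the post-decimation
Nyquist frequency (1562.5 Hz); we keep the stated procedure — the
zero-phase filter's roll-off leaves negligible energy above Nyquist, and
all analysis frequencies sit below 100 Hz anyway.

Time-frequency amplitude uses a complex Morlet wavelet of 6 cycles on 40
log-spaced frequencies between 0.5 and 100 Hz (the wavelet family and
grid are our choices; both are configurable). Kernels are normalised so a
sinusoid of amplitude A produces a ridge of amplitude ~A, and each
spectrum records its per-frequency kernel energy so that white-noise
flatness can be checked after energy correction. Traces are internally
decimated to ~500 Hz before the transform — two orders of magnitude above
the highest analysis frequency — to keep 12-minute recordings cheap.

Trial-averaged spectra are epoched at block onsets, averaged over the 6
trials, and z-scored per frequency against the pre-onset baseline window
(10 s default, validated not to overlap the previous block). Fractional
band change is `(stim − baseline)/baseline` on mean band *power*
(amplitude squared; an amplitude convention is
available as an option — under the amplitude
convention a suppression to 50% reads −0.5 instead of −0.75). The first
5 s of every epoch — stimulation epochs and the post-offset baseline
epochs alike — are excluded, matching the ~5 s lag of LFP power changes;
band defaults are delta = 1–4 Hz and gamma = 30–90 Hz.

Network bursts are detected from population spike counts in 100 ms bins
as maximal runs exceeding 3× the median baseline bin count, with runs
separated by < 200 ms merged (all three constants configurable; there is no
canonical burst definition, so ours is stated explicitly). The merge rule imposes an effective dead time of ~0.3 s, so
at high burst rates detected rates sit below true rates by the factor
`1/(1 + r·0.3)`; the tests use this correction as the oracle.

## Group inference

Second-level inference permutes ROI-wise COPE maps between groups.
Nuisance covariates (sex, scan order) are handled Freedman–Lane style:
covariates are regressed out and the covariate-residualised rows are
permuted, keeping nuisance structure intact (the standard scheme for
permutation inference with nuisance regressors). Family-wise
corrected p-values use the max-|t| statistic over ROIs;
cluster-extent correction forms clusters as connected components of the
supra-threshold set on an ROI adjacency graph (forming threshold:
uncorrected two-sided p < 0.01 by default, always reported in output) and
compares observed extents to the permutation distribution of maximum
extents. The full analysis uses 5000 permutations; the calibration suite
runs 500 simulated null datasets at 500 permutations each and checks the
family-wise error is 0.05 ± 0.02. Permutation p-values use the
`(1 + exceedances)/(n_perm + 1)` estimator, which is valid (super-uniform
under the null — also asserted).

DRN-normalised connectivity divides every projection ROI's COPE by the
DRN COPE; we require |t| ≥ 2 on the DRN COPE before normalising because
the ratio is unstable around a null denominator. The restraint preset's
global 0.5 blunting leaves this normalised profile exactly unchanged —
the no-change-in-connectivity finding expressed as a pipeline property.

## Electro-vascular coupling

Band-power envelopes (sampled at 10 Hz, well above the HRF bandwidth) or
MUA rates are convolved with the same HRF as the GLM and bin-averaged to
the volume grid; a boxcar input reproduces the GLM activity regressor to
machine precision, which pins the two code paths together. Site-level
coupling is the Pearson correlation between the convolved regressor and
the preprocessed CBV series (the correlation target; raw series would add
the clearance drift to both sides), excluding an 8-volume convolution
burn-in. Site p-values are descriptive; no multiplicity correction is
applied at site level. The `coupling_delta` preset draws CBV as a scaled
copy of each site's convolved envelope plus white noise whose variance is
set analytically (over the analysed, post-burn-in volumes) so the
population correlation equals the target (0.75 for delta). Regional
coupling correlates a fractional electrophysiological change with the
COPE across strictly (animal, ROI)-matched sites; the `fig3e`/`fig3f`
presets draw the 15 matched pairs from a bivariate normal model with
population correlation 0.69 (delta power) or 0.78 (burst frequency), and
replicate means over 50 seeds recover the targets despite the small-n
bias of the sample correlation (≈ ρ(1−ρ²)/2n, under 0.02 here).

## Structure-function comparison

Anatomical maps (projection density, receptor expression) are compared to
the COPE map by Pearson correlation over the inner join of ROI labels
(case-insensitive; dropped labels reported), after optional white-matter
masking so projection maps reflect terminal fields rather than fibre
tracts. The 39-ROI atlas drops the DRN for this comparison (38 ROIs): the
stimulated nucleus itself is not part of its own projection field. The
map generator mixes the standardised COPE map with an in-sample
orthogonalised standardised noise map as
$m = r\,u + \sqrt{1-r^2}\,z_\perp$, which makes the sample r² equal the
target *exactly* for every seed — the calibration invariant
(±0.02 over 100 seeds) is then met by construction. Receptor screens are
BH-FDR corrected across the screened maps (the screened-set correction is
our choice) and ranked by r², ties broken by label. Judging map
"robustness" by eye is out of scope; maps are taken as given.

## Numerical and design notes

* All randomness flows through a seed argument per generator call; the
  caller's RNG state is saved and restored, and identical (arguments,
  seed) give bit-identical outputs, including written tables.
* Problem sizes in the test suite are chosen so the whole suite runs in
  about a minute and a half: ephys fixtures use 2 kHz or 25 kHz traces of
  30–120 s, Monte-Carlo loops use 10–500 replicates, and permutation
  tests 200–500 permutations. These are the package's own verification
  sizes; the analysis defaults (5000 permutations, full-length
  recordings) remain the documented production settings.
* The smoothing contract interprets the stated "0.45 mm² kernel" as a
  0.45 mm FWHM isotropic Gaussian — the area/width ambiguity is noted
  here; mass is preserved in the interior and a FWHM below the voxel size
  passes through with a warning.
* Frame-wise displacement converts rotations to arc length on a 5 mm
  sphere (a mouse-brain radius); the formula is
  `FD = Σ|Δtrans| + r·Σ|Δrot|`.
* The ROI data model (ROI × time tables with JSON sidecars, int16 binary
  + sidecar for probe data, two-column TSV for maps) is the primary
  interface; volumetric NIfTI export is available through RNifti for
  smoothing/overlay work. Directory layouts are BIDS-inspired but not
  claimed BIDS-valid.
* The package is driven from R: the exported functions plus
  `run_experiment()`/`validate_config()` are the orchestration surface,
  and every result bundle carries a manifest from which it can be
  regenerated.

## What the generators do not emulate

Synthetic cohorts have no motion, no k-space or susceptibility artefacts,
no registration errors, and Gaussian (optionally AR(1)) noise rather than
physiological noise spectra; probe recordings have stationary noise and
stereotyped templates without electrode drift. Passing recovery tests on
these data shows the *estimators* are correct and calibrated under the
stated models — it does not certify performance on real recordings, whose
headline statistics depend on live-animal data this package does not
ship.
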