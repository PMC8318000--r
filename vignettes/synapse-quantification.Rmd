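---
title: "Quantifying the B cell immune synapse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the B cell immune synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapseQuant)
```

## Scope

When a B cell meets antigen (Ag) presented on a surface or on an
antigen-presenting cell (APC), B cell receptor (BCR) signaling remodels the
actin cytoskeleton: the cell spreads radially, a peripheral branched F-actin
ring drives lamellipodia outward while flowing centripetally (retrograde
flow), and BCR–Ag microclusters coalesce toward the center of the contact,
in many cells forming a central supramolecular activation cluster (cSMAC).
`synapseQuant` implements the measurement side of this biology as a tested
pipeline over five quantification stages:

1. **Spreading area** from the F-actin channel.
2. **Radial fluorescence intensity profiles** and their population-level
   smoothing, used to localize proteins (e.g. GMF&gamma;) relative to the
   peripheral actin ring.
3. **Kymograph velocimetry** of actin retrograde flow from TIRF time-lapse
   movies.
4. **Microcluster quantification** at the B cell–APC interface: background
   subtraction, thresholding, segmentation, per-cluster intensity fractions,
   the cSMAC call, and the per-cell pCD79:Ag signal-amplification ratio.
5. **Statistics**: robust outlier removal (ROUT), Mann–Whitney U, paired t
   tests, per-experiment percent-of-control normalization, densitometry
   ratios, and summary tables.

A synthetic-microscopy generator provides ground-truth-annotated input for
every stage, so the pipeline's accuracy is measurable without any real data.

## The camera model

Synthetic scenes are rendered noiselessly from analytic shapes and passed
through a fixed acquisition chain: Gaussian PSF blur (`psf_sigma_px`), a
Poisson photon draw scaled by `photon_gain` (shot-noise variance =
mean / gain in intensity units), additive Gaussian read noise
(`read_noise_sd`), clipping at zero, and a constant baseline `offset`. The
defaults (`psf_sigma_px = 1`, `photon_gain = 1`, `read_noise_sd = 2`,
`offset = 100`) describe a well-exposed EMCCD-like acquisition; no intensity
statistics were available to calibrate them, so they are package choices,
and the photon-transfer property (sample variance = mean/gain + read&sigma;&sup2;)
is what the tests pin down rather than any particular SNR. Because clipping
acts at zero, mean-preservation (the average of many noisy renders converges
to the blurred clean scene plus offset) holds wherever the scene is more
than a few read-noise SDs above zero; the test suite checks it on such
scenes.

All generators take an explicit integer seed, use R's default Mersenne
Twister stream, restore the caller's RNG state on exit, and are
bit-reproducible. A single master seed is fanned out to per-stage child
seeds (`derive_seed`), so any stage of a pipeline run can be reproduced in
isolation.

## Synthetic scenes and what they do (and do not) emulate

**Spreading cells** are a soft-edged disk footprint with a dim cell body
plus an annular Gaussian actin peak at the designed ring radius, and a
GMF&gamma; channel peaking interior to the ring
(`gmf_peak_radius_px < actin_ring_radius_px`), reproducing by construction
the observed ordering of the two radial peaks. Defaults (cell radius 50 px
at 0.1 &mu;m/px, i.e. a 10-&mu;m contact; ring at 0.8 R) match a
well-spread B cell.

**Synapse frames** render each Ag microcluster as an isotropic 2D Gaussian
(&sigma; = 2 px) whose integral is the designed intensity; the clean pCD79
channel is exactly `pcd79_per_ag` times the clean Ag channel, so the
designed per-cell amplification ratio is known. Random truths draw cluster
counts uniformly (1–6 by default), place centers with a minimum separation
of 14 px so designed clusters stay resolvable, and draw intensities
log-normally with `sdlog = 0.35`. That intensity spread (a few-fold range
within one cell) is a deliberate generator condition: it keeps every
designed cluster bright enough to survive global Otsu thresholding, so the
designed fractions — and the cSMAC truth computed from them — describe what
is actually present and recoverable in the rendered image. A wider spread
would put designed clusters below any single-threshold detection limit and
make the annotation unfaithful to its own image.

**Flow movies** translate a 1D band texture (a sum of twelve random-phase
cosines, analytic so sub-pixel translation is exact) toward the cell center
by exactly `v_true * dt / (1000 * pixel_size_um)` px per frame under a
static lamellipodial envelope, at the acquisition defaults of 0.1 &mu;m/px
and 2 s/frame. Per-frame displacements in (0, 0.05) px are rejected as
indistinguishable from a static scene; zero motion is allowed.

None of the scenes simulate actin mechanics, membrane deformation, receptor
diffusion, multi-cell fields, or non-Gaussian PSFs. Passing recovery tests
therefore demonstrates that the measurement code is correct and well
calibrated on images whose structure it assumes; it does not certify
performance on real data with debris, uneven illumination, or touching
cells. In real-data mode, per-cell ROI label masks scope the measurements
instead of the one-cell-per-image assumption.

## Stage-by-stage notes and numerical choices

### Rolling-ball background subtraction

The background is the grayscale morphological opening of the image with a
non-flat spherical structuring element (default radius 10 px); offsets
outside the image are ignored rather than padded. This is the exact
rolling-ball model; the widely used ImageJ plug-in approximates the ball by
a paraboloid on downsampled images, a dialect difference we do not
reproduce bit-exactly. Opening is anti-extensive and offset-equivariant, so
the subtracted image is nonnegative and invariant to any constant added to
the input — the property the whole downstream pipeline inherits. One
consequence of the exact spherical element: a 1-px spike is preserved only
up to the sub-pixel curvature of the ball (r − sqrt(r&sup2; − 1) &asymp; 0.05
for r = 10).

### Otsu thresholding

Candidate thresholds are the 255 interior boundaries of a 256-bin
quantization of the intensity range; for each candidate the between-class
variance w0·w1·(&mu;0 − &mu;1)&sup2; is computed *exactly* from the data via
cumulative sums over the sorted intensities, and the lowest maximizing
candidate wins (ties break toward the lower threshold). Computing class
means from the data rather than from bin centers makes the implementation
agree exactly with a brute-force exhaustive search, which the tests
exploit. Foreground is strictly above the threshold; a constant image warns
and returns an empty mask, which propagates as "zero clusters, cSMAC not
evaluable" rather than an error.

### Cluster segmentation and the cSMAC rule

Connected components use 8-connectivity by default (the diagonal-inclusive
particle-analysis convention; 4-connectivity is a documented switch).
Components are retained only if strictly larger than 0.05 &mu;m&sup2;; the
strict inequality is enforced robustly against floating-point round-off, so
a 5-px component at 0.1 &mu;m/px (exactly 0.05 &mu;m&sup2;) is excluded
while a 6-px one is kept. Retained masks are mapped back onto the
background-subtracted image and summed, giving per-cluster integrated
intensities and fractions of the per-cell clustered total. A cell is called
cSMAC-positive when the smallest number of largest clusters whose fractions
sum above 0.90 is at most two. Ag and pCD79 are segmented independently,
each on its own histogram (the alternative — reusing the Ag mask for pCD79
— is a plausible reading of the original workflow; independent segmentation
was chosen because the two channels are quantified as separate "clustered"
pools). The amplification ratio is clustered pCD79 over clustered Ag; a
nonpositive Ag total is "not evaluable", distinct from zero.

### Radial profiles

In-mask pixels are binned into 1-px annuli around the mask centroid (the
center definition is a package choice; the original macro does not state
one). Each annulus value is the in-mask mean intensity; empty annuli are
dropped, not zero-filled — this is the in-mask reading of "pixels that are
part of the image", applied to out-of-cell and out-of-frame pixels alike.
Values are normalized to the per-cell maximum (exactly 1 somewhere by
construction) and radii to the distance of the farthest mask pixel (global,
not per-angle). Population curves smooth the pooled per-cell points with a
fixed-span loess (span 0.35, degree 2) — a deliberate stand-in for the
generalized additive model used for published population profiles, which
names the model family but no basis, knots or penalty; parity with any
specific GAM library is a non-goal. The curve's standard error is the
between-cell SEM of the per-cell profiles interpolated onto the grid, so N
identical profiles give SE exactly 0 and the band reflects cell-to-cell
variability, not residual noise.

### Spreading area

Otsu on the actin channel, largest component, interior holes filled (the
actin-depleted center of a spread cell belongs to the footprint), area =
pixel count × pixel size&sup2;. One cell per analyzed frame is assumed; no
touching-cell splitting is attempted.

### Kymographs and flow velocity

Kymographs sample each frame along a line at 1-px spacing by bilinear
interpolation, averaging across an odd perpendicular width (1-px offset
spacing). The primary velocity measurement mirrors manual kymograph
reading: annotated endpoint pairs converted as
|&Delta;position| · pixel size · 1000 / (&Delta;frames · interval) nm/s.
An automated estimator is provided as a clearly-labeled extension for
synthetic benchmarking: columns `frame_lag` apart are cross-correlated over
integer shifts with parabolic sub-pixel refinement; it reports speed, not
direction. Cohort summaries give per-condition medians and percent
reduction versus control, 100·(1 − median_test/median_control).

### Statistics

`rout_outliers` is the location-model specialization of robust regression
plus outlier removal: Lorentzian-weighted IRLS for the center (at most 60
iterations, relative tolerance 1e-9), RSDR = 68.27th percentile of absolute
residuals × n/(n−1), residual t-ratios (df n−1) tested most-extreme-first
against the step-down boundary Q·(n−i+1)/n, stopping at the first failure.
Below n = 5, and whenever the RSDR degenerates to zero, nothing is flagged.
Flags are affine-invariant and are *marks*, not deletions; downstream
summaries exclude flagged values but the values are always reported. On
clean Gaussian data the flagged fraction calibrates to about Q, and a 10-SD
contaminant in n = 31 is caught essentially always — both checked by Monte
Carlo in the test suite.

The Mann–Whitney U test reports the exact permutation p-value when there
are no ties and n&middot;m &le; 400 (a tractability bound, verified against
full enumeration), otherwise the tie- and continuity-corrected normal
approximation. The paired t test follows the closed form; an all-zero
difference vector returns t = 0, p = 1 (no evidence of change), while a
constant nonzero difference vector — zero variance, unbounded statistic —
is reported as not evaluable rather than p = 0. Percent-of-control
normalization computes 100·median(knockdown)/median(control) within each
(experiment, time point) stratum; densitometry ratios divide band/loading
by the reference sample's own ratio so the reference is 1.0 by definition.

## Problem sizes used for validation

The bundled recovery runs use 200 synthetic synapse frames (96×96 px) for
the cSMAC end-to-end check, 5 movies per speed at 25/50/100/200 nm/s plus
two 50-track cohorts (designed median ratio 0.62) for flow, 15 frames per
designed amplification ratio, 10,000 clean-data replicates and 1,000
spiked-data trials for ROUT calibration. These sizes put the binomial and
Monte-Carlo error of each check comfortably below its acceptance margin
while keeping a full validation run within a few minutes on one CPU.

## Known limitations

* The rolling-ball opening is exact, so results differ slightly from
  ImageJ's paraboloid approximation; the difference is a constant-free
  background term and does not affect offset invariance.
* Otsu is computed per image (or per ROI-scoped image in real-data mode);
  whether the original macros thresholded per cell or per field is unknown.
* The automated kymograph slope estimator assumes one dominant motion along
  the line; crossing tracks call for manual endpoint annotation.
* `average_profiles` reports between-cell SEM, not the smoother's internal
  standard error; with very few cells the band is accordingly wide.
* The generator's noise and intensity scales are package defaults, not
  calibrated to any instrument.
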