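---
title: "Quality-control methods in niqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-control methods in niqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niqc)
```

## The problem

Small-animal MR studies accumulate hundreds of scans across scanners,
coils and operators, and a handful of them are always degraded — low SNR
from a detuned coil, ghosting from EPI readout errors or periodic
physiological motion, frame-to-frame displacement in long functional and
diffusion acquisitions. Screening them by eye does not scale and manual
region-of-interest (ROI) placement does not reproduce. `niqc` computes
every quality feature without any manual ROI and flags suspect scans
relative to their own cohort, so the reviewer only opens the scans that an
ensemble of detectors agrees look unusual.

The pipeline has three stages: **parsing** (discover NIfTI/BIDS files or
Bruker study folders, classify each scan as anatomical, diffusion or
functional), **feature calculation**, and **outlier detection** with
majority voting. Stage III consumes stage II's tables, which consume stage
I's manifest; each stage is also callable on its own.

## Quality features

### Standard SNR (COI sphere / corner cuboids)

The centre of intensity (COI) — the intensity-weighted centroid — anchors a
sphere that samples "true signal"; eight cuboids in the volume corners
sample air noise. The feature is

$$\mathrm{SNR}_{\mathrm{std}} = 20\,\log_{10}\!\frac{\mu_S}{\sigma_C}\ \mathrm{dB},$$

with $\mu_S$ the sphere mean and $\sigma_C$ the population standard
deviation pooled over all eight cuboids. For 4D diffusion data the first
b0 volume (b-value below 50 s/mm², or the first volume when no b-table
exists) represents the image.

The sphere radius is $\lfloor 0.1 \cdot \min(\mathrm{dims})\rfloor$
(at least 2 voxels, shrunk to stay inside the lattice) and each cuboid
edge is $\lfloor 0.15 \cdot \mathrm{dim}\rfloor$ per axis (at least 2).
Tying the radius to the *smallest* extent matters for small-animal data:
coronal rodent protocols are thin slabs (many in-plane voxels, few
slices), and a radius derived from the in-plane extent would poke out of
tissue along z and dilute the signal mean with air. Sphere and cuboids are
verified disjoint at construction; volumes below 8 voxels per axis are
rejected with an explanatory error.

### Chang-style histogram SNR

The second estimator needs no geometric noise region at all: the noise
standard deviation of each slice is read off the distribution of local
variability. Sample standard deviations over sliding 3×3 windows are
histogrammed with $\lceil\sqrt{n}\rceil$ bins, the counts are smoothed
with a 3-bin moving average, and the mode is taken as $\sigma(z)$ — in a
brain slice most windows sit in air or homogeneous tissue, so the mode
tracks the noise floor rather than anatomy. Per slice,
$E(z) = 20\log_{10}(\mu_{\mathrm{sphere}}(z)/\sigma(z))$, where
$\mu_{\mathrm{sphere}}(z)$ is the mean over the COI sphere's cross-section
in that slice (slices that do not intersect the sphere carry no signal
reference and are skipped). The scalar feature averages $E(z)$ over
slices, and for 4D diffusion data additionally over all non-b0 directions.

The estimator is deliberately simple and biased low by roughly 5–15%
(the mode of a small-sample SD distribution sits below $\sigma$); that
bias is common to every scan in a cohort and cancels in relative outlier
detection. Window size and smoothing width are config-exposed
(`chang_window`, `chang_smooth_bins`).

### Temporal SNR

For functional series, the per-voxel temporal mean over temporal standard
deviation becomes a dB map,
$\mathrm{tSNR}(v) = 20\log_{10}(\mu_t(v)/\sigma_t(v))$, and the scalar
feature is the map's mean over the COI sphere built on the time-averaged
volume (the same radius rule as above — the two spheres are intentionally
identical so spatial and temporal features describe the same tissue).
Temporally constant voxels are undefined in the map; they are excluded
from the sphere mean and counted in the scan's notes rather than silently
absorbed.

### Mutual information: ghosting and motion

All image-similarity scores use normalized mutual information from a
64×64-bin joint histogram over each image's own intensity range,
$\mathrm{NMI} = 2 I(a;b)/(H(a)+H(b))$, which maps self-comparison to 1 and
independence to ~0. The normalization choice is the package's own (the
underlying idea only requires "MI near 1 for identical images"); the bin
count is config-exposed. Constant (zero-entropy) inputs are defined cases:
1 if both images are constant and equal, else 0, always flagged.

**Ghost evidence.** The representative slice (middle z slice; for 4D data,
of the fourth-axis average) is compared with circularly shifted copies of
itself over every offset $1..N-1$ along the second in-plane axis. A clean
scan gives a smooth bowl: similarity falls as the shift grows and recovers
as the cycle completes. A displaced, attenuated copy of the object — a
ghost — re-aligns with the original at its displacement and produces an
interior peak; Nyquist ghosts sit at exactly half the field of view. A
peak counts when its prominence exceeds both 10% of the curve's range
(scale-free, per-scan) and an absolute floor of 0.05 NMI units. The floor
exists because an all-noise slice yields a flat curve whose "range" is
itself noise; without an absolute reference the relative rule would fire
on it. Both thresholds are config-exposed. The phase-encode axis of plain
NIfTI data is unknown, so the shift axis is a convention (second in-plane
axis); a ghost along the other axis is invisible to the curve — a known
limitation.

**Motion severity.** On the slice with the highest mean intensity over the
fourth axis (the brightest, most tissue-filled slice, which also bounds
processing time), NMI is computed between a reference repetition and every
repetition. Series with at least 20 repetitions use repetition 10 as the
reference — by then the signal has reached steady state — and shorter
series use repetition 1; the cutoff is config-exposed
(`reference_volume_threshold`). Motion severity is the population standard
deviation of that trace: 0 for a perfectly static series, growing with
displacement amplitude and frequency. Diffusion series keep their b0
frames in the trace (contrast changes between shells lower the absolute
NMI level, but severity measures *variability*, which motion dominates).

## Outlier detection and majority voting

Features are assembled per sequence class — anatomical
{standard SNR, Chang SNR}, diffusion {both SNRs, motion severity},
functional {tSNR, motion severity} — and each class table is screened by
five detectors:

* **IQR** (univariate): linear-interpolation quartiles per feature; a scan
  is flagged only for quality-*bad* violations — SNR below
  $Q_1 - 1.5\,\mathrm{IQR}$, motion severity above
  $Q_3 + 1.5\,\mathrm{IQR}$. An unusually good value is never an outlier.
* **One-class SVM** (RBF kernel, `e1071`), **isolation forest**, **local
  outlier factor** and **elliptic envelope** (MCD robust covariance +
  Mahalanobis distance) on the z-scored feature matrix. z-scoring is
  essential: decibels and NMI standard deviations differ by orders of
  magnitude. The isolation forest and LOF are implemented in the package
  (100 trees / subsample 256; $k = \min(20, n-1)$ neighbours); the score
  threshold for the three score-based methods is the
  $(1-\mathrm{contamination})$ quantile of in-cohort scores with
  contamination 0.05, so each flags roughly its most anomalous 5%.

The one-class SVM uses its own decision boundary with $\nu = 0.1$. The
choice is deliberate: $\nu n$ bounds the number of margin violators, and
with cohorts of ~30 scans, $\nu = 0.05$ leaves less than one scan of
slack — an isolated extreme scan then sits numerically *on* the margin
(its decision value is ~0 and the flag becomes solver noise). $\nu = 0.1$
keeps at least one scan of slack and isolates extremes decisively. All
detector parameters are config-exposed.

Each scan's five 0/1 flags sum to a majority vote of 0–5; votes at or
above the review threshold (default 3, settable 1–5) mark the scan for
inspection. A failed detector (singular covariance on degenerate data, too
few rows) contributes 0 to everyone and is listed in the log, keeping the
0–5 scale intact. Detector inputs are sorted into a canonical row order
before fitting so the flags do not depend on how the cohort rows happened
to be ordered. ±Inf feature sentinels (e.g. zero measured noise) stay in
the multivariate matrix, clamped just beyond the finite cohort range —
they are informative extremes, not missing data; features that failed
outright (NA) are median-imputed and logged; rows with no features at all
are excluded and logged.

Ghost evidence is reported per scan but kept out of the detector matrix by
default (`ghost_in_feature_matrix` switches it in): it is a boolean with
its own threshold semantics, and mixing it into z-scored continuous
features would let a single convention dominate votes.

## The phantom simulator

`make_phantom()` builds an ellipsoidal "brain" (semi-axes 35% of each
extent, so the corner cuboids always sit in air) of tissue intensity 50
with a ±5% smooth sinusoidal texture, over an air background with Gaussian
noise of SD 5 — a baseline standard SNR of ~20 dB, typical of routine
rodent T2-weighted work. The background rides on a pedestal of 4 noise
SDs so magnitude non-negativity holds without clipping the noise
distribution (clipping would bias the corner SD and break the closed-form
dB checks); the pedestal is 0 when the noise is 0. 4D phantoms redraw the
noise independently per frame, which makes temporal and spatial noise
equal by construction — physically what thermal noise does.

Artifact injections mirror the validation families: additive Gaussian
noise (default variance 0.2 on intensities normalised to [0, 1]), gamma
shading (0.6), salt-and-pepper (default amount 0.05) and speckle (default
variance 0.2) — the last two defaults are the package's own, since only
the Gaussian variance and gamma value are pinned by the validation
protocol — plus frame-wise uniform integer translations (motion) and
half-FOV ghost copies (fraction 0.3 by default). Every injection with
zero-magnitude parameters is the identity map, and everything is
deterministic under its seed.

What the phantom does *not* emulate: anatomy (it is an ellipsoid, not an
atlas brain), Rician noise statistics, coil shading profiles, k-space-level
artifacts, physiological noise. Passing the simulation suite therefore
shows that the *estimators and detectors* behave correctly on controlled
input — monotone under graded degradation, separating contaminated from
clean groups, recovering planted outliers — not that any fixed dB value
transfers to a particular scanner.

## Numerical conventions and degenerate inputs

* All SNR-type values are $20\log_{10}$ decibels.
* Quantiles use linear interpolation between order statistics
  (`type = 7`), pinned so the IQR rule is oracle-testable.
* Population (not sample) standard deviations for the MI trace and the
  pooled cuboid noise: both are descriptive statistics of a fixed set.
* Middle slice of an even extent $N$ is index $\lfloor N/2\rfloor$
  (0-based).
* b0 means b-value < 50 s/mm²; without a b-table the first volume is
  assumed b0.
* Zero measured noise gives a +Inf dB sentinel plus a note; an all-zero
  image is an explicit "no signal mass" error; constant slices and
  zero-entropy MI inputs return flagged, defined values. Nothing is
  silently dropped.
* Scans are never spatially reoriented; mismatched metadata (a b-table
  that does not match the volume count, a 2dseq payload that does not
  match its matrix) is an error instructing manual correction, never a
  silent fix.

## Problem sizes in the shipped validation

The test and acceptance runs use 64×64×24 phantoms (40 frames for
functional, 12 directions for diffusion), cohorts of 31 scans, 30
repetitions of the planted-outlier experiment and 100 seeded trials per
ghost condition — sizes at which every statistical check (Welch tests at
p < 0.001, ≥90% recovery, ≥95%/≤5% ghost rates) is comfortably powered
while a full run stays in the minutes range on one CPU.

## Known limitations

* Ghost detection scans one in-plane axis; phase-encode direction is not
  read from metadata.
* The Chang noise mode is biased low on slices where air occupies little
  area; the bias cancels within a cohort but the absolute dB values should
  not be compared against other tools.
* Detector decisions below ~10 scans per class are unstable (warned, not
  refused); the IQR band needs at least 4.
* Bruker support covers the minimal ParaVision parameter subset (matrix,
  resolution, b-table, repetitions, int16/float32 2dseq); exotic
  reconstructions are out of scope.
* Nyquist and discrete ghosts are not distinguished; animal and hardware
  motion are not separated.
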