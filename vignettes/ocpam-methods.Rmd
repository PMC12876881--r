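---
title: "ocpam: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ocpam: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each `ocpam` stage, the meaning,
units and rationale of every tunable parameter, what the synthetic-data
module does and does not emulate, and the numerical choices that matter for
reproducibility. It makes no empirical performance claims beyond what the
package's own test suite and `scripts/acceptance.R` compute.

# Data model and conventions

All gridded data live in `Volume3D` (intensities) or `LabelMask` (integer
labels) objects. Arrays are indexed `(z, y, x)` — depth first — with voxel
spacing `(dz, dy, dx)` in micrometres. Physical coordinates are
`index * spacing` with the first voxel at 0 µm, and bounding boxes are
0-based, half-open. `FusionCalibration` stores the axis-aligned affine
`ocm = scale * pam + offset` per axis (offsets in µm, scales unitless).

Two default grids recur throughout:

* organoid fields at 2.52 µm isotropic spacing (optical-coherence-microscopy
  scale), and
* spheroid/photoacoustic fields at 0.84 µm isotropic spacing.

# Spectral-domain reconstruction (`reconstructBscan`)

The interferogram model is a Gaussian source envelope (centre wavelength
845 nm, FWHM bandwidth 131 nm) sampled uniformly in *wavelength*, with each
reflector at depth $d$ contributing $r \cos(2 k n d + \phi(k))$, where
$n = 1.38$ is the refractive index of the medium (soft tissue / hydrogel)
and $\phi$ an optional residual-dispersion polynomial in $(k - k_0)$.
Reconstruction performs, in order: background subtraction, resampling to a
uniform wavenumber axis (the axis is nonlinear in $k$ because the
spectrometer is linear in wavelength) by cubic spline, numerical dispersion
compensation $\exp(-i\phi(k))$, apodization, and an inverse FFT. The axial
pixel pitch is $\pi / (n\,\Delta k)$ for a spectral span $\Delta k$; the
test suite verifies reflector localization against this relationship.
Log compression uses a dB floor of −40 dB (`recon$db_floor`), below which
amplitudes are clipped; −40 dB is far above double-precision noise but
within the dynamic range a display or downstream threshold can use.

# Segmentation (`preprocessVolume`, `segmentOrganoids`)

Preprocessing clips intensities to the `c(1, 99.99)` percentile window and
rescales to [0, 1], then applies a 3×3×3 median filter. The *upper* clip is
deliberately extreme: organoids typically occupy well under 1 % of a field,
so a conventional 99th-percentile clip would saturate the entire object
class and destroy the bimodality that global Otsu thresholding needs. The
lower 1 % clip only trims dark outliers.

Segmentation is classical: global Otsu threshold, grey-scale closing
(rank-max then rank-min) to seal small gaps, 26-connected component
labelling, and marker-controlled watershed splitting of components that
contain more than one distance-transform maximum. Markers are 26-connected
local maxima of the squared Euclidean distance transform, greedily thinned
to a minimum separation of 20 µm — roughly the smallest organoid radius
worth splitting, so closer maxima are treated as one object. Components
below `min_volume_um3 = 500` µm³ (≈ a 5 µm-diameter cell) are discarded as
debris.

# Tracking (`buildTracks`)

Organoids are matched day-to-day by maximizing a convex combination of
three attribute similarities:

* spatial: $\exp(-d^2 / 2\sigma_d^2)$ on centroid distance, with
  $\sigma_d = 30$ µm — the scale of plate drift plus organoid motility
  between imaging days (default drift in the generator is 1.5 µm/day over
  2-day intervals, so genuine matches score near 1);
* volume: $\min(v_1, v_2)/\max(v_1, v_2)$, tolerant of several-fold growth;
* bounding-box IoU in physical coordinates.

Weights are `c(spatial = 0.5, volume = 0.3, bbox = 0.2)` and pairs scoring
below `tau = 0.4` are left unmatched; 0.4 rejects a pair whose centroids
are several $\sigma_d$ apart even when sizes agree. Assignment is solved
exactly per day pair with an in-package Hungarian algorithm, and tracks are
chained outward from the *middle* imaging day so that segmentation dropouts
on the first or last day do not seed spurious tracks. Unmatched objects are
flagged `APPEARED`/`LOST`, and disappearing objects whose volume is
absorbed by an adjacent track are flagged `MERGED_INTO`.

# Growth quantification (`relativeGrowth`, `classifyGrowthPattern`)

Volumes are normalized to the first *observed* day of each track (not a
fixed calendar day), making trajectories comparable across tracks that
appear late. Classification of the final relative volume $R$ uses decade
boundaries, inclusive: $\log_{10} R \ge 2$ → `RAPID`, $\ge 1$ → `MEDIUM`,
otherwise `WEAK`. A `DTP` (drug-tolerant-persister, i.e. biphasic) call
requires at least one growth interval, then a plateau of ≥ 2 consecutive
intervals with fold change ≤ `f_plateau = 1.25` (chosen above day-to-day
measurement jitter but below real growth), followed by cumulative regrowth
≥ `f_regrow = 10`. DTP is tested before the decade rules because a
regrowing persister can also exceed 2 decades.

`classTrajectory` provides the canonical per-interval fold sequences used
by the generator; the `RAPID` sequence begins with a 10-fold first
interval, and the `DTP` sequence (grow, plateau, regrow) needs at least 4
intervals to be expressible — requesting fewer is an error by design, not a
degraded approximation.

# Fluorescence viability (`viabilityTable`)

Live and dead channels are binarized per channel (contrast-limited adaptive
histogram equalization with 8×8 tiles, clip limit 2, then Otsu), and cells
are counted per organoid ROI. A cell positive in both channels counts as
*dead*: membrane-compromised cells take up the dead stain regardless of
residual esterase activity. The per-organoid score is
`live / (live + dead)`; status is `HIGH` if the score *exceeds* 0.5 —
exactly 0.5 is `LOW`, a deliberate tie-break so that a coin-flip organoid
is never reported viable. ROIs with no detected cells are `UNSCORABLE`.
`overallViability` is simply the fraction of imaging days a track is called
`HIGH` (e.g. 8 of 10 days → 0.8).

# Radiomics (`extractFeatureVector`)

Exactly 32 features per ROI: 9 first-order, 13 grey-level co-occurrence
(GLCM) and 10 run-length (GLRLM) features. Intensities inside the ROI are
discretized to `n_levels = 32` equal-width bins between the ROI minimum and
maximum (affine-invariant by construction); 32 levels keeps co-occurrence
matrices well-populated in ROIs of a few thousand voxels. Texture matrices
are accumulated over the 13 unique 3-D directions at `distance = 1` voxel
(the 26-neighbourhood modulo symmetry); GLCMs are symmetrized and features
averaged over directions. A run starts where the predecessor voxel along
the direction is outside the grid, outside the ROI, or a different level.
ROIs smaller than `min_roi_voxels = 27` (a 3×3×3 block) are rejected since
texture statistics are meaningless below that. The C++ matrix builders are
validated in the test suite against brute-force enumeration oracles written
independently in R.

# Classification (`crossValidate`, `learningCurve`)

The viability classifier is gradient-boosted trees (`xgboost`; 300 rounds,
maximum depth 4, learning rate 0.1, single thread for determinism) under
k-fold *stratified* cross-validation (default k = 10, round-robin within
class after a seeded shuffle). AUC is computed with `pROC` with fixed
`direction` and `levels` so that it never silently auto-orients. The
learning curve re-runs cross-validation on seeded class-stratified
subsamples at fractions 10 %…100 % in steps of 10 % (10 points); each
fraction is floored at k samples per class so small fractions remain
cross-validatable. Note that *retraining* on inverted labels leaves AUC
unchanged (labels and predictions both flip); only rescoring fixed
predictions against inverted labels mirrors it — the suite asserts both.

# OCM/PAM fusion (`calibrateFusion`, `detectAbsorbers`, `fuseOverlay`)

Calibration images a pyramid phantom in both modalities and estimates the
per-axis affine. The top surface is extracted per depth line; the peak
depth is refined to sub-voxel precision by a parabolic vertex fit on
log-intensities around the line maximum (exact for a Gaussian axial
profile — a plain intensity-weighted mean carries a grid-phase bias that
differs between the flat base plane and the pyramid flank and measurably
inflates the lateral second moments). Lateral scale and offset follow from
height-weighted first and second moments of the surface footprint, after
zeroing weights below 2 % of the peak prominence (the near-base skirt
carries no shape information and is noise-dominated); axial scale and
offset come from a least-squares fit of OCM surface depths against PAM
surface depths resampled at corresponding lateral positions. Pure-noise
volumes fail an explicit surface-detection floor (max of 0.3 × global peak
and median + 10 MAD), and exactly flat surfaces raise a "lateral scale
unidentifiable" error rather than returning garbage.

`applyCalibration` resamples PAM onto the OCM grid by trilinear
interpolation; target voxels mapping outside the PAM field are zero, which
includes the trailing half-open boundary layer.

`detectAbsorbers` thresholds each depth line at `threshold_fraction = 0.87`
of its own peak (the high cut isolates strong melanin absorption against
the weak background photoacoustic response), skipping lines whose peak
stays below a noise floor of mean + 5 SD of a background border region.
Surviving voxels are grouped 26-connectedly and components smaller than 5
voxels are discarded — a real absorber spans at least the acoustic
point-spread function (≈ 16 voxels at 0.84 µm sampling), whereas noise
excursions above a 5-SD floor are isolated voxels. A known characteristic
of per-line thresholding: when a strong absorber shares a depth line with a
weaker one, the weaker can be suppressed; `scope = "global"` trades this
for a single volume-wide threshold.

`fuseOverlay` composites a warm-colormap PAM maximum projection onto the
grayscale OCM standard-deviation projection. The emptiness decision reuses
`detectAbsorbers`: if no absorber is detected the output is exactly the
grayscale image, so noise-only PAM channels add no colour.

# The synthetic-data module: what it does and does not emulate

Every generator is seeded, restores the caller's random-number state, and
returns a ground-truth object alongside the data.

Emulated:

* organoid time series as bright ellipsoids with per-class volume fold
  sequences (`RAPID` starting at 10-fold/interval, `MEDIUM`, `WEAK`, and
  biphasic `DTP`), log-normal fold jitter (σ = 0.06), slow centroid drift
  (1.5 µm/day), speckle-like intensity texture, and rejection sampling of
  placements so objects never overlap at their final size — a scene that
  cannot fit its organoids is an error, not a silent overlap;
* live/dead fluorescence pairs with class-dependent live fractions and
  spatially disjoint blob channels (brighter channel wins at overlap);
* mixed spheroids with a set fraction of melanin-loaded cells whose
  photoacoustic amplitude far exceeds the non-absorbing background;
* pyramid calibration phantoms under a known affine, and spectral
  interferograms with dispersion and detector noise.

Not emulated: optical shadowing and attenuation with depth, refraction,
speckle decorrelation between days, organoid shape change beyond scaling,
apoptotic debris, stain leakage or bleed-through, acoustic reverberation.
In particular, the two texture regimes of `generateTextureCohort` differ
mainly in mean brightness and blob granularity, so classifier separability
on this cohort exercises the *pipeline*, not radiomics subtlety: a
real-data texture problem is much harder.

# Numerical choices

* All stochastic steps take explicit integer seeds; generators use an
  internal `withSeed` that saves and restores `.Random.seed`.
* xgboost runs single-threaded with a fixed seed; results are bitwise
  reproducible on a given platform.
* The C++ kernels (connected components, distance transform, watershed,
  rank filters, texture-matrix accumulation) use 0-based linear indexing
  `z + nz (y + ny x)` and are exercised against independent R oracles.
* Quantile-based parameters use R's default type-7 quantiles.
* TIFF I/O stores integer-valued grids at 8/16 bits (value-exact round
  trip); all other grids must lie in [0, 1] and are stored at 32-bit depth,
  quantized at 1/(2^32 − 1) ≈ 2.3e-10. Reads always return double storage.

# Limitations

* The segmentation percentile clip assumes sparse bright objects on a dark
  background; a field dominated by signal would need a lower upper clip.
* Tracking assumes modest inter-day motion relative to organoid spacing;
  σ_d and τ must be retuned for dense cultures.
* The DTP rule is a pattern heuristic on relative-volume trajectories; it
  needs at least four imaging intervals and cannot distinguish a persister
  plateau from transient segmentation undersizing on a single day.
* Radiomics features are computed at a single distance (1 voxel) and one
  discretization (32 levels); no wavelet or shape families are included.
* Fusion calibration assumes an axis-aligned affine (no rotation or shear)
  and a phantom with lateral structure; it will correctly refuse flat or
  featureless inputs rather than estimate a rotation it cannot represent.
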