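---
title: "Skin microvascular biomarkers from dual-band optoacoustic mesoscopy"
author: "rsomskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin microvascular biomarkers from dual-band optoacoustic mesoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsomskin)
```

## The measurement and the model

Raster-scan optoacoustic mesoscopy (RSOM) images the first ~1.5 mm of
human skin by exciting hemoglobin and melanin with a pulsed 532 nm laser
and raster-scanning a wideband (10--120 MHz) ultrasound detector over a
4 x 2 mm^2 field. Reconstructing the detected signals separately in a low
(10--40 MHz) and a high (40--120 MHz) frequency band yields two
co-registered volumes in which large (~40--150 um) and small (<40 um)
vessels dominate respectively, on a 12 x 12 x 3 um grid
(fast x slow x depth).

From such a band pair this package derives six label-free biomarkers per
subject:

1. **SVN** -- small vessel number (junctions of the high-band network with
   connected-vessel mean diameter < 40 um);
2. **LVN** -- large vessel number (low-band junctions >= 40 um);
3. **TVN** -- total vessel number (SVN + LVN);
4. **TBV** -- total blood volume, `100 * N / T` with `N` the dermal voxels
   above 20% of the dermal maximum intensity and `T` all voxels of the
   4 x 2 x 1.5 mm^3 dermis slab;
5. **epidermal thickness** -- mean width between the segmented epidermis
   boundaries;
6. **epidermal signal density** -- mean intensity per voxel of the
   segmented epidermis.

The per-subject pipeline is: surface detection and flattening ->
epidermis segmentation -> dermis slab -> per-band vessel analysis ->
biomarkers. Cohort statistics then compare the biomarkers across
diabetes-severity groups.

## Layer segmentation

The flattened low-band volume is split into four 0.5 mm stacks along the
slow axis (equal voxel counts; when the slice count does not divide by
four, the leading stacks take the extra slice, e.g. 167 -> 42/42/42/41).
Each stack's sagittal maximum-intensity projection (depth x fast) is
segmented by an exact dynamic program on a per-pixel graph: an edge from
a pixel to the three pixels of the next column within +/-1 row costs
`2 - (g(a) + g(b)) + 1e-5`, where `g` is the column-normalized vertical
intensity gradient -- dark-to-bright polarity for the epidermis top,
bright-to-dark for the bottom. Virtual zero-cost start and end columns
leave the endpoints free, and the bottom boundary is searched at least
two rows below the found top to avoid degenerate coincidence. The four
boundary pairs are smoothed by an 11-column moving average with the
`bottom >= top` constraint re-clamped afterwards.

Thickness is the mean per-column width averaged over stacks (the
"average width" reading, not a geodesic path length); density is summed
intensity over the epidermis voxels divided by their count.

Design notes on points the underlying method leaves open:

* The gradient polarity of the bottom boundary (bright-to-dark) and all
  DP constants are configurable (`rsomConfig()`); the edge-cost form is
  the classic normalized-gradient two-boundary scheme used in layered
  tissue segmentation.
* The surface detector (for flattening) takes, per A-line, the first
  depth at which the 5-voxel-smoothed profile exceeds half its own
  maximum, followed by a 3 x 3 lateral median filter; it is a declared
  stand-in validated on phantoms, since the production detector of the
  imaging system is out of scope here.
* Flattening uses integer-voxel shifts only, so intensities (and all
  intensity-threshold biomarkers) are untouched.

## Dermis slab and the epidermal-bleed guard

The dermis interval starts at the epidermis bottom boundary and extends
1.5 mm deeper (clipped, with a warning, at the grid bottom). One
numerical choice matters: the axial point-spread function smears the
bright epidermis edge over a few depth voxels, and the boundary the DP
finds sits at the *center* of that blurred edge. Without correction the
first rows of the slab carry up to half the epidermal intensity, which
inflates TBV several-fold on phantoms and floods the coronal MIP that
vessel segmentation runs on. The slab therefore excludes its first
`dermis$guard_voxels` rows (default 2, i.e. 6 um -- about three axial
PSF sigmas at the stated 4.5 um axial resolution); the slab end stays at
boundary + 1.5 mm.

## Vessel analysis

Vessel analysis runs per band on the coronal MIP of the dermis slab
(junction markers in this field are conventionally displayed on coronal
MIPs; TBV alone is computed in 3D per its explicit volumetric
definition).

**Matched filter.** Zero-mean Gaussian-profile line kernels at scales
`c(15, 30, 45, 60, 90)` um and 12 orientations over 180 degrees:
cross-section sd `scale/2.355/2`, length `3 * scale`. Each kernel is
normalized by its positive-lobe sum, making the response a contrast in
image-intensity units that is comparable across scales and peaks at the
scale matching the ridge width (an L2 normalization, by contrast, biases
the argmax towards the largest kernel). At the border the local kernel
mean is subtracted so flat regions respond exactly zero everywhere.

**Mask.** Otsu's threshold on the positive responses (absolute override
in config), 1-pixel morphological closing, then a half-maximum
refinement: within each detected component, only pixels whose *image*
intensity reaches half the component maximum are kept. The matched
filter spreads beyond the vessel by roughly the kernel width, whereas
the half-max contour of a blurred tube sits at the true boundary; the
refinement is what makes the diameter estimate accurate to one lateral
voxel on phantoms.

**Skeleton, junctions, diameters.** Zhang--Suen thinning gives a
1-pixel 8-connected skeleton; isolated components shorter than 5 pixels
with no junction are removed (the operative noise rule; attached short
spurs are kept). Junctions are skeleton pixels with Rutovitz crossing
number >= 3 -- at least three branches entering the 8-neighbourhood. A
raw "three or more neighbours" rule would also fire on the double-corner
pixels that 8-connected diagonal runs necessarily contain, producing
periodic false junctions on perfectly straight vessels; crossing-number
pixels are a strict subset of degree->=3 pixels, so the stated invariant
is preserved. Adjacent junction pixels merge into one junction at their
centroid (an X-crossing counts once). Removing junction pixels
partitions the skeleton into segments; the local diameter at a
centerline pixel is twice the Euclidean distance to the nearest
background pixel times the lateral spacing, and a segment's diameter is
the mean over its pixels.

**Counting.** TVN is the junction count; each junction is classified by
the length-weighted mean diameter of its incident segments against the
40 um arteriole/venule cutoff, so `svn + lvn = tvn` by construction.
Per subject, SVN comes from the high-band network, LVN from the
low-band network, and TVN is their sum; TBV is computed on the combined
`low + weight * high` volume. Whether unbranched (junction-free)
components should add one count each is genuinely open; the literal
junction-count rule is the default and `vessels$count_unbranched`
enables the alternative.

## The synthetic phantom

`makeSkinPhantom()` renders a bright epidermis slab (constant or
position-dependent surface depth, optional sinusoidal ridge texture --
cosmetic only, expressed as a fractional intensity modulation) over a
dermis containing hard-cylinder vessels rasterized into their band at
voxel-center resolution. Both volumes are blurred by an anisotropic
Gaussian PSF with sigmas `c(4.5, 18.4, 18.4)/2.355` um (the system's
stated axial/lateral resolutions converted from FWHM) and optionally
corrupted by additive zero-mean Gaussian noise; the noise model is a
choice, as the real system's noise is not characterized here. Ground
truth (boundary surfaces, per-band vessel masks, branch points, analytic
TBV) describes the scene *before* blur and noise.

What the phantom does not emulate: speckle and reconstruction
artifacts, depth-dependent sensitivity, melanin heterogeneity,
motion. Tests passing on phantoms therefore validate the geometry and
the numerics of the pipeline, not its robustness to the full physics of
clinical data.

Phantom tests use grids around 640 x 160 x 84 voxels
(1.9 x 1.9 x 1.0 mm): large enough for a full 1.5 mm dermis below the
epidermis and several-millimetre tubes, small enough that the whole
suite runs in minutes. Recovery on noiseless phantoms: epidermal
thickness within 2 depth voxels (6 um) over the 60--150 um range,
junction counts exact for tubes separated by >= 24 um, diameters within
one lateral voxel (12 um) for tubes >= 36 um, and TBV within the
PSF-blur bound -- the 20%-of-max contour of a blurred cylinder of
diameter `d` extends its radius by about `sigma * sqrt(2 ln 5)` (~12 um
laterally), so the recovered/true ratio is bounded by
`(1 + 2*12/d)` squared and approaches 1 for wide vessels.

## The synthetic cohort

`makeCohort()` draws per-subject biomarker rows from per-group normal
distributions. The healthy (n = 48) and pooled diabetic (n = 95) groups
carry the published cohort statistics for all six biomarkers (e.g. SVN
9.78 +/- 3.41 vs. 3.45 +/- 2.62; TBV 4.21 +/- 1.10 vs. 1.58 +/- 0.90%).
Draws are untruncated by default (`clipAtZero` exists and is off), so
a group like HN can produce slightly negative counts -- a deliberate
trade-off that keeps the first two moments exact.

The severity subgroups are not tabulated in full in the published
results, so their defaults are the package's own choice, fixed once by
a power analysis: NC 5.5 +/- 2.6, LN 2.8 +/- 1.2, HN 0.6 +/- 0.5 for
SVN (with analogous choices for the other biomarkers) reproduce the
reported significance ladder -- healthy/NC at p < 0.01, NC/LN at
p < 0.05, LN/HN at p < 0.001 -- in about 96% of seeds at the reported
subgroup sizes (45/13/12), while keeping the size-weighted subgroup
mixture consistent with the pooled diabetic SVN mean. Two published
inconsistencies are noted: sex splits that do not sum to the group
sizes (proportions of the printed counts are used), and a pooled
diabetic epidermal thickness (81 um) lower than a severity structure in
which the no-complications group is *thicker* than healthy can produce
when pooled; the subgroup defaults follow the severity structure, the
pooled "diabetic" group keeps the printed values, and the two are not
drawn together. Healthy HbA1c is unrecorded in the study table; 5.4 +/-
0.4% (a typical non-diabetic value) is used so covariate-adjusted models
are estimable.

Neuropathy scores are drawn consistently with the grouping rules
(NC: both zero; LN: 1--5; HN: >5 on at least one; the
atherosclerosis group carries neuropathic scores plus the ASCVD flag),
so `assignGroup()` round-trips the generated table exactly.

## Cohort statistics

Two-group comparisons use Shapiro--Wilk at alpha = 0.05 on both samples
to gate between the unpaired two-sided t test (Welch) and the two-sided
Mann--Whitney U test -- the underlying study names the gate but not the
normality test, and Shapiro--Wilk is the conventional choice. The exact
Mann--Whitney distribution is used for `n1 * n2 <= 64` tie-free samples,
the tie/continuity-corrected normal approximation otherwise. Stars map
p exactly: `*` < 0.05, `**` < 0.01, `***` < 0.001. Spearman
correlations use tie-corrected ranks; covariate-adjusted logistic
models report Wald statistics with explicit perfect-separation
diagnostics and drop constant covariates with a warning. The ROC of the
single-biomarker threshold classifier ("diabetic below threshold", the
direction of every vascular effect here) computes AUC by the rank
(Mann--Whitney) identity with midrank tie handling; an independent
trapezoidal integration (`trapezoidAUC()`) must agree to 1e-12 and does.
The classifier threshold maximizes accuracy over cut midpoints. No
multiple-testing correction is applied, matching the source analysis.

At the published SVN parameters the closed-form AUC
`pnorm(dmu / sqrt(sd1^2 + sd2^2))` is 0.9295; 100 simulated replicates
at n = 48/95 average to 0.93, the value `scripts/acceptance.R`
recomputes.

## Known limitations

* Mask thresholding is relative (Otsu on the response): a band
  containing *no* vascular signal at all yields a noise-driven mask and
  meaningless counts. Clinical scans always carry vessels in both
  bands; for pathological inputs set the absolute
  `vessels$mask_threshold` override.
* Vessel topology is quantified only through 2D junction counting on
  coronal MIPs; vessels overlapping in depth merge in projection.
* Diameter accuracy below ~24 um (2 lateral voxels) is
  quantization-limited.
* The band splitter (`bandpassSplit()`) is an ideal zero-phase FFT mask
  for synthetic time series; real pipelines enter at reconstructed
  volumes.
* The DP boundary search assumes one dominant bright layer; strongly
  layered pathologies (e.g. blisters) would need a different graph.
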