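---
title: "Quantifying retinal lesions by mathematical morphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal lesions by mathematical morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Grading non-proliferative diabetic retinopathy (NPDR) from color fundus
photographs rests on counting and measuring lesions: bright lipid
**exudates** and small dark **microaneurysms** (MAs, dilated capillaries of
12–100 µm diameter, resolvable in fundus photographs above roughly 30 µm).
Manual assessment is slow and observer-dependent. `retinoquant` implements
an unsupervised, morphology-based quantification pipeline that turns one
photograph into two numbers per eye:

* the **exudates/disk ratio** — total segmented exudate area divided by the
  optic-disk area, a scale-free burden statistic that cancels pixel
  calibration and camera magnification; and
* the **microaneurysm count**, by either of two interchangeable protocols.

A seeded phantom generator and a two-group comparison stage make the whole
pipeline testable end-to-end without patient data.

# Image model and standardization

All images are resampled bilinearly to a common 685 × 584 working grid, so
that structuring-element radii and size priors have a fixed meaning, and all
analysis runs on the **green channel**, where both bright and dark retinal
lesions have their strongest contrast. Intensities live on a canonical
[0, 1] scale internally; 8-bit conversion happens only at file boundaries,
which avoids double-scaling bugs between stages. The resampling kernel is
not critical for area statistics; bilinear was chosen because it is
deterministic and ring-free. Aspect ratio is not padded: the target grid is
used exactly, and the µm/pixel calibration must be rescaled by
`original_width / 685` (see `rescale_calibration()`).

# Enhancement

Two shared operators prepare the green channel:

* `stretch_contrast()` — the luminance-compensated linear stretch
  $J = a\,(I - I_{\min}) / (I_{\max} - I_{\min})$, clipped to [0, 1]. With
  the default $a = 1$ the observed range maps onto the full scale; $a$ is
  exposed because acquisitions differ in global luminance. A constant image
  has no range and is returned unchanged with a warning.
* `adaptive_equalize()` — contrast-limited adaptive histogram equalization
  (CLAHE): the image is tiled (`tile_grid` per axis, default 8), each
  tile's 256-bin histogram is clipped at `clip_limit` (a *fraction of the
  tile's pixels*, default 0.01), excess mass is redistributed uniformly,
  and each tile's mapping is its clipped CDF; pixels are mapped by bilinear
  blending of the four surrounding tile mappings. Two design points
  matter. First, the mapping is the plain clipped CDF, not the
  minimum-anchored variant used for global equalization — anchoring each
  tile's minimum to zero puts tiles with different content on incompatible
  output ranges and produces severe seams. Second, the clip fraction
  bounds the local contrast gain at `clip_limit × 256` (≈ 2.6 at the
  default), which is what keeps sensor noise from being amplified into
  pseudo-lesions. With `tile_grid = 1, clip_limit = 1` the operator reduces
  to global histogram equalization, which is how it is validated against an
  independent CDF oracle in the tests.

The MA branch additionally uses `top_bottom_hat_enhance()`: the image plus
its top-hat minus its bottom-hat with respect to a disk (default radius
6 px, larger than any expected MA so that opening/closing removes dots but
preserves the long axis of vessels). Small dark structures become darker,
small bright ones brighter, and anything larger than the element is left
alone. Because both hat residues are envelope operators, they roughly
*triple* the amplitude of unsmoothed noise; the MA chain therefore starts
with a 3 × 3 **median** filter (`median3()`). A median rather than a
Gaussian is essential: a Gaussian widens the MA intensity wells, and the
vessel-subtraction step below would then erase the very dots it is meant to
keep.

# Exudate quantification

1. Enhancement: stretch, then CLAHE.
2. **Threshold classification**: foreground where intensity ≥ t. The
   default threshold is Otsu's, computed within the camera field of view
   (estimated by `estimate_fov()`; the dark region outside the aperture
   would otherwise dominate the histogram). Because exudates are a small
   *minority* bright class while the image also contains a sizable dark
   vessel class, a single Otsu cut tends to fall between vessels and
   background. `segment_exudates()` therefore applies Otsu *recursively*:
   while the bright class exceeds `max_foreground` (default 20% — far above
   any plausible exudate burden) the cut is recomputed on that class alone,
   walking the threshold up to the background/lesion boundary. A fixed
   threshold can be supplied instead.
3. **Cleanup**: binary opening (radius 1) plus removal of components under
   5 px (`clean_mask()`); the result is always a subset of the input.
4. **Labeling**: 8-connected components with area, centroid, bounding box
   and circularity $4\pi A / P^2$ (perimeter counted as pixel edges facing
   the background). 8-connectivity avoids splitting diagonal lesion chains.
5. **Optic disk**: the ratio denominator must be reproducible, but disk
   segmentation is a problem of its own; the package offers brightest-
   circular-region detection (smooth, threshold at the 99th percentile,
   largest component within a plausible radius range) plus a manual-mask
   override, and every report records which source was used. The disk —
   itself bright — is excluded from the exudate mask, and any residual
   labeled region overlapping the disk by ≥ 50% of its area is dropped.
6. **Ratio**: Σ region areas / disk area.

# Microaneurysm counting

Shared front end: median → CLAHE → top/bottom-hat; Otsu's threshold
(`otsu_threshold()`, an exhaustive 256-cut scan maximizing the
between-class variance $\omega_0\omega_1(\mu_0-\mu_1)^2$, lowest cut on
ties); `binarize_invert()` makes dark structures — vessels and MAs — white.

**Protocol 1, morphology.** `remove_vessels()` erodes the binary image with
a 2-px disk (anything thinner than the element — the MA dots — vanishes;
vessels survive as their centerlines), dilates the survivor with a 3-px
disk to reconstruct the vessels' original extent, and subtracts this
reconstruction from the input. The sizing logic: at the working scale
vessels are ≥ 4 px wide and segmented MA dots ≤ ~4 px, so the 2-px erosion
is exactly the discriminator; the dilation radius exceeds the erosion
radius by 1 px so reconstruction covers boundary scallops. The remaining
blobs pass the lesion prior (`filter_candidates()`): equivalent diameter
$2\sqrt{A/\pi}$ in 30–100 µm and circularity ≥ 0.5. The lower bound is the
visibility limit (30 µm), not the anatomical minimum (12 µm): smaller MAs
are below what a fundus photograph resolves.

**Protocol 2, circular Hough transform.** The same vessel-free mask —
after dropping components below the minimum resolvable MA area
($\pi (d_{\min}/2)^2$ px) or below the circularity floor, which are
vessel-crossing residues, not candidates — contributes its morphological
boundary as the edge image. Each edge pixel votes for every circle center
it could lie on ($x = a + r\cos\theta$, $y = b + r\sin\theta$), one vote
per accumulator cell per radius: votes are cast through the *unique*
rasterized perimeter offsets of each radius, so a complete drawn circle
attains support ≈ 1 rather than an angular-sampling-dependent pile-up. A
peak is accepted only when its votes reach `support_min` (default 0.5)
times the number of rasterized perimeter pixels at that radius — the
height a complete circle would produce — so a half-circle has support
≈ 0.5 and partial shapes degrade proportionally. Non-maximum suppression
merges accepted peaks within 5 px. Scanned radii span the size prior
(1–5 px at 10 µm/px).

The two protocols are reported separately, never ensembled; `count_mas()`
echoes its full configuration in every report.

# Cohort statistics

Per-group endpoints are summarized as mean ± SD (sample SD, n − 1), and the
two groups are compared with a two-sided **pooled-variance Student t test**
(df = n₁ + n₂ − 2); a Welch variant is one flag away since equal variances
are an assumption, not a fact. Significance is declared at α = 0.05. MA
counts are treated as continuous, as is conventional for this endpoint;
rank-based alternatives are out of scope. `compare_from_summary()`
reconstructs the pooled t from printed summary statistics (n, mean, SD),
which is how published group comparisons can be checked without raw data.

# The phantom generator

`make_phantom()` renders, deterministically for a given spec + seed: a
vignetted background inside a circular 45°-style aperture, a bright optic
disk, dark vessels as random walks leaving the disk (width 4–8 px, wide
enough that the 2-px erosion test discriminates them from dots), bright
irregular exudates (unions of jittered disks), dark circular MAs, then
Gaussian intensity noise and 8-bit quantization. Ground-truth masks are the
ideal pre-noise shapes and are pairwise disjoint by construction.
`make_cohort()` draws per-image Poisson jitter around two spec templates
and emits a manifest with planted truth.

Several generator defaults are deliberate *calibrations* to the detection
defaults, documented as such rather than claimed as biological fact:

* `ma_diameter_um = c(40, 44)`: rasterized radius 2.0–2.2 px, giving
  post-median binary blobs of 8–16 px — above the 30 µm size filter yet
  below the footprint that survives the 2-px erosion. The published
  structuring elements implicitly define the size band the morphology
  protocol can retain; the generator plants MAs inside it.
* MAs are rendered hard-edged: partial-contrast anti-aliased edge pixels
  push the segmented extent across the erosion-survival boundary.
* `noise_sd = 0.01` (on [0, 1]): at 0.02, noise pixels attach to MA blobs
  and occasionally reconstitute erosion-surviving shapes.

What the phantoms do **not** emulate: hemorrhages, drusen, cotton-wool
spots, vessel caliber variation and central reflex, camera optics,
compression artifacts, and the soft texture of real retinal background.
Passing recovery tests on phantoms therefore demonstrates that the
*implementation* realizes the method's stated geometry and statistics — not
that the method attains any particular accuracy on clinical images.

# Numerical choices and degenerate inputs

* Otsu ties break to the lowest maximizing cut; constant images raise a
  degenerate-input error rather than returning an arbitrary threshold.
* Grayscale morphology uses replicated borders, which preserves the
  erosion/dilation duality (bottom-hat(g) = top-hat(1 − g)) up to machine
  precision at the image edge; binary mask morphology uses zero padding,
  the natural convention for masks.
* The Hough accumulator is quantized at 1 px in center and radius; expected
  perimeter counts use the rasterized (not continuous 2πr) pixel count, so
  support is calibrated against discretization.
* Region circularity uses the pixel-edge perimeter; a rasterized disk
  scores ≈ 0.6–0.8 and a 1-px-wide bar ≈ 0.2, which is the separation the
  0.5 floor exploits.
* Empty masks, empty region lists and empty candidate sets flow through as
  empty results, never errors; infeasible phantom placement errors out
  after bounded retries.

# Problem sizes used in validation

The test-suite and the acceptance script validate at the package's working
scale: full 685 × 584 phantoms for all end-to-end recovery checks (Dice,
ratio rank-correlation over 20 phantoms, MA count recovery, a 10 + 10
cohort), 200 × 200 grids with 1–20 planted circles for Hough recovery
(50 replicates), 64 × 64 images for the 200-fold Otsu oracle equivalence,
and 1000 null replicates for the type-I-error calibration of the t
machinery. These sizes were chosen as the smallest at which each property
is meaningfully exercised.

# Known limitations

* The optic-disk detector assumes the disk is the brightest compact region;
  large confluent exudates can defeat it — the manual-mask override exists
  for exactly that case, and the report always names the disk source.
* Counts from the two MA protocols agree on phantoms but need not agree on
  clinical images; they are reported separately by design.
* The recursive-Otsu exudate threshold assumes exudates occupy well under
  20% of the field of view; a fundus dominated by confluent exudation
  should use a fixed threshold.
* Hemorrhage/MA discrimination is not implemented; dark lesions larger than
  the size prior are silently excluded, not classified.
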