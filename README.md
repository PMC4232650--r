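# retinoquant

Computer-aided quantification of retinal lesions in color fundus
photographs of non-proliferative diabetic retinopathy (NPDR). The package
turns one photograph into the two numbers a grader cares about:

* the **exudates/disk ratio** — total segmented exudate area divided by the
  optic-disk area, a scale-free lesion-burden statistic; and
* the **microaneurysm (MA) count**, by two interchangeable protocols:
  Otsu thresholding with morphological vessel subtraction, or a circular
  Hough transform with accumulator-peak validation.

It is aimed at readers of the retinal image-analysis literature who want an
unsupervised, fully inspectable morphology pipeline (no training data), and
at method developers who need a reproducible substrate: a seeded synthetic
fundus-phantom generator with exact ground truth and a two-group cohort
comparison stage are first-class parts of the package.

## The method in brief

Images are standardized to a 685 × 584 working grid; all analysis runs on
the green channel on a canonical [0, 1] scale.

**Exudates.** Luminance-compensated stretch
J = a (I − I_min)/(I_max − I_min), contrast-limited adaptive histogram
equalization, threshold classification (recursive Otsu over the field of
view by default), binary opening + small-component removal, 8-connected
labeling. The optic disk (detected as the brightest compact region, or
supplied as a manual mask) is excluded, and the ratio is
Σ lesion areas / disk area.

**Microaneurysms.** 3 × 3 median, adaptive equalization, then top/bottom-hat
enhancement g + (g − opening) − (closing − g) with a 6-px disk. Otsu's
threshold (exhaustive scan maximizing ω₀ω₁(μ₀ − μ₁)²) and inverted
binarization make dark structures white. Protocol 1 subtracts a vessel
reconstruction — dilate(erode(mask, disk 2 px), disk 3 px) — leaving small
round residues, then applies the 30–100 µm equivalent-diameter and
circularity priors. Protocol 2 feeds the candidate-mask boundary to a
circular Hough transform (x = a + r cos θ, y = b + r sin θ); a peak counts
only if its votes reach half the rasterized perimeter pixel count of that
radius, so partial circles degrade support proportionally.

**Statistics.** Per-group mean ± SD and a two-sided pooled-variance Student
t test at α = 0.05 (Welch variant available).

## Worked example

```r
library(retinoquant)

# a synthetic 685 x 584 fundus phantom: optic disk, vessels,
# 5 exudate blobs, 15 microaneurysms, exact ground truth
ph  <- make_phantom(phantom_spec(seed = 1))
cal <- pixel_calibration(10)          # 10 um per pixel

ex <- quantify_exudates(ph$image)
c(measured = ex$exudates_disk_ratio, planted = ph$truth$totals$true_ratio)
#>  measured   planted
#> 0.4809057 0.5056778

quantify_mas(ph$image, cal, method = "morphology")$count
#> [1] 15
quantify_mas(ph$image, cal, method = "hough")$count
#> [1] 15
ph$truth$totals$ma_count
#> [1] 15
```

The measured ratio of 0.48 against a planted 0.51 reflects conservative
exudate edges after thresholding; the planted 15 microaneurysms are
recovered exactly by both protocols on this phantom.

A whole cohort, from simulation to group comparison:

```r
man <- cmd_simulate("phantoms", n_per_group = 10, seed = 7)     # writes PNGs + manifest
res <- cmd_cohort("phantoms/manifest.csv", out = "report")      # measurements.csv + summary.json
res$comparisons[[1]][c("metric", "t_statistic", "df", "p_value")]
#> $metric
#> [1] "exudates_disk_ratio"
#> $t_statistic
#> [1] -5.431314
#> $df
#> [1] 18
#> $p_value
#> [1] 3.685925e-05
```

(The severe template carries double the moderate lesion load; the negative
t reflects the alphabetical group order moderate − severe.)

A thin shell wrapper with the same subcommands is installed at
`inst/cli/retinoquant`:

```sh
retinoquant simulate --out phantoms --seed 7
retinoquant cohort --manifest phantoms/manifest.csv --out report
retinoquant ma --method hough --out ma.csv phantoms/moderate_01.png
```

## Package layout

| Where | What |
|---|---|
| `R/fundus_io.R` | read/write, standardization, green channel, calibration |
| `R/preprocess.R` | stretch, CLAHE, grayscale morphology, median, hats |
| `R/exudates.R` | segmentation, cleanup, labeling, optic disk, ratio |
| `R/microaneurysms.R` | Otsu, vessel subtraction, size prior, Hough, counting |
| `R/synthetic_fundus.R` | phantom and cohort generators with ground truth |
| `R/stats_report.R` | group summaries, t tests, report writing |
| `R/pipeline.R`, `R/cli.R` | per-image chains and command entry points |
| `vignettes/methods.Rmd` | the model, its assumptions, parameters and limits |
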