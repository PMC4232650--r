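test_that("phantom generation is deterministic and true to its spec", {
  sp <- phantom_spec(seed = 23L, n_exudates = 5L, n_mas = 0L,
                     width = 400L, height = 360L,
                     disk = list(center = c(180, 300), radius = 24,
                                 brightness = 0.95))
  ph1 <- make_phantom(sp)
  ph2 <- make_phantom(sp)
  expect_identical(ph1$image$pixels, ph2$image$pixels)
  expect_identical(ph1$truth, ph2$truth)

  expect_equal(nrow(label_regions(ph1$truth$exudate_mask)$regions), 5L)
  expect_equal(nrow(ph1$truth$ma_centers), 0L)
  expect_equal(ph1$truth$totals$ma_count, 0L)
})

test_that("ground-truth masks are pairwise disjoint and totals consistent", {
  ph <- cached_phantom(1L)
  tr <- ph$truth
  expect_equal(sum(tr$exudate_mask & tr$disk_mask), 0L)
  expect_equal(sum(tr$exudate_mask & tr$vessel_mask), 0L)
  expect_equal(sum(tr$ma_mask & tr$vessel_mask), 0L)
  expect_equal(sum(tr$ma_mask & tr$disk_mask), 0L)
  expect_equal(sum(tr$ma_mask & tr$exudate_mask), 0L)
  expect_equal(tr$totals$exudate_area, sum(tr$exudate_mask))
  expect_equal(tr$totals$disk_area, sum(tr$disk_mask))
  expect_equal(tr$totals$true_ratio,
               tr$totals$exudate_area / tr$totals$disk_area)
  expect_equal(tr$totals$ma_count, nrow(tr$ma_centers))
})

test_that("planted MA diameters respect the spec range", {
  ph <- cached_phantom(6L)
  d_um <- 2 * ph$truth$ma_centers$radius_px * ph$spec$microns_per_pixel
  expect_true(all(d_um >= ph$spec$ma_diameter_um[1] - 1e-9))
  expect_true(all(d_um <= ph$spec$ma_diameter_um[2] + 1e-9))
  expect_error(phantom_spec(ma_diameter_um = c(5, 50)),
               class = "retinoquant_argument_error")
})

test_that("infeasible placement raises a placement error", {
  expect_error(
    make_phantom(phantom_spec(width = 120L, height = 120L, n_mas = 400L,
                              disk = list(center = c(60, 90), radius = 15,
                                          brightness = 0.95),
                              n_vessels = 2L, n_exudates = 0L)),
    class = "retinoquant_placement_error")
})

test_that("cohorts are reproducible with ordered group loads", {
  mod <- phantom_spec(n_exudates = 3L, n_mas = 8L, width = 400L, height = 360L,
                      disk = list(center = c(180, 300), radius = 24,
                                  brightness = 0.95))
  sev <- mod; sev$n_exudates <- 6L; sev$n_mas <- 16L
  c1 <- make_cohort(mod, sev, n_per_group = 3, seed = 5)
  c2 <- make_cohort(mod, sev, n_per_group = 3, seed = 5)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 6L)
  agg <- aggregate(cbind(true_ratio, true_ma_count) ~ group, c1$manifest, mean)
  expect_gt(agg$true_ratio[agg$group == "severe"],
            agg$true_ratio[agg$group == "moderate"])
  expect_gt(agg$true_ma_count[agg$group == "severe"],
            agg$true_ma_count[agg$group == "moderate"])
  expect_error(make_cohort(mod, sev, n_per_group = 1),
               class = "retinoquant_argument_error")
})

test_that("written cohorts round-trip through the file system", {
  dir <- withr::local_tempdir()
  mod <- phantom_spec(n_exudates = 2L, n_mas = 4L, width = 300L, height = 280L,
                      disk = list(center = c(140, 220), radius = 20,
                                  brightness = 0.95))
  res <- make_cohort(mod, mod, n_per_group = 2, seed = 9, out_dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4L)
  expect_true(all(file.exists(man$path)))
  img <- read_fundus(man$path[1])
  expect_identical(img$pixels, res$phantoms[[man$image_id[1]]]$image$pixels)
  gt <- read_mask(file.path(dir, paste0(man$image_id[1], "_disk.png")))
  expect_identical(gt, res$phantoms[[man$image_id[1]]]$truth$disk_mask)
})

test_that("measured ratios rank-correlate with planted ratios", {
  planted <- c(); measured <- c()
  for (s in 1:8) {
    n_ex <- 1L + (s %% 4) * 2L
    ph <- cached_phantom(100L + s, n_exudates = n_ex,
                         exudate_area_px = c(150, 450), n_mas = 0L)
    planted <- c(planted, ph$truth$totals$true_ratio)
    measured <- c(measured, quantify_exudates(ph$image)$exudates_disk_ratio)
  }
  expect_gte(cor(planted, measured, method = "spearman"), 0.9)
})
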