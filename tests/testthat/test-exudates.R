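test_that("threshold segmentation follows its definition", {
  g <- matrix(c(rep(0.9, 8), rep(0.1, 8)), 4, 4)
  m <- segment_exudates(g, threshold = 0.5)
  expect_equal(matrix(as.integer(g >= 0.5), 4), unclass(m)[, ],
               ignore_attr = TRUE)
  expect_true(all(m[g == 0.9] == 1L) && all(m[g == 0.1] == 0L))

  dark <- matrix(runif(25, 0, 0.3), 5)
  expect_true(all(segment_exudates(dark, threshold = 0.5) == 0L))
  expect_error(segment_exudates(g, threshold = 1.5),
               class = "retinoquant_argument_error")
})

test_that("mask cleanup removes specks, keeps solids, never adds pixels", {
  speck <- matrix(0L, 9, 9); speck[5, 5] <- 1L
  expect_true(all(clean_mask(speck, open_radius = 1, min_area = 0) == 0L))

  # opening a solid square by the radius-1 disk (a plus) clips only the four
  # corners; verify against the brute-force opening oracle
  square <- matrix(0L, 15, 15); square[3:13, 3:13] <- 1L
  opened <- brute_dilate_bin(brute_erode_bin(square, 1), 1)
  expect_identical(clean_mask(square, open_radius = 1, min_area = 5), opened)
  expect_equal(sum(square) - sum(opened), 4)

  empty <- matrix(0L, 6, 6)
  expect_identical(clean_mask(empty), empty)

  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rbinom(32 * 32, 1, 0.4), 32, 32)
    out <- clean_mask(m, open_radius = 1, min_area = 3)
    expect_true(all(out <= m))                    # subset of input
    expect_identical(clean_mask(m, open_radius = 0, min_area = 0), m)
  }
})

test_that("labeling is 8-connected, sorted by area, and matches flood fill", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2] <- 1L; m[2, 3] <- 1L                  # 3-pixel blob
  m[7:8, 6:7] <- 1L; m[7, 8] <- 1L                # 5-pixel blob
  lr <- label_regions(m)
  expect_equal(lr$regions$area, c(5L, 3L))

  diag2 <- matrix(0L, 5, 5); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(nrow(label_regions(diag2)$regions), 1L)
  expect_equal(label_regions(diag2)$regions$area, 2L)

  expect_equal(nrow(label_regions(matrix(0L, 4, 4))$regions), 0L)
})

test_that("labeling agrees with the flood-fill oracle on random masks", {
  set.seed(99)
  for (i in 1:200) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.1, 0.6)), 32, 32)
    lr <- label_regions(m)
    oracle <- flood_label(m)
    expect_equal(max(lr$label_grid), max(oracle))
    expect_equal(sum(lr$regions$area), sum(m))
    # same partition: one oracle label per package label and vice versa
    if (max(oracle) > 0) {
      tab <- table(lr$label_grid[m == 1L], oracle[m == 1L])
      expect_true(all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L))
    }
  }
})

test_that("region geometry (centroid, bbox, circularity) is sensible", {
  m <- matrix(0L, 12, 12); m[4:6, 4:6] <- 1L      # 3 x 3 square
  r <- label_regions(m)$regions
  expect_equal(c(r$centroid_row, r$centroid_col), c(5, 5))
  expect_equal(c(r$top, r$left, r$bottom, r$right), c(4L, 4L, 6L, 6L))
  expect_equal(r$circularity, 4 * pi * 9 / 144)   # 12 boundary edges

  bar <- matrix(0L, 12, 30); bar[6, 3:28] <- 1L
  rb <- label_regions(bar)$regions
  expect_lt(rb$circularity, 0.3)                  # elongated, far from a disk
})

test_that("optic disk is found on phantoms and manual masks pass through", {
  ph <- cached_phantom(1L)
  green <- extract_green(ph$image)
  disk <- find_optic_disk(green)
  true_center <- ph$spec$disk$center
  expect_lt(sqrt(sum((disk$center - true_center)^2)), 3)
  expect_lt(abs(disk$area - ph$truth$totals$disk_area) /
              ph$truth$totals$disk_area, 0.1)
  expect_equal(disk$source, "detected")

  manual <- matrix(0L, 40, 40); manual[10:29, 8:32] <- 1L
  md <- find_optic_disk(matrix(0.5, 40, 40) + diag(40) * 1e-3,
                        manual_mask = manual)
  expect_equal(md$area, 500L)
  expect_equal(md$source, "manual")

  expect_error(find_optic_disk(matrix(0.5, 50, 50)),
               class = "retinoquant_detection_error")
})

test_that("exudates/disk ratio is exact arithmetic and drops disk overlap", {
  m <- matrix(0L, 40, 40); m[5:24, 5:19] <- 1L    # 300 px lesion
  disk_mask <- matrix(0L, 40, 40); disk_mask[30:39, 30:39] <- 1L
  disk <- find_optic_disk(matrix(0.5, 40, 40), manual_mask = disk_mask)
  rep <- exudate_disk_ratio(label_regions(m), disk)
  expect_equal(rep$exudates_disk_ratio, 3.0)
  expect_equal(rep$n_lesions, 1L)

  rep0 <- exudate_disk_ratio(label_regions(matrix(0L, 40, 40)), disk)
  expect_equal(rep0$exudates_disk_ratio, 0)
  expect_equal(rep0$n_lesions, 0L)

  # a region sitting mostly on the disk is excluded
  on_disk <- matrix(0L, 40, 40); on_disk[31:36, 31:36] <- 1L
  expect_message(repd <- exudate_disk_ratio(label_regions(on_disk), disk),
                 "overlap")
  expect_equal(repd$n_lesions, 0L)
})

test_that("ratio is invariant under simultaneous 2x upsampling", {
  ph <- cached_phantom(3L)
  ex <- ph$truth$exudate_mask; dk <- ph$truth$disk_mask
  up <- function(m) kronecker(m, matrix(1L, 2, 2))
  r1 <- sum(ex) / sum(dk)
  r2 <- sum(up(ex)) / sum(up(dk))
  expect_equal(r2, r1, tolerance = 0.05)
})

test_that("planted exudates are recovered through the full chain", {
  ph <- cached_phantom(2L)
  rep <- quantify_exudates(ph$image)
  truth <- ph$truth
  inter <- sum(rep$mask == 1L & truth$exudate_mask == 1L)
  dice <- 2 * inter / (sum(rep$mask) + sum(truth$exudate_mask))
  expect_gte(inter / sum(truth$exudate_mask), 0.9)   # planted-pixel overlap
  expect_gte(dice, 0.8)
  expect_equal(rep$exudates_disk_ratio, truth$totals$true_ratio,
               tolerance = 0.15)
})
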