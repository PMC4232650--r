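test_that("Otsu matches the exhaustive brute-force scan", {
  # two-level image: threshold must fall strictly between the levels
  vals <- c(rep(50 / 256, 10), rep(200 / 256, 10))
  ot <- otsu_threshold(matrix(vals, 4, 5))
  expect_gt(ot$threshold, 50 / 256)
  expect_lte(ot$threshold, 200 / 256)
  expect_equal(ot$t_index, brute_otsu_index(vals))

  set.seed(3)
  for (i in 1:20) {
    vals <- runif(64 * 64)^runif(1, 0.5, 2)
    ot <- otsu_threshold(matrix(vals, 64, 64))
    expect_identical(ot$t_index, brute_otsu_index(vals))
  }
  expect_error(otsu_threshold(matrix(0.5, 8, 8)),
               class = "retinoquant_degenerate_error")
})

test_that("Otsu result satisfies its own invariants", {
  set.seed(4)
  vals <- rbeta(4096, 2, 5)
  ot <- otsu_threshold(matrix(vals, 64, 64))
  expect_equal(sum(ot$class_probs), 1)
  expect_equal(sum(ot$histogram), 4096L)
  expect_gte(ot$between_class_variance, 0)
})

test_that("inverted binarization marks dark structures as foreground", {
  g <- matrix(0.9, 6, 6); g[2:3, 4] <- 0.1
  m <- binarize_invert(g, 0.5)
  expect_equal(sum(m), 2L)
  expect_true(all(m[g == 0.1] == 1L))
  expect_true(all(binarize_invert(g, 0.05) == 0L))     # below global minimum
  expect_error(binarize_invert(g, 0), class = "retinoquant_argument_error")

  set.seed(8)
  for (i in 1:10) {
    g <- matrix(runif(100), 10, 10)
    t <- runif(1, 0.2, 0.8)
    expect_identical(binarize_invert(g, t),
                     matrix(1L - as.integer(g > t), 10, 10))
  }
})

test_that("vessel subtraction keeps dots and deletes bars", {
  h <- 40; w <- 120
  dot <- matrix(0L, h, w)
  dot[20:22, 20:22] <- 1L; dot[19, 21] <- 1L; dot[23, 21] <- 1L  # ~3 px dot
  out <- remove_vessels(dot)
  expect_identical(out, dot)                      # fully retained

  bar <- matrix(0L, h, w)
  bar[17:23, 10:109] <- 1L                        # 7 px x 100 px vessel
  out <- remove_vessels(bar)
  expect_lt(sum(out) / sum(bar), 0.05)

  expect_identical(remove_vessels(matrix(0L, 10, 10)), matrix(0L, 10, 10))
})

test_that("vessel subtraction equals its morphological definition (oracle)", {
  set.seed(17)
  m <- matrix(0L, 30, 30)
  m[5:9, 5:25] <- 1L                              # thick bar
  m[20:21, 8:9] <- 1L                             # small blob
  m[cbind(sample(30, 6), sample(30, 6))] <- 1L    # specks
  vessels <- brute_dilate_bin(brute_erode_bin(m, 2), 3)
  expect_identical(remove_vessels(m),
                   matrix(as.integer(m == 1L & vessels == 0L), 30, 30))
  out <- remove_vessels(m)
  expect_true(all(out <= m))                      # subset invariant
})

test_that("size/circularity filter applies the 30-100 um diameter prior", {
  cal <- pixel_calibration(10)
  m <- matrix(0L, 60, 60)
  m[5:9, 5:9] <- 1L                               # 25 px -> ~56 um, round
  m[30, 10:49] <- 1L                              # bar: big + non-circular
  m[50, 50] <- 1L                                 # 1 px -> ~11 um
  lr <- label_regions(m)
  kept <- filter_candidates(lr, cal)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$area, 25L)
  expect_equal(kept$equiv_diameter_um, 2 * sqrt(25 / pi) * 10)

  # 300 px region at 10 um/px -> 195 um equivalent diameter, rejected
  big <- matrix(0L, 40, 40); big[11:30, 11:25] <- 1L
  expect_equal(nrow(filter_candidates(label_regions(big), cal)), 0L)
  expect_equal(nrow(filter_candidates(label_regions(matrix(0L, 5, 5)), cal)), 0L)
})

test_that("Hough transform recovers drawn circles exactly", {
  expect_equal(nrow(hough_circles(matrix(0L, 50, 50), radii = 3:6)), 0L)
  expect_error(hough_circles(matrix(0L, 10, 10), radii = integer()),
               class = "retinoquant_argument_error")

  m <- matrix(0L, 100, 100)
  m <- draw_circle(m, 40, 40, 10)
  cand <- hough_circles(m, radii = 3:12)
  expect_equal(nrow(cand), 1L)
  expect_lte(sqrt((cand$row - 40)^2 + (cand$col - 40)^2), 1)
  expect_lte(abs(cand$radius - 10), 1)
  expect_gte(cand$support, 0.9)

  m2 <- matrix(0L, 120, 120)
  m2 <- draw_circle(m2, 30, 30, 5)
  m2 <- draw_circle(m2, 80, 85, 9)
  cand2 <- hough_circles(m2, radii = 3:12)
  expect_equal(nrow(cand2), 2L)
  cand2 <- cand2[order(cand2$radius), ]
  expect_lte(abs(cand2$radius[1] - 5), 1)
  expect_lte(abs(cand2$radius[2] - 9), 1)
})

test_that("partial circles degrade support proportionally", {
  full <- draw_circle(matrix(0L, 100, 100), 50, 50, 10)
  half <- draw_circle(matrix(0L, 100, 100), 50, 50, 10, arc = c(0, pi))
  s_full <- hough_circles(full, radii = 8:12, support_min = 0.2)$support[1]
  s_half <- hough_circles(half, radii = 8:12, support_min = 0.2)$support[1]
  expect_equal(s_half, s_full / 2, tolerance = 0.2)
  expect_lte(abs(s_half - 0.5), 0.1)
})

test_that("accumulator bookkeeping is consistent with the stamp scheme", {
  m <- draw_circle(matrix(0L, 60, 60), 30, 30, 6)
  cand <- hough_circles(m, radii = 5:7, return_accumulator = TRUE)
  acc <- attr(cand, "accumulator")
  expect_equal(acc$edge_count, sum(m))
  expect_true(all(vapply(acc$votes, min, 0) >= 0))
  # one vote per edge pixel per cell at most: peak cannot exceed edge count
  expect_lte(max(vapply(acc$votes, max, 0)), acc$edge_count)
})

test_that("both protocols recover planted microaneurysm counts", {
  cal <- pixel_calibration(10)
  ph <- cached_phantom(1L)
  truth_n <- ph$truth$totals$ma_count
  morph <- quantify_mas(ph$image, cal, "morphology")
  hough <- quantify_mas(ph$image, cal, "hough")
  expect_lte(abs(morph$count - truth_n), 2)
  expect_lte(abs(hough$count - truth_n), 2)
  # most hough detections sit on planted centers
  tc <- ph$truth$ma_centers
  hits <- vapply(seq_len(nrow(tc)), function(i)
    any(sqrt((hough$candidates$row - tc$row[i])^2 +
             (hough$candidates$col - tc$col[i])^2) <= 2), TRUE)
  expect_gte(mean(hits), 0.8)

  clean <- cached_phantom(50L, n_exudates = 0L, n_mas = 0L)
  expect_lte(quantify_mas(clean$image, cal, "morphology")$count, 1)
  expect_lte(quantify_mas(clean$image, cal, "hough")$count, 1)
})
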