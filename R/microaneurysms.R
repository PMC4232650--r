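# Microaneurysm detection by two interchangeable protocols: (1) Otsu
# thresholding + morphological vessel subtraction, (2) circular Hough
# transform with accumulator-peak validation against the expected number of
# perimeter edge pixels.

# Otsu's method on a vector of intensities in [0, 1], quantized to 256 bins.
# Exhaustive scan of all 256 cut points; the between-class variance
# w0 * w1 * (mu0 - mu1)^2 is maximized (equivalently the intra-class variance
# minimized), ties broken by the lowest threshold.
otsu_core <- function(values) {
  bin <- pmin(floor(values * 256), 255)            # 0-based bin of each pixel
  n_i <- tabulate(bin + 1L, nbins = 256L)
  abort_if(sum(n_i > 0L) < 2L, "constant image: Otsu threshold undefined",
           "retinoquant_degenerate_error")
  n <- sum(n_i)
  p <- n_i / n
  lev <- 0:255
  w0 <- cumsum(p)                                  # class C0 = bins 0..t
  mu_cum <- cumsum(p * lev)
  mu_tot <- mu_cum[256]
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, mu_cum / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu_tot - mu_cum) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  t_star <- which.max(sigma_b) - 1L                # lowest maximizer (0-based)
  structure(list(
    threshold = (t_star + 1L) / 256,               # boundary between bins t, t+1
    t_index = t_star,
    class_probs = c(w0[t_star + 1L], w1[t_star + 1L]),
    class_means = c(mu0[t_star + 1L] / 255, mu1[t_star + 1L] / 255),
    between_class_variance = sigma_b[t_star + 1L],
    histogram = n_i
  ), class = "otsu_result")
}

#' Otsu threshold of an intensity image
#'
#' Quantizes the image to 256 gray levels and scans all 256 candidate cut
#' points exhaustively, returning the one that maximizes the between-class
#' variance w0 * w1 * (mu0 - mu1)^2 of the two classes it induces (the lowest
#' such cut on ties). The returned threshold is the bin boundary on the
#' [0, 1] scale: pixels strictly below it form class C0.
#'
#' @param gray numeric matrix in [0, 1] with at least two distinct quantized
#'   values.
#' @return a list of class `otsu_result`: threshold, class_probs,
#'   class_means, between_class_variance, histogram (the 256 bin counts).
#' @export
otsu_threshold <- function(gray) {
  check_gray(gray)
  otsu_core(as.numeric(gray))
}

#' Inverted binarization
#'
#' Foreground where intensity <= t, so that dark structures — vessels and
#' microaneurysms — become white in the binary image.
#'
#' @param gray numeric matrix in [0, 1].
#' @param t threshold in (0, 1).
#' @return a 0/1 matrix.
#' @export
binarize_invert <- function(gray, t) {
  check_gray(gray)
  abort_if(!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1,
           "`t` must be in (0, 1)", "retinoquant_argument_error")
  matrix(as.integer(gray <= t), nrow(gray))
}

#' Subtract vessels from an inverted binary image
#'
#' Erosion with a 2-pixel disk erases anything thinner than the element —
#' microaneurysm dots — while vessels survive; dilating the survivor with a
#' slightly larger disk reconstructs the vessels' original extent, and
#' subtracting this reconstruction from the input leaves the small round
#' residues. The output is always a subset of the input foreground.
#'
#' @param mask 0/1 matrix (dark structures as foreground).
#' @param erode_radius disk radius of the vessel-estimating erosion.
#' @param dilate_radius extra radius for the reconstruction dilation (the
#'   dilation disk has radius `erode_radius + dilate_radius`).
#' @param dilate_difference if TRUE, use the alternative reading — dilate the
#'   erosion residue itself — retained for comparison only; it inflates noise.
#' @return the vessel-free 0/1 matrix.
#' @export
remove_vessels <- function(mask, erode_radius = 2L, dilate_radius = 1L,
                           dilate_difference = FALSE) {
  check_mask(mask)
  m <- matrix(as.numeric(mask), nrow(mask))
  er <- EBImage::erode(m, disk_element(erode_radius))
  if (dilate_difference) {
    diff <- matrix(as.numeric(m > 0.5 & er < 0.5), nrow(mask))
    out <- EBImage::dilate(diff, disk_element(max(1L, dilate_radius)))
    return(matrix(as.integer(out > 0.5 & m > 0.5), nrow(mask)))
  }
  vessels <- EBImage::dilate(er, disk_element(erode_radius + dilate_radius))
  matrix(as.integer(m > 0.5 & vessels < 0.5), nrow(mask))
}

#' Filter candidate regions by the microaneurysm size prior
#'
#' Microaneurysms are 12-100 um in diameter and resolvable in fundus
#' photographs above about 30 um. Regions are kept when their equivalent
#' diameter 2 * sqrt(area / pi), converted to microns through the pixel
#' calibration, lies within [d_min_um, d_max_um] and their circularity is at
#' least `min_circularity`.
#'
#' @param regions the region table of a `labeled_regions` object (or the
#'   object itself).
#' @param cal a [pixel_calibration()].
#' @param d_min_um,d_max_um diameter bounds in microns.
#' @param min_circularity minimum circularity, in (0, 1].
#' @return the retained rows of the region table, with an
#'   `equiv_diameter_um` column added.
#' @export
filter_candidates <- function(regions, cal, d_min_um = 30, d_max_um = 100,
                              min_circularity = 0.5) {
  if (inherits(regions, "labeled_regions")) regions <- regions$regions
  abort_if(!inherits(cal, "pixel_calibration"),
           "`cal` must be a pixel_calibration", "retinoquant_argument_error")
  if (nrow(regions) == 0L) {
    regions$equiv_diameter_um <- numeric(0)
    return(regions)
  }
  d_um <- 2 * sqrt(regions$area / pi) * cal$microns_per_pixel
  regions$equiv_diameter_um <- d_um
  keep <- d_um >= d_min_um & d_um <= d_max_um &
    regions$circularity >= min_circularity
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# unique rasterized perimeter offsets of a circle of radius r
# (360 angular samples, 1-degree steps, rounded to the pixel grid)
circle_offsets <- function(r) {
  theta <- (0:359) * pi / 180
  off <- unique(cbind(round(r * sin(theta)), round(r * cos(theta))))
  off
}

#' Circular Hough transform with perimeter-support validation
#'
#' Every edge pixel votes for the circle centers it could lie on,
#' x = a + r cos(theta), y = b + r sin(theta), one vote per accumulator cell
#' per radius. A peak is accepted only if its votes reach `support_min` times
#' the number of rasterized perimeter pixels at that radius — the height a
#' complete circle would produce — so partial circles degrade support in
#' proportion to their missing arc. Accepted peaks within `nms_dist` pixels
#' of a stronger peak are suppressed.
#'
#' @param edge_mask 0/1 matrix of edge pixels (e.g. a candidate-mask
#'   boundary).
#' @param radii integer radii to scan, all >= 1.
#' @param support_min minimum support (votes / expected perimeter pixels).
#' @param nms_dist non-maximum-suppression radius in pixels.
#' @param return_accumulator if TRUE, attach the per-radius vote grids as
#'   attribute `"accumulator"`.
#' @return a data.frame of class `circle_candidates`: row, col, radius,
#'   votes, support — one row per accepted circle.
#' @export
hough_circles <- function(edge_mask, radii, support_min = 0.5, nms_dist = 5,
                          return_accumulator = FALSE) {
  check_mask(edge_mask, "edge_mask")
  abort_if(length(radii) == 0L || any(radii < 1),
           "`radii` must be a nonempty set of radii >= 1",
           "retinoquant_argument_error")
  h <- nrow(edge_mask); w <- ncol(edge_mask)
  idx <- which(edge_mask == 1L)
  cand <- list(); acc <- list()
  if (length(idx) > 0L) {
    er <- (idx - 1L) %% h + 1L
    ec <- (idx - 1L) %/% h + 1L
    for (k in seq_along(radii)) {
      off <- circle_offsets(radii[k])
      noff <- nrow(off)
      cr <- rep(er, each = noff) + off[, 1]
      cc <- rep(ec, each = noff) + off[, 2]
      ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
      votes <- tabulate(cr[ok] + h * (cc[ok] - 1L), nbins = h * w)
      if (return_accumulator) acc[[k]] <- matrix(votes, h, w)
      hit <- which(votes >= support_min * noff)
      if (length(hit))
        cand[[length(cand) + 1L]] <- data.frame(
          row = (hit - 1L) %% h + 1L, col = (hit - 1L) %/% h + 1L,
          radius = radii[k], votes = votes[hit],
          support = votes[hit] / noff)
    }
  }
  if (length(cand) == 0L) {
    out <- data.frame(row = integer(), col = integer(), radius = numeric(),
                      votes = integer(), support = numeric())
  } else {
    all_c <- do.call(rbind, cand)
    all_c <- all_c[order(-all_c$support, -all_c$votes, all_c$row, all_c$col), ]
    keep <- logical(nrow(all_c))
    kr <- numeric(0); kc <- numeric(0)
    for (i in seq_len(nrow(all_c))) {
      if (length(kr) == 0L ||
          min((kr - all_c$row[i])^2 + (kc - all_c$col[i])^2) > nms_dist^2) {
        keep[i] <- TRUE
        kr <- c(kr, all_c$row[i]); kc <- c(kc, all_c$col[i])
      }
    }
    out <- all_c[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("circle_candidates", "data.frame")
  if (return_accumulator)
    attr(out, "accumulator") <- list(votes = acc, radii = radii,
                                     edge_count = length(idx))
  out
}

ma_config_defaults <- function(config = list()) {
  defaults <- list(erode_radius = 2L, dilate_radius = 1L,
                   d_min_um = 30, d_max_um = 100, min_circularity = 0.5,
                   support_min = 0.5, nms_dist = 5,
                   dilate_difference = FALSE)
  defaults[names(config)] <- config
  defaults
}

#' Count microaneurysms in an enhanced green channel
#'
#' Runs one of the two detection protocols on a green channel that has been
#' through the microaneurysm preprocessing chain (adaptive equalization, then
#' top/bottom-hat enhancement; see [ma_preprocess()]):
#' \describe{
#'   \item{morphology}{Otsu threshold, inverted binarization, vessel
#'     subtraction, 8-connected labeling, then the 30-100 um size and
#'     circularity filter.}
#'   \item{hough}{the same candidate mask's boundary fed to
#'     [hough_circles()] with radii spanning the microaneurysm size prior.}
#' }
#'
#' @param green numeric matrix in [0, 1], the preprocessed green channel.
#' @param cal a [pixel_calibration()].
#' @param method "morphology" or "hough".
#' @param config named list overriding the defaults: erode_radius,
#'   dilate_radius, d_min_um, d_max_um, min_circularity, support_min,
#'   nms_dist, dilate_difference.
#' @param fov_mask optional 0/1 field-of-view mask; candidates outside it are
#'   discarded.
#' @return a list of class `ma_report`: count, candidates (a data.frame),
#'   method, params_used.
#' @export
count_mas <- function(green, cal, method = c("morphology", "hough"),
                      config = list(), fov_mask = NULL) {
  method <- match.arg(method)
  check_gray(green, "green")
  abort_if(!inherits(cal, "pixel_calibration"),
           "`cal` must be a pixel_calibration", "retinoquant_argument_error")
  cfg <- ma_config_defaults(config)
  ot <- otsu_threshold(green)
  bw <- binarize_invert(green, ot$threshold)
  bw <- remove_vessels(bw, cfg$erode_radius, cfg$dilate_radius,
                       cfg$dilate_difference)
  if (!is.null(fov_mask)) bw <- bw * (fov_mask == 1)
  if (method == "morphology") {
    lr <- label_regions(bw)
    cands <- filter_candidates(lr, cal, cfg$d_min_um, cfg$d_max_um,
                               cfg$min_circularity)
  } else {
    # the size-and-shape prior applies to the candidate mask too: residues
    # smaller than the smallest resolvable MA (area < pi * (d_min/2)^2) or
    # clearly elongated (vessel-crossing leftovers) are not candidates
    min_area <- floor(pi * (cfg$d_min_um / cal$microns_per_pixel / 2)^2)
    if (any(bw == 1L)) {
      lr0 <- label_regions(bw)
      drop <- lr0$regions$id[lr0$regions$area < min_area |
                               lr0$regions$circularity < cfg$min_circularity]
      if (length(drop)) bw[lr0$label_grid %in% drop] <- 0L
    }
    inner <- EBImage::erode(matrix(as.numeric(bw), nrow(bw)), disk_element(1L))
    edge <- matrix(as.integer(bw > 0.5 & inner < 0.5), nrow(bw))
    r_lo <- max(1L, floor(cfg$d_min_um / cal$microns_per_pixel / 2))
    r_hi <- max(r_lo, ceiling(cfg$d_max_um / cal$microns_per_pixel / 2))
    cands <- hough_circles(edge, radii = r_lo:r_hi,
                           support_min = cfg$support_min,
                           nms_dist = cfg$nms_dist)
  }
  structure(list(count = nrow(cands), candidates = cands, method = method,
                 params_used = c(cfg, list(otsu_threshold = ot$threshold))),
            class = "ma_report")
}

#' Microaneurysm preprocessing chain
#'
#' Median denoising, adaptive histogram equalization, then top/bottom-hat
#' enhancement. The denoising step matters because the two hat residues are
#' envelope operators: on raw sensor noise they each return roughly the
#' local noise amplitude, and their sum triples the noise swing around the
#' background before thresholding. A median (rather than Gaussian) filter is
#' used because it suppresses noise without widening the microaneurysm
#' wells — a Gaussian would spread them past the 2-px erosion that the
#' vessel-subtraction step relies on to tell dots from vessels.
#'
#' @param green green channel, numeric matrix in [0, 1].
#' @param tile_grid,clip_limit see [adaptive_equalize()].
#' @param hat_radius disk radius for [top_bottom_hat_enhance()].
#' @param denoise whether to apply the 3 x 3 median ([median3()]) first.
#' @return the enhanced image.
#' @export
ma_preprocess <- function(green, tile_grid = 8L, clip_limit = 0.01,
                          hat_radius = 6L, denoise = TRUE) {
  if (denoise) green <- median3(green)
  green |>
    adaptive_equalize(tile_grid = tile_grid, clip_limit = clip_limit) |>
    top_bottom_hat_enhance(disk_element(hat_radius))
}
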