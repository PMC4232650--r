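# Exudate segmentation and quantification: threshold classification of the
# enhanced green channel, morphological cleanup, connected-component labeling,
# optic-disk localization, and the scale-free exudates/disk area ratio.

#' Threshold segmentation of bright exudate lesions
#'
#' Classifies pixels of the enhanced green channel as exudate where intensity
#' >= threshold. With `threshold = "otsu"` the cut is chosen by
#' [otsu_threshold()]; an optional field-of-view mask restricts the histogram
#' to the retina, keeping the dark region outside the camera aperture from
#' dominating it. The optic disk is bright too and must be excluded downstream
#' (see [exudate_disk_ratio()]).
#'
#' Exudates occupy a small bright minority of the retina; a single Otsu cut
#' on an image that also contains dark vessels tends to separate the vessels
#' from the background instead. In "otsu" mode the cut is therefore applied
#' recursively: while the bright class still covers more than
#' `max_foreground` of the histogram, Otsu is re-run on that class alone,
#' walking the threshold up to the background/lesion boundary.
#'
#' @param enhanced numeric matrix in [0, 1], output of the exudate
#'   preprocessing chain.
#' @param threshold a value in (0, 1), or "otsu".
#' @param fov_mask optional 0/1 matrix marking the field of view.
#' @param max_foreground largest plausible bright-class fraction used by the
#'   recursive Otsu rule.
#' @return a 0/1 matrix; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
segment_exudates <- function(enhanced, threshold = "otsu", fov_mask = NULL,
                             max_foreground = 0.2) {
  check_gray(enhanced, "enhanced")
  if (identical(threshold, "otsu")) {
    vals <- if (is.null(fov_mask)) as.numeric(enhanced) else enhanced[fov_mask == 1]
    threshold <- otsu_core(vals)$threshold
    for (i in 1:3) {
      upper <- vals[vals >= threshold]
      if (mean(vals >= threshold) <= max_foreground ||
          sum(tabulate(pmin(floor(upper * 256), 255) + 1L, 256L) > 0L) < 2L)
        break
      threshold <- otsu_core(upper)$threshold
    }
  } else {
    abort_if(!is.numeric(threshold) || length(threshold) != 1L ||
               threshold <= 0 || threshold >= 1,
             "`threshold` must be in (0, 1) or \"otsu\"",
             "retinoquant_argument_error")
  }
  mask <- matrix(as.integer(enhanced >= threshold), nrow(enhanced))
  if (!is.null(fov_mask)) mask <- mask * (fov_mask == 1)
  structure(mask, threshold = threshold)
}

#' Morphological cleanup of a segmentation mask
#'
#' Binary opening with a disk followed by removal of components smaller than
#' `min_area` pixels, discarding speckle noise. Never adds foreground: the
#' result is a subset of the input. With `open_radius = 0` and `min_area = 0`
#' this is the identity.
#'
#' @param mask a 0/1 matrix.
#' @param open_radius radius of the opening disk (0 skips the opening).
#' @param min_area smallest component area kept, in pixels.
#' @return the cleaned 0/1 matrix.
#' @export
clean_mask <- function(mask, open_radius = 1L, min_area = 5L) {
  check_mask(mask)
  out <- matrix(as.numeric(mask), nrow(mask))
  if (open_radius >= 1) {
    el <- disk_element(open_radius)
    out <- EBImage::dilate(EBImage::erode(out, el), el)
  }
  out <- matrix(as.integer(out > 0.5), nrow(mask))
  if (min_area > 0 && any(out == 1L)) {
    lab <- label_regions(out)
    drop <- lab$regions$id[lab$regions$area < min_area]
    if (length(drop)) out[lab$label_grid %in% drop] <- 0L
  }
  out
}

# merge 4-connected labels that touch diagonally (union-find over label ids)
merge_diagonal <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  if (h < 2L || w < 2L) return(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right neighbors
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # up-right neighbors
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, 0L)
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Label connected components and measure regions
#'
#' 8-connected component labeling of a binary mask with per-region area,
#' centroid, bounding box and circularity (4 * pi * area / perimeter^2, with
#' the perimeter counted as pixel edges bordering the background). Regions are
#' sorted by decreasing area, ties broken by bounding-box (top, left), and the
#' label grid is renumbered to match.
#'
#' @param mask a 0/1 matrix.
#' @return a list of class `labeled_regions` with `label_grid` (integer
#'   matrix, 0 = background) and `regions` (a data.frame with one row per
#'   region: id, area, centroid_row, centroid_col, top, left, bottom, right,
#'   perimeter, circularity).
#' @export
label_regions <- function(mask) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  empty <- data.frame(id = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      top = integer(), left = integer(),
                      bottom = integer(), right = integer(),
                      perimeter = integer(), circularity = numeric())
  if (!any(mask == 1L))
    return(structure(list(label_grid = matrix(0L, h, w), regions = empty),
                     class = "labeled_regions"))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), h, w))   # 4-connected
  lab <- merge_diagonal(matrix(as.integer(lab), h, w))
  ids <- sort(unique(lab[lab > 0]))
  lab <- matrix(match(lab, c(0L, ids), nomatch = 1L) - 1L, h, w)
  k <- length(ids)
  idx <- which(lab > 0)
  rr <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  lv <- lab[idx]
  area <- tabulate(lv, k)
  # perimeter: for each foreground pixel, 4-neighbors that are background/out
  nb <- function(dr, dc) {
    r2 <- rr + dr; c2 <- cc + dc
    out <- r2 < 1L | r2 > h | c2 < 1L | c2 > w
    inb <- !out
    bgn <- logical(length(idx))
    bgn[inb] <- mask[cbind(r2[inb], c2[inb])] == 0L
    out | bgn
  }
  per_px <- nb(-1L, 0L) + nb(1L, 0L) + nb(0L, -1L) + nb(0L, 1L)
  perim <- as.integer(rowsum(as.numeric(per_px), lv)[, 1])
  reg <- data.frame(
    id = seq_len(k), area = area,
    centroid_row = rowsum(as.numeric(rr), lv)[, 1] / area,
    centroid_col = rowsum(as.numeric(cc), lv)[, 1] / area,
    top = as.integer(tapply(rr, lv, min)), left = as.integer(tapply(cc, lv, min)),
    bottom = as.integer(tapply(rr, lv, max)), right = as.integer(tapply(cc, lv, max)),
    perimeter = perim,
    circularity = 4 * pi * area / pmax(perim, 1L)^2
  )
  ord <- order(-reg$area, reg$top, reg$left)
  reg <- reg[ord, , drop = FALSE]
  remap <- integer(k); remap[reg$id] <- seq_len(k)
  reg$id <- seq_len(k)
  rownames(reg) <- NULL
  lab[idx] <- remap[lv]
  structure(list(label_grid = lab, regions = reg), class = "labeled_regions")
}

#' Estimate the camera field of view
#'
#' The retina occupies a bright disc inside a dark aperture; a low fixed
#' threshold on the smoothed green channel separates the two.
#'
#' @param green numeric matrix in [0, 1].
#' @param threshold intensity cut separating aperture from retina.
#' @return a 0/1 matrix marking the field of view.
#' @export
estimate_fov <- function(green, threshold = 0.1) {
  check_gray(green, "green")
  sm <- EBImage::gblur(green, sigma = 3)
  matrix(as.integer(sm > threshold), nrow(green))
}

#' Locate the optic disk
#'
#' The denominator of the exudates/disk ratio. A manual mask, when given, is
#' used verbatim; otherwise the brightest circular region is detected: the
#' smoothed green channel is thresholded at its 99th intensity percentile, the
#' largest component whose equivalent radius falls in `radius_range` is taken,
#' and the component's own pixel count is the disk area.
#'
#' @param green numeric matrix in [0, 1].
#' @param radius_range plausible disk radii in pixels, c(min, max).
#' @param manual_mask optional 0/1 matrix of a hand-drawn disk.
#' @param smooth_sigma Gaussian smoothing before thresholding.
#' @param percentile intensity quantile for the brightness threshold.
#' @return a list of class `optic_disk`: mask, area (px), center (row, col),
#'   equivalent radius, and source ("detected" or "manual").
#' @export
find_optic_disk <- function(green, radius_range = c(12, 80), manual_mask = NULL,
                            smooth_sigma = 3, percentile = 0.99) {
  check_gray(green, "green")
  if (!is.null(manual_mask)) {
    check_mask(manual_mask, "manual_mask")
    area <- sum(manual_mask == 1L)
    abort_if(area == 0L, "`manual_mask` is empty", "retinoquant_argument_error")
    idx <- which(manual_mask == 1L)
    ctr <- c(mean((idx - 1L) %% nrow(manual_mask) + 1L),
             mean((idx - 1L) %/% nrow(manual_mask) + 1L))
    return(structure(list(mask = manual_mask, area = area, center = ctr,
                          r_eq = sqrt(area / pi), source = "manual"),
                     class = "optic_disk"))
  }
  sm <- EBImage::gblur(green, sigma = smooth_sigma)
  thr <- quantile(sm, percentile, names = FALSE)
  bw <- matrix(as.integer(sm >= thr & sm > min(sm)), nrow(green))
  lr <- label_regions(bw)
  reg <- lr$regions
  reg <- reg[sqrt(reg$area / pi) >= radius_range[1] &
             sqrt(reg$area / pi) <= radius_range[2], , drop = FALSE]
  abort_if(nrow(reg) == 0L,
           "optic disk not detected; supply a manual mask",
           "retinoquant_detection_error")
  best <- reg[1L, ]   # regions already sorted by decreasing area
  mask <- matrix(as.integer(lr$label_grid == best$id), nrow(green))
  structure(list(mask = mask, area = best$area,
                 center = c(best$centroid_row, best$centroid_col),
                 r_eq = sqrt(best$area / pi), source = "detected"),
            class = "optic_disk")
}

#' Exudate burden relative to the optic disk
#'
#' Total segmented exudate area divided by the optic-disk area — a scale-free
#' lesion-burden statistic that cancels pixel calibration. Any labeled region
#' overlapping the disk mask by 50% or more of its own area is dropped (with a
#' message): the disk is bright and would otherwise count as exudate.
#'
#' @param regions a `labeled_regions` object of exudate candidates.
#' @param disk an `optic_disk`.
#' @return a list of class `exudate_report`: total_exudate_area, disk_area,
#'   exudates_disk_ratio, n_lesions, regions (the retained region table).
#' @export
exudate_disk_ratio <- function(regions, disk) {
  abort_if(!inherits(regions, "labeled_regions"),
           "`regions` must come from label_regions()", "retinoquant_argument_error")
  abort_if(!inherits(disk, "optic_disk"), "`disk` must be an optic_disk",
           "retinoquant_argument_error")
  abort_if(disk$area <= 0, "disk area must be > 0", "retinoquant_argument_error")
  reg <- regions$regions
  if (nrow(reg) > 0L) {
    on_disk <- regions$label_grid > 0L & disk$mask == 1L
    if (any(on_disk)) {
      ov <- tabulate(regions$label_grid[on_disk], nbins = nrow(reg))
      drop <- which(ov / reg$area >= 0.5)
      if (length(drop)) {
        message(sprintf("dropping %d region(s) overlapping the optic disk", length(drop)))
        reg <- reg[!reg$id %in% drop, , drop = FALSE]
      }
    }
  }
  total <- sum(reg$area)
  structure(list(total_exudate_area = total, disk_area = disk$area,
                 exudates_disk_ratio = total / disk$area,
                 n_lesions = nrow(reg), regions = reg),
            class = "exudate_report")
}
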