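# Contrast enhancement shared by the exudate and microaneurysm branches:
# luminance-compensated min-max stretch, contrast-limited adaptive histogram
# equalization (CLAHE), and top/bottom-hat small-structure enhancement.

pad_replicate <- function(g, r) {
  h <- nrow(g); w <- ncol(g)
  ri <- c(rep(1L, r), seq_len(h), rep(h, r))
  ci <- c(rep(1L, r), seq_len(w), rep(w, r))
  g[ri, ci, drop = FALSE]
}

crop_pad <- function(g, r, h, w) g[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE]

morph_gray <- function(gray, element, fun) {
  r <- (nrow(element) - 1L) %/% 2L
  h <- nrow(gray); w <- ncol(gray)
  out <- fun(pad_replicate(gray, r), element)
  crop_pad(out, r, h, w)
}

#' Grayscale morphology with a disk structuring element
#'
#' Erosion, dilation, opening, closing and the top-hat / bottom-hat residues,
#' all with replicated borders so that erosion and dilation stay dual at the
#' image edge. The top-hat (image minus opening) isolates bright structures
#' smaller than the element; the bottom-hat (closing minus image) isolates
#' dark ones.
#'
#' @param gray numeric matrix in [0, 1].
#' @param element a 0/1 structuring-element matrix, e.g. [disk_element()].
#' @return a numeric matrix of the same size.
#' @name gray-morphology
NULL

#' @rdname gray-morphology
#' @export
gray_erode <- function(gray, element) morph_gray(gray, element, EBImage::erode)

#' @rdname gray-morphology
#' @export
gray_dilate <- function(gray, element) morph_gray(gray, element, EBImage::dilate)

#' @rdname gray-morphology
#' @export
gray_opening <- function(gray, element) gray_dilate(gray_erode(gray, element), element)

#' @rdname gray-morphology
#' @export
gray_closing <- function(gray, element) gray_erode(gray_dilate(gray, element), element)

#' @rdname gray-morphology
#' @export
gray_tophat <- function(gray, element) gray - gray_opening(gray, element)

#' @rdname gray-morphology
#' @export
gray_bottomhat <- function(gray, element) gray_closing(gray, element) - gray

#' 3 x 3 median filter
#'
#' Classic salt-and-pepper denoiser: each pixel is replaced by the median of
#' its 3 x 3 neighborhood (replicated borders). Unlike a Gaussian it does not
#' blur step edges, so small dark lesions keep their footprint. Implemented
#' as a vectorized 9-element sorting network.
#'
#' @param gray numeric matrix.
#' @return the filtered matrix.
#' @export
median3 <- function(gray) {
  abort_if(!is.matrix(gray), "`gray` must be a matrix",
           "retinoquant_argument_error")
  h <- nrow(gray); w <- ncol(gray)
  p <- pad_replicate(gray, 1L)
  v <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    v[[k]] <- as.numeric(p[(1L + dr):(h + dr), (1L + dc):(w + dc)])
  }
  swap <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network; v[[5]] ends as the median
  swap(2, 3); swap(5, 6); swap(8, 9); swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9); swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6); swap(5, 8); swap(3, 5); swap(5, 7)
  swap(3, 5)
  matrix(v[[5]], h, w)
}

#' Luminance-compensated contrast stretch
#'
#' Linear normalization of an intensity image by its own extremes,
#' J = a * (I - I_min) / (I_max - I_min), clipped to [0, 1]; `a` is the
#' luminance compensation coefficient (a = 1 maps the full observed range
#' onto [0, 1]). A constant image has no range and is returned unchanged with
#' a warning.
#'
#' @param gray numeric matrix in [0, 1].
#' @param a luminance compensation coefficient, > 0.
#' @return the stretched image, values in [0, 1].
#' @export
stretch_contrast <- function(gray, a = 1) {
  check_gray(gray)
  abort_if(!is.numeric(a) || length(a) != 1L || a <= 0,
           "`a` must be a single positive number", "retinoquant_argument_error")
  lo <- min(gray); hi <- max(gray)
  if (hi <= lo) {
    warning("constant image: contrast stretch is undefined, returning input")
    return(gray)
  }
  clip01(a * (gray - lo) / (hi - lo))
}

# CLAHE lookup tables: one clipped-histogram equalization mapping per tile.
# Rows/cols are partitioned into `grid` contiguous chunks; the clip limit is a
# fraction of the tile's pixel count, excess mass redistributed uniformly.
clahe_luts <- function(gray, grid, clip_limit, bins = 256L) {
  h <- nrow(gray); w <- ncol(gray)
  bin <- pmin(floor(gray * bins), bins - 1L)                 # 0-based bins
  row_tile <- ceiling(seq_len(h) / h * grid)
  col_tile <- ceiling(seq_len(w) / w * grid)
  tile <- row_tile[row(gray)] + grid * (col_tile[col(gray)] - 1L)
  counts <- tabulate(bin + 1L + bins * (tile - 1L), nbins = bins * grid^2)
  counts <- matrix(counts, nrow = bins)
  luts <- matrix(0, nrow = bins, ncol = grid^2)
  ident <- (seq_len(bins) - 0.5) / bins
  for (t in seq_len(grid^2)) {
    hst <- counts[, t]
    n <- sum(hst)
    if (sum(hst > 0) < 2L) { luts[, t] <- ident; next }  # flat tile: identity
    clip <- clip_limit * n
    excess <- sum(pmax(hst - clip, 0))
    hst <- pmin(hst, clip) + excess / bins
    luts[, t] <- cumsum(hst) / n
  }
  list(luts = luts, bin = bin,
       row_centers = vapply(seq_len(grid), function(i) mean(which(row_tile == i)), 0),
       col_centers = vapply(seq_len(grid), function(i) mean(which(col_tile == i)), 0))
}

# bracketing tile indices and interpolation weight for positions `p`
blend_index <- function(p, centers) {
  g <- length(centers)
  i1 <- pmin(pmax(findInterval(p, centers), 1L), g)
  i2 <- pmin(i1 + 1L, g)
  below <- p <= centers[1]
  i2[below] <- 1L
  span <- centers[i2] - centers[i1]
  wgt <- ifelse(span > 0, (p - centers[i1]) / span, 0)
  list(i1 = i1, i2 = i2, w = pmin(pmax(wgt, 0), 1))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Partitions the image into a `tile_grid` x `tile_grid` grid, equalizes each
#' tile's clipped histogram (clip limit expressed as a fraction of the tile's
#' pixels; 1 disables clipping), and blends the per-tile mappings bilinearly
#' between tile centers. With `tile_grid = 1` and `clip_limit = 1` this
#' reduces to global histogram equalization.
#'
#' @param gray numeric matrix in [0, 1].
#' @param tile_grid tiles per axis, integer >= 1.
#' @param clip_limit histogram clip limit as a fraction of tile pixels, in (0, 1].
#' @return the equalized image, values in [0, 1].
#' @export
adaptive_equalize <- function(gray, tile_grid = 8L, clip_limit = 0.01) {
  check_gray(gray)
  abort_if(tile_grid < 1, "`tile_grid` must be >= 1", "retinoquant_argument_error")
  abort_if(clip_limit <= 0 || clip_limit > 1,
           "`clip_limit` must be in (0, 1]", "retinoquant_argument_error")
  h <- nrow(gray); w <- ncol(gray)
  abort_if(h < tile_grid || w < tile_grid,
           "image smaller than the tile grid", "retinoquant_argument_error")
  tg <- as.integer(tile_grid)
  cl <- clahe_luts(gray, tg, clip_limit)
  rb <- blend_index(seq_len(h), cl$row_centers)
  cb <- blend_index(seq_len(w), cl$col_centers)
  g <- tg
  look <- function(ri, ci) {
    tile <- outer(ri, ci, function(i, j) i + g * (j - 1L))
    matrix(cl$luts[cl$bin + 1L + 256L * (tile - 1L)], h, w)
  }
  wr <- matrix(rb$w, h, w); wc <- matrix(cb$w, h, w, byrow = TRUE)
  out <- (1 - wr) * (1 - wc) * look(rb$i1, cb$i1) +
         (1 - wr) * wc       * look(rb$i1, cb$i2) +
         wr       * (1 - wc) * look(rb$i2, cb$i1) +
         wr       * wc       * look(rb$i2, cb$i2)
  clip01(out)
}

#' Top/bottom-hat enhancement of small lesions
#'
#' Adds the top-hat and subtracts the bottom-hat of the image with respect to
#' a disk structuring element: small bright structures become brighter and
#' small dark structures (microaneurysms) darker relative to the background,
#' while structures larger than the element — the retinal background and the
#' long axis of vessels — are left alone.
#'
#' @param gray numeric matrix in [0, 1].
#' @param element disk structuring element; defaults to [disk_element()] of
#'   radius 6, larger than the largest expected microaneurysm at the standard
#'   685 x 584 working scale.
#' @return the enhanced image, clipped to [0, 1].
#' @export
top_bottom_hat_enhance <- function(gray, element = disk_element(6L)) {
  check_gray(gray)
  r <- (nrow(element) - 1L) %/% 2L
  abort_if(r >= min(nrow(gray), ncol(gray)) / 2,
           "structuring element too large for the image",
           "retinoquant_argument_error")
  op <- gray_opening(gray, element)
  cl <- gray_closing(gray, element)
  clip01(gray + (gray - op) - (cl - gray))
}
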