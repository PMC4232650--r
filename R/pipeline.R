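# End-to-end per-image quantification: the exudate chain (contrast stretch,
# adaptive equalization, threshold classification, cleanup, labeling, optic
# disk, exudates/disk ratio) and the microaneurysm chain (equalization,
# top/bottom-hat, one of the two detection protocols).

#' Exudate preprocessing chain
#'
#' Luminance-compensated contrast stretch followed by adaptive histogram
#' equalization, applied to the green channel before threshold
#' classification.
#'
#' @param green green channel, numeric matrix in [0, 1].
#' @param a luminance compensation coefficient.
#' @param tile_grid,clip_limit see [adaptive_equalize()].
#' @return the enhanced image.
#' @export
exudate_preprocess <- function(green, a = 1, tile_grid = 8L, clip_limit = 0.01) {
  green |>
    stretch_contrast(a = a) |>
    adaptive_equalize(tile_grid = tile_grid, clip_limit = clip_limit)
}

#' Quantify exudates in one fundus image
#'
#' Full exudate chain: green channel, enhancement, threshold classification
#' (Otsu by default, restricted to the field of view), morphological cleanup,
#' 8-connected labeling, optic-disk localization, and the exudates/disk
#' ratio.
#'
#' @param img a [fundus_image()].
#' @param threshold segmentation threshold in (0, 1) or "otsu".
#' @param manual_disk_mask optional 0/1 optic-disk mask used verbatim.
#' @param a,tile_grid,clip_limit enhancement parameters.
#' @param open_radius,min_area cleanup parameters, see [clean_mask()].
#' @param disk_radius_range plausible optic-disk radii in pixels.
#' @return an `exudate_report` (see [exudate_disk_ratio()]) with the
#'   segmentation mask, threshold used and disk source attached.
#' @export
quantify_exudates <- function(img, threshold = "otsu", manual_disk_mask = NULL,
                              a = 1, tile_grid = 8L, clip_limit = 0.01,
                              open_radius = 1L, min_area = 5L,
                              disk_radius_range = c(12, 80)) {
  green <- extract_green(img)
  fov <- estimate_fov(green)
  enh <- exudate_preprocess(green, a = a, tile_grid = tile_grid,
                            clip_limit = clip_limit)
  mask <- segment_exudates(enh, threshold = threshold, fov_mask = fov)
  thr_used <- attr(mask, "threshold")
  cleaned <- clean_mask(mask, open_radius = open_radius, min_area = min_area)
  disk <- find_optic_disk(green, radius_range = disk_radius_range,
                          manual_mask = manual_disk_mask)
  cleaned[disk$mask == 1L] <- 0L
  regions <- label_regions(cleaned)
  rep <- exudate_disk_ratio(regions, disk)
  rep$mask <- cleaned
  rep$threshold_used <- thr_used
  rep$disk_source <- disk$source
  rep
}

#' Quantify microaneurysms in one fundus image
#'
#' Full microaneurysm chain: green channel, adaptive equalization,
#' top/bottom-hat enhancement, then [count_mas()] with the chosen protocol.
#'
#' @param img a [fundus_image()].
#' @param cal a [pixel_calibration()].
#' @param method "morphology" or "hough".
#' @param config detector configuration, see [count_mas()]; may also carry
#'   tile_grid, clip_limit and hat_radius for the preprocessing.
#' @return an `ma_report`.
#' @export
quantify_mas <- function(img, cal, method = c("morphology", "hough"),
                         config = list()) {
  method <- match.arg(method)
  green <- extract_green(img)
  fov <- estimate_fov(green)
  enh <- ma_preprocess(green,
                       tile_grid = config$tile_grid %||% 8L,
                       clip_limit = config$clip_limit %||% 0.01,
                       hat_radius = config$hat_radius %||% 6L)
  count_mas(enh, cal, method = method, config = config, fov_mask = fov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify both lesion types in one image
#'
#' @param img a [fundus_image()].
#' @param cal a [pixel_calibration()].
#' @param ma_method microaneurysm protocol.
#' @param config shared configuration list.
#' @return a list of class `lesion_report` with `exudates` (an
#'   `exudate_report`) and `mas` (an `ma_report`).
#' @export
quantify_fundus <- function(img, cal, ma_method = "morphology",
                            config = list()) {
  structure(list(
    exudates = quantify_exudates(img,
                                 threshold = config$threshold %||% "otsu",
                                 manual_disk_mask = config$manual_disk_mask,
                                 a = config$a %||% 1,
                                 tile_grid = config$tile_grid %||% 8L,
                                 clip_limit = config$clip_limit %||% 0.01,
                                 open_radius = config$open_radius %||% 1L,
                                 min_area = config$min_area %||% 5L),
    mas = quantify_mas(img, cal, method = ma_method, config = config)
  ), class = "lesion_report")
}
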