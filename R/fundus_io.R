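#' Fundus image container
#'
#' An 8-bit RGB fundus photograph held as a height x width x 3 integer array
#' with intensities in 0..255, plus the path it came from (if any).
#'
#' @param pixels numeric or integer array, height x width x 3, values 0..255.
#' @param source_path optional path the image was read from.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, source_path = NA_character_) {
  abort_if(!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L,
           "`pixels` must be a height x width x 3 array", "retinoquant_argument_error")
  abort_if(dim(pixels)[1] < 1L || dim(pixels)[2] < 1L,
           "image must be at least 1 x 1", "retinoquant_argument_error")
  abort_if(min(pixels) < 0 || max(pixels) > 255,
           "intensities must lie in [0, 255]", "retinoquant_argument_error")
  structure(list(pixels = round(pixels), source_path = source_path),
            class = "fundus_image")
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d px, RGB 8-bit, source: %s>\n",
              d[1], d[2], x$source_path))
  invisible(x)
}

#' Pixel calibration
#'
#' Physical scale of an image: microns per pixel, with the camera field of
#' view recorded for reference. Lesion size priors (e.g. the 30-100 um
#' microaneurysm band) are converted to pixels through this.
#'
#' @param microns_per_pixel microns spanned by one pixel, > 0.
#' @param fov_degrees camera field of view in degrees (informational).
#' @return an object of class `pixel_calibration`.
#' @export
pixel_calibration <- function(microns_per_pixel, fov_degrees = 45) {
  abort_if(!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
             !is.finite(microns_per_pixel) || microns_per_pixel <= 0,
           "`microns_per_pixel` must be a single positive number",
           "retinoquant_argument_error")
  structure(list(microns_per_pixel = microns_per_pixel,
                 fov_degrees = fov_degrees),
            class = "pixel_calibration")
}

#' Rescale a calibration after resizing
#'
#' When an image of `original_width` pixels is resampled to `new_width`
#' pixels, each new pixel spans `original_width / new_width` old pixels.
#'
#' @param cal a [pixel_calibration()].
#' @param original_width,new_width widths in pixels before and after resize.
#' @return the rescaled `pixel_calibration`.
#' @export
rescale_calibration <- function(cal, original_width, new_width) {
  pixel_calibration(cal$microns_per_pixel * original_width / new_width,
                    cal$fov_degrees)
}

#' Read a fundus photograph
#'
#' Reads an 8-bit PNG, TIFF or JPEG raster into a [fundus_image()]. Grayscale
#' files are replicated across the three channels with a warning; an alpha
#' channel, if present, is dropped. JPEG input triggers a warning because
#' compression artifacts can disturb small-lesion detection.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return a `fundus_image`.
#' @export
read_fundus <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path),
           "retinoquant_not_found_error")
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop(errorCondition(sprintf("unsupported image format: .%s", ext),
                        class = c("retinoquant_format_error", "error", "condition")))
  ), error = function(e) {
    if (inherits(e, "retinoquant_format_error")) stop(e)
    stop(errorCondition(sprintf("could not decode %s: %s", path, conditionMessage(e)),
                        class = c("retinoquant_format_error", "error", "condition")))
  })
  if (ext %in% c("jpg", "jpeg"))
    warning("JPEG input: compression artifacts may affect small-lesion detection")
  if (is.matrix(raw)) {
    warning("grayscale input replicated to 3 channels")
    raw <- array(raw, c(dim(raw), 3L))
  } else if (dim(raw)[3] == 2L) {
    warning("grayscale input replicated to 3 channels")
    raw <- array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  } else if (dim(raw)[3] == 4L) {
    raw <- raw[, , 1:3]
  }
  fundus_image(round(raw * 255), source_path = path)
}

#' Write a fundus image to disk
#'
#' Lossless PNG or TIFF output; `read_fundus(write_fundus(img))` is
#' pixel-identical for these formats.
#'
#' @param img a [fundus_image()].
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path) {
  abort_if(!inherits(img, "fundus_image"), "`img` must be a fundus_image",
           "retinoquant_argument_error")
  ext <- tolower(tools::file_ext(path))
  x <- img$pixels / 255
  switch(ext,
    png  = png::writePNG(x, path),
    tif  = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop(errorCondition("output format must be PNG or TIFF",
                        class = c("retinoquant_format_error", "error", "condition")))
  )
  invisible(path)
}

#' Standardize image size
#'
#' Bilinear resampling to a common working grid, 685 x 584 pixels by default,
#' so that morphological structuring elements and lesion size priors apply
#' uniformly across acquisitions. The physical calibration must be rescaled by
#' the same factor (see [rescale_calibration()]).
#'
#' @param img a [fundus_image()].
#' @param target_width,target_height output size in pixels.
#' @return a `fundus_image` of exactly the target size.
#' @export
standardize <- function(img, target_width = 685L, target_height = 584L) {
  abort_if(!inherits(img, "fundus_image"), "`img` must be a fundus_image",
           "retinoquant_argument_error")
  abort_if(target_width < 1 || target_height < 1,
           "target dimensions must be >= 1", "retinoquant_argument_error")
  d <- dim(img$pixels)
  if (d[1] == target_height && d[2] == target_width) return(img)
  # EBImage::resize: `w` is the first array dimension (rows), `h` the second.
  # Resampling runs on the 0..255 scale directly so the full-resolution
  # array is traversed only once.
  out <- EBImage::resize(img$pixels, w = target_height, h = target_width,
                         filter = "bilinear")
  out <- round(pmin(pmax(out, 0), 255))
  structure(list(pixels = out, source_path = img$source_path),
            class = "fundus_image")
}

#' Extract the green channel
#'
#' The green channel of an RGB fundus photograph carries the strongest
#' contrast between the retinal background and both bright (exudate) and dark
#' (vessel, microaneurysm) structures; every detector in this package works on
#' it. Returned on the canonical internal scale [0, 1].
#'
#' @param img a [fundus_image()].
#' @return a numeric matrix in [0, 1] with the image's dimensions.
#' @export
extract_green <- function(img) {
  abort_if(!inherits(img, "fundus_image"), "`img` must be a fundus_image",
           "retinoquant_argument_error")
  img$pixels[, , 2L] / 255
}

#' Read a binary mask (single-channel PNG, 0 = background, 255 = foreground)
#' @param path path to the mask PNG.
#' @return a 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path),
           "retinoquant_not_found_error")
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
}

#' Write a binary mask as a single-channel PNG
#' @param mask a 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
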