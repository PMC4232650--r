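# Seeded generator of fundus-like phantom images: a bright optic disk, dark
# vessels random-walking out of it, bright irregular exudate blobs and dark
# circular microaneurysms inside a 45-degree-style circular field of view,
# with exact ground-truth masks. The test substrate for every detector.

#' Phantom specification
#'
#' Parameters of a synthetic fundus image. Defaults emulate the standard
#' 685 x 584 working grid at 10 um/pixel: a bright optic disk of 30 px
#' radius, six vessels 4-8 px wide, five exudate blobs of 200-600 px, and 15
#' microaneurysms with diameters drawn from 40-44 um — inside the
#' clinically visible band (over 30 um) and small enough that, after the
#' standard median denoising, a 2-px-disk erosion erases them while vessels
#' survive, which is the premise of the vessel-subtraction protocol.
#'
#' @param width,height image size in pixels.
#' @param microns_per_pixel physical scale.
#' @param disk list: center (row, col), radius (px), brightness.
#' @param n_vessels number of vessels.
#' @param vessel_width_px range of vessel widths.
#' @param n_exudates number of exudate blobs.
#' @param exudate_area_px range of per-blob areas.
#' @param exudate_contrast brightness of exudates above local background.
#' @param n_mas number of microaneurysms.
#' @param ma_diameter_um range of MA diameters, within 12-100 um.
#' @param ma_contrast darkness of MAs below local background.
#' @param vessel_contrast darkness of vessels below local background.
#' @param background list: base intensity, vignette strength, noise_sd.
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 685L, height = 584L, microns_per_pixel = 10,
                         disk = list(center = c(height / 2, width * 0.76),
                                     radius = 30, brightness = 0.95),
                         n_vessels = 6L, vessel_width_px = c(4, 8),
                         n_exudates = 5L, exudate_area_px = c(200, 600),
                         exudate_contrast = 0.3,
                         n_mas = 15L, ma_diameter_um = c(40, 44),
                         ma_contrast = 0.25, vessel_contrast = 0.2,
                         background = list(base = 0.5, vignette = 0.15,
                                           noise_sd = 0.01),
                         seed = 1L) {
  abort_if(n_vessels < 0 || n_exudates < 0 || n_mas < 0,
           "counts must be >= 0", "retinoquant_argument_error")
  abort_if(ma_diameter_um[1] < 12 || ma_diameter_um[2] > 100,
           "`ma_diameter_um` must lie within [12, 100]",
           "retinoquant_argument_error")
  structure(list(width = as.integer(width), height = as.integer(height),
                 microns_per_pixel = microns_per_pixel, disk = disk,
                 n_vessels = as.integer(n_vessels),
                 vessel_width_px = vessel_width_px,
                 n_exudates = as.integer(n_exudates),
                 exudate_area_px = exudate_area_px,
                 exudate_contrast = exudate_contrast,
                 n_mas = as.integer(n_mas), ma_diameter_um = ma_diameter_um,
                 ma_contrast = ma_contrast, vessel_contrast = vessel_contrast,
                 background = background, seed = as.integer(seed)),
            class = "phantom_spec")
}

# pixels of a filled disk at (r0, c0), plus anti-aliased edge alpha
disk_pixels <- function(r0, c0, radius, h, w, aa = TRUE) {
  rr <- max(1L, floor(r0 - radius - 1)):min(h, ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(w, ceiling(c0 + radius + 1))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  alpha <- if (aa) pmin(pmax(radius + 0.5 - d, 0), 1) else (d <= radius) * 1
  sel <- which(alpha > 0, arr.ind = TRUE)
  data.frame(row = rr[sel[, 1]], col = cc[sel[, 2]],
             alpha = alpha[sel], hard = d[sel] <= radius)
}

blend_dark <- function(g, px, contrast) {
  i <- cbind(px$row, px$col)
  g[i] <- g[i] - px$alpha * contrast
  g
}

blend_bright <- function(g, px, contrast) {
  i <- cbind(px$row, px$col)
  g[i] <- g[i] + px$alpha * contrast
  g
}

#' Render a fundus phantom with ground truth
#'
#' Deterministic for a given spec (the seed is part of the spec): renders the
#' vignetted background, the bright optic disk, dark anti-aliased vessels as
#' random walks leaving the disk, bright irregular exudates (unions of
#' jittered disks) and dark circular microaneurysms, then adds Gaussian
#' intensity noise and quantizes to 8 bits. The green channel carries the
#' full lesion contrast; red and blue are derived with reduced contrast.
#' Ground-truth masks are the ideal pre-noise shapes and are pairwise
#' disjoint by construction (lesions are placed away from the disk, the
#' vessels and each other, with bounded retries).
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (a [fundus_image()]) and `truth`: exudate_mask,
#'   disk_mask, vessel_mask (0/1 matrices), ma_centers (data.frame row, col,
#'   radius_px), and totals (exudate_area, disk_area, true_ratio, ma_count).
#' @export
make_phantom <- function(spec) {
  abort_if(!inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec",
           "retinoquant_argument_error")
  with_rng(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  h <- spec$height; w <- spec$width
  fov_c <- c(h / 2, w / 2)
  fov_r <- min(h, w) / 2 - 4
  rho <- sqrt(outer((seq_len(h) - fov_c[1])^2, (seq_len(w) - fov_c[2])^2, "+"))
  inside <- rho <= fov_r
  bg <- spec$background
  g <- matrix(0.02, h, w)
  g[inside] <- bg$base * (1 - bg$vignette * (rho[inside] / fov_r)^2)

  # optic disk
  dk <- spec$disk
  dpx <- disk_pixels(dk$center[1], dk$center[2], dk$radius, h, w)
  i <- cbind(dpx$row, dpx$col)
  g[i] <- g[i] * (1 - dpx$alpha) + dk$brightness * dpx$alpha
  disk_mask <- matrix(0L, h, w); disk_mask[i[dpx$hard, , drop = FALSE]] <- 1L

  # vessels: random walks out of the disk, stamped with width/2 disks
  vessel_mask <- matrix(0L, h, w)
  for (v in seq_len(spec$n_vessels)) {
    width_v <- runif(1, spec$vessel_width_px[1], spec$vessel_width_px[2])
    stamp_r <- max(2L, as.integer(round(width_v / 2)))
    ang <- runif(1, 0, 2 * pi)
    pos <- dk$center
    pts_r <- numeric(0); pts_c <- numeric(0)
    for (s in seq_len(400L)) {
      ang <- ang + rnorm(1, 0, 0.12)
      pos <- pos + 2 * c(sin(ang), cos(ang))
      if (sqrt(sum((pos - fov_c)^2)) > fov_r - 3) break
      pts_r <- c(pts_r, pos[1]); pts_c <- c(pts_c, pos[2])
    }
    if (!length(pts_r)) next
    off <- which(disk_element(stamp_r) == 1, arr.ind = TRUE) - stamp_r - 1L
    sr <- pmin(pmax(rep(round(pts_r), each = nrow(off)) + off[, 1], 1L), h)
    sc <- pmin(pmax(rep(round(pts_c), each = nrow(off)) + off[, 2], 1L), w)
    vessel_mask[cbind(sr, sc)] <- 1L
  }
  vessel_mask[disk_mask == 1L] <- 0L
  vsel <- vessel_mask == 1L & inside
  g[vsel] <- g[vsel] - spec$vessel_contrast

  dist2 <- function(p, q) sum((p - q)^2)

  # exudates: unions of jittered bright disks, kept clear of disk and vessels
  exudate_mask <- matrix(0L, h, w)
  n_ex_placed <- 0L
  for (e in seq_len(spec$n_exudates)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      ctr <- fov_c + runif(2, -1, 1) * (fov_r - 30)
      if (sqrt(dist2(ctr, fov_c)) > fov_r - 30) next
      if (sqrt(dist2(ctr, dk$center)) < dk$radius + 35) next
      area <- runif(1, spec$exudate_area_px[1], spec$exudate_area_px[2])
      r0 <- sqrt(area / pi) * 0.75
      sub <- cbind(c(0, runif(3, -0.8, 0.8) * r0),
                   c(0, runif(3, -0.8, 0.8) * r0),
                   r0 * c(1, runif(3, 0.5, 0.8)))
      px <- unique(do.call(rbind, lapply(seq_len(nrow(sub)), function(k)
        disk_pixels(ctr[1] + sub[k, 1], ctr[2] + sub[k, 2], sub[k, 3],
                    h, w, aa = FALSE)[, c("row", "col")])))
      i <- as.matrix(px)
      near <- cbind(pmin(pmax(rep(i[, 1], 5) + rep(c(0, -5, 5, 0, 0), each = nrow(i)), 1L), h),
                    pmin(pmax(rep(i[, 2], 5) + rep(c(0, 0, 0, -5, 5), each = nrow(i)), 1L), w))
      if (any(vessel_mask[near] == 1L) || any(exudate_mask[near] == 1L) ||
          any(disk_mask[near] == 1L)) next
      g[i] <- g[i] + spec$exudate_contrast * runif(1, 0.85, 1.15)
      exudate_mask[i] <- 1L
      n_ex_placed <- n_ex_placed + 1L
      placed <- TRUE
      break
    }
    abort_if(!placed, "could not place all exudates; reduce counts or sizes",
             "retinoquant_placement_error")
  }

  # microaneurysms: dark anti-aliased dots clear of everything else
  ma_centers <- data.frame(row = numeric(0), col = numeric(0),
                           radius_px = numeric(0))
  for (m in seq_len(spec$n_mas)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      ctr <- fov_c + runif(2, -1, 1) * (fov_r - 20)
      if (sqrt(dist2(ctr, fov_c)) > fov_r - 20) next
      if (sqrt(dist2(ctr, dk$center)) < dk$radius + 20) next
      if (nrow(ma_centers) &&
          min((ma_centers$row - ctr[1])^2 + (ma_centers$col - ctr[2])^2) < 14^2) next
      rr <- round(ctr[1]); cc <- round(ctr[2])
      win_r <- pmin(pmax((rr - 6):(rr + 6), 1L), h)
      win_c <- pmin(pmax((cc - 6):(cc + 6), 1L), w)
      if (any(vessel_mask[win_r, win_c] == 1L) ||
          any(exudate_mask[win_r, win_c] == 1L)) next
      d_um <- runif(1, spec$ma_diameter_um[1], spec$ma_diameter_um[2])
      r_px <- d_um / spec$microns_per_pixel / 2
      px <- disk_pixels(ctr[1], ctr[2], r_px, h, w, aa = FALSE)
      g <- blend_dark(g, px, spec$ma_contrast)
      ma_centers <- rbind(ma_centers,
                          data.frame(row = ctr[1], col = ctr[2], radius_px = r_px))
      placed <- TRUE
      break
    }
    abort_if(!placed, "could not place all microaneurysms",
             "retinoquant_placement_error")
  }
  ma_mask <- matrix(0L, h, w)
  if (nrow(ma_centers))
    for (m in seq_len(nrow(ma_centers))) {
      px <- disk_pixels(ma_centers$row[m], ma_centers$col[m],
                        ma_centers$radius_px[m], h, w)
      ma_mask[cbind(px$row, px$col)[px$hard, , drop = FALSE]] <- 1L
    }

  g <- clip01(g)
  red <- clip01(0.35 + 0.55 * g)
  blue <- clip01(0.25 * g)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- red; img[, , 2] <- g; img[, , 3] <- blue
  img <- clip01(img + rnorm(length(img), 0, bg$noise_sd))

  exudate_area <- sum(exudate_mask)
  disk_area <- sum(disk_mask)
  list(image = fundus_image(round(img * 255), source_path = "<phantom>"),
       truth = list(exudate_mask = exudate_mask, disk_mask = disk_mask,
                    vessel_mask = vessel_mask, ma_mask = ma_mask,
                    ma_centers = ma_centers,
                    totals = list(exudate_area = exudate_area,
                                  disk_area = disk_area,
                                  true_ratio = exudate_area / disk_area,
                                  ma_count = nrow(ma_centers))),
       spec = spec)
}

#' Generate a two-group phantom cohort
#'
#' Renders `n_per_group` phantoms per group from two spec templates, with
#' per-image Poisson jitter of the exudate and microaneurysm counts around
#' the template values, and returns (optionally writes) a cohort manifest
#' with the planted ground truth.
#'
#' @param moderate_spec,severe_spec [phantom_spec()] templates; group labels
#'   are taken from the argument names of the manifest ("moderate",
#'   "severe").
#' @param n_per_group images per group, >= 2.
#' @param seed cohort seed; image i of group k uses a seed derived from it.
#' @param out_dir if non-NULL, write images (PNG), ground-truth masks and a
#'   `manifest.csv` there.
#' @return a list with `manifest` (data.frame: image_id, group, true_ratio,
#'   true_ma_count, and path if written) and `phantoms` (the rendered list).
#' @export
make_cohort <- function(moderate_spec, severe_spec, n_per_group, seed = 1L,
                        out_dir = NULL) {
  abort_if(n_per_group < 2, "`n_per_group` must be >= 2",
           "retinoquant_argument_error")
  templates <- list(moderate = moderate_spec, severe = severe_spec)
  phantoms <- list(); rows <- list()
  k <- 0L
  for (grp in names(templates)) {
    tpl <- templates[[grp]]
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      seed_i <- (as.integer(seed) * 131L + k * 7919L) %% 2147483647L
      jit <- with_rng(seed_i, c(rpois(1, tpl$n_exudates), rpois(1, tpl$n_mas)))
      sp <- tpl
      sp$n_exudates <- jit[1]; sp$n_mas <- jit[2]
      sp$seed <- seed_i + 1L
      ph <- make_phantom(sp)
      id <- sprintf("%s_%02d", grp, i)
      phantoms[[id]] <- ph
      rows[[k]] <- data.frame(image_id = id, group = grp,
                              true_ratio = ph$truth$totals$true_ratio,
                              true_ma_count = ph$truth$totals$ma_count)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, paste0(manifest$image_id, ".png"))
    for (id in names(phantoms)) {
      ph <- phantoms[[id]]
      write_fundus(ph$image, file.path(out_dir, paste0(id, ".png")))
      write_mask(ph$truth$exudate_mask,
                 file.path(out_dir, paste0(id, "_exudates.png")))
      write_mask(ph$truth$disk_mask, file.path(out_dir, paste0(id, "_disk.png")))
      jsonlite::write_json(
        list(ma_centers = ph$truth$ma_centers, totals = ph$truth$totals),
        file.path(out_dir, paste0(id, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, phantoms = phantoms)
}
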