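# Independent brute-force oracles and shared fixtures. Every oracle here is
# deliberately written by the most naive route available (per-pixel loops,
# recursion, closed forms) so it shares no code path with the package.

# --- phantom cache: default phantoms are reused across test files ----------
.phantoms <- new.env(parent = emptyenv())
cached_phantom <- function(seed = 1L, ...) {
  key <- paste0(seed, "|", paste(deparse(list(...)), collapse = ""))
  if (is.null(.phantoms[[key]]))
    .phantoms[[key]] <- make_phantom(phantom_spec(seed = seed, ...))
  .phantoms[[key]]
}

# --- brute-force flood-fill labeling (8-connectivity), stack based ---------
flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask == 1L & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- nxt
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w) {
          q <- r2 + h * (c2 - 1L)
          if (mask[q] == 1L && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# --- naive grayscale morphology with replicated borders --------------------
brute_morph <- function(gray, radius, fun) {
  h <- nrow(gray); w <- ncol(gray)
  out <- gray
  for (r in seq_len(h)) for (c in seq_len(w)) {
    vals <- c()
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r2 <- min(max(r + dr, 1L), h); c2 <- min(max(c + dc, 1L), w)
        vals <- c(vals, gray[r2, c2])
      }
    }
    out[r, c] <- fun(vals)
  }
  out
}
brute_erode <- function(gray, radius) brute_morph(gray, radius, min)
brute_dilate <- function(gray, radius) brute_morph(gray, radius, max)

# naive binary morphology with zero padding (matches mask-side conventions)
brute_erode_bin <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    keep <- TRUE
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1L || r2 > h || c2 < 1L || c2 > w || mask[r2, c2] == 0L) keep <- FALSE
      }
    }
    if (keep) out[r, c] <- 1L
  }
  out
}
brute_dilate_bin <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1L && r2 <= h && c2 >= 1L && c2 <= w && mask[r2, c2] == 1L) hit <- TRUE
      }
    }
    if (hit) out[r, c] <- 1L
  }
  out
}

# --- exhaustive Otsu scan: evaluate all 256 cut points one at a time -------
brute_otsu_index <- function(values) {
  bin <- pmin(floor(values * 256), 255)
  h <- tabulate(bin + 1L, 256L)
  n <- length(bin)
  lev <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- lev <= t
    n0 <- sum(h[lo]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) v <- 0
    else {
      mu0 <- sum(h[lo] * lev[lo]) / n0
      mu1 <- sum(h[!lo] * lev[!lo]) / n1
      v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# --- rasterized circle drawing (for Hough recovery tests) ------------------
draw_circle <- function(m, r0, c0, rad, arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = max(720, round(16 * rad)))
  rr <- round(r0 + rad * sin(th)); cc <- round(c0 + rad * cos(th))
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[ok], cc[ok])] <- 1L
  m
}

# place n non-overlapping circles, returning the edge mask and their params
plant_circles <- function(n, size = 200L, radii = 3:10) {
  m <- matrix(0L, size, size)
  ctr <- matrix(NA_real_, 0, 3)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      rad <- sample(radii, 1)
      r0 <- runif(1, rad + 2, size - rad - 2)
      c0 <- runif(1, rad + 2, size - rad - 2)
      if (nrow(ctr) == 0 ||
          min(sqrt((ctr[, 1] - r0)^2 + (ctr[, 2] - c0)^2) - (ctr[, 3] + rad)) > 3) {
        ctr <- rbind(ctr, c(r0, c0, rad))
        m <- draw_circle(m, r0, c0, rad)
        break
      }
    }
  }
  list(mask = m, circles = ctr)
}
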