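#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm rpois runif sd setNames t.test pt
#' @importFrom utils read.csv write.csv
NULL

abort_if <- function(cond, msg, class = "retinoquant_error") {
  if (cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(NULL)
}

is_gray <- function(x) is.matrix(x) && is.numeric(x)

check_gray <- function(gray, arg = "gray") {
  abort_if(!is_gray(gray), sprintf("`%s` must be a numeric matrix", arg),
           "retinoquant_argument_error")
  abort_if(length(gray) == 0L, sprintf("`%s` is empty", arg),
           "retinoquant_argument_error")
  abort_if(min(gray) < -1e-9 || max(gray) > 1 + 1e-9,
           sprintf("`%s` must have values in [0, 1]", arg),
           "retinoquant_argument_error")
  invisible(NULL)
}

check_mask <- function(mask, arg = "mask") {
  abort_if(!is.matrix(mask), sprintf("`%s` must be a matrix", arg),
           "retinoquant_argument_error")
  abort_if(!all(mask %in% c(0, 1)),
           sprintf("`%s` must be binary (0/1)", arg),
           "retinoquant_argument_error")
  invisible(NULL)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Discrete disk structuring element
#'
#' Footprint of the disk of given radius: all integer offsets (dr, dc) with
#' dr^2 + dc^2 <= radius^2, returned as a (2r+1) x (2r+1) 0/1 matrix suitable
#' for morphological erosion and dilation.
#'
#' @param radius integer radius in pixels, >= 1.
#' @return a square 0/1 matrix of size 2*radius + 1.
#' @export
disk_element <- function(radius) {
  abort_if(!is.numeric(radius) || length(radius) != 1L || radius < 1,
           "`radius` must be a single integer >= 1", "retinoquant_argument_error")
  radius <- as.integer(radius)
  d <- -radius:radius
  fp <- outer(d^2, d^2, "+") <= radius^2
  matrix(as.numeric(fp), 2L * radius + 1L)
}

# run a block with a private, seeded RNG stream, restoring global state
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
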