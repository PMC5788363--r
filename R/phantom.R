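#' Specification of a synthetic bias-field phantom
#'
#' Describes a piecewise-constant test image corrupted by a smooth
#' multiplicative bias field and additive Gaussian noise — the structure
#' of intensity-inhomogeneous test images used throughout the package's
#' tests. Ground truth is the exact object support.
#'
#' @param shape Object shape: `"disc"`, `"ring"`, `"blob"` (a smoothly
#'   perturbed disc) or `"multi"` (two discs).
#' @param size Grid dimensions `c(height, width)`.
#' @param center Object center as row/column fractions of the grid. The
#'   default is deliberately off-center so that generic initial contours
#'   (e.g. a centered rectangle) do not coincide with the ground truth.
#' @param object_intensity,background_intensity Base intensities in
#'   \[0, 1\]. The defaults (0.65 / 0.25) keep the full bias range free of
#'   clipping.
#' @param bias Bias field model: `"linear"` (ramp along x), `"radial"`
#'   (Gaussian bump centered on the grid), `"polynomial"` (low-order 2-D
#'   quadratic), or `"none"`.
#' @param bias_range `c(min_gain, max_gain)` of the multiplicative field;
#'   both must be positive.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer RNG seed; generation is bit-reproducible per seed.
#' @return List of class `acseg_phantom_spec`.
#' @export
phantom_spec <- function(shape = c("disc", "ring", "blob", "multi"),
                         size = c(128L, 128L),
                         center = c(0.40, 0.62),
                         object_intensity = 0.65,
                         background_intensity = 0.25,
                         bias = c("linear", "radial", "polynomial", "none"),
                         bias_range = c(0.5, 1.5),
                         noise_sd = 0.02, seed = 1L) {
  shape <- match.arg(shape)
  bias <- match.arg(bias)
  if (any(bias_range <= 0)) stop("bias gains must be positive", call. = FALSE)
  if (object_intensity < 0 || object_intensity > 1 ||
      background_intensity < 0 || background_intensity > 1)
    stop("base intensities must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(size < 16)) stop("grid too small for the object shapes", call. = FALSE)
  if (any(center <= 0.2) || any(center >= 0.8))
    stop("object center fractions must lie in (0.2, 0.8)", call. = FALSE)
  structure(list(shape = shape, size = as.integer(size), center = center,
                 object_intensity = object_intensity,
                 background_intensity = background_intensity,
                 bias = bias, bias_range = bias_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acseg_phantom_spec")
}

phantom_object_mask <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  cy <- spec$center[1] * h; cx <- spec$center[2] * w
  r0 <- 0.28 * min(h, w)
  switch(spec$shape,
    disc = (xs - cx)^2 + (ys - cy)^2 <= r0^2,
    ring = {
      d2 <- (xs - cx)^2 + (ys - cy)^2
      d2 <= (0.28 * min(h, w))^2 & d2 >= (0.16 * min(h, w))^2
    },
    blob = {
      theta <- atan2(ys - cy, xs - cx)
      r <- r0 * (1 + 0.25 * sin(3 * theta) + 0.12 * cos(5 * theta))
      (xs - cx)^2 + (ys - cy)^2 <= r^2
    },
    multi = {
      c1x <- cx - 0.22 * w; c2x <- cx + 0.22 * w
      ((xs - c1x)^2 + (ys - cy)^2 <= (0.16 * min(h, w))^2) |
        ((xs - c2x)^2 + (ys - cy)^2 <= (0.12 * min(h, w))^2)
    })
}

phantom_bias_field <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  bmin <- spec$bias_range[1]; bmax <- spec$bias_range[2]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  switch(spec$bias,
    none = matrix(1, h, w),
    linear = bmin + (bmax - bmin) * (xs - 1) / (w - 1),
    radial = {
      # Gaussian bump on the object center, tight enough that the default
      # disc (radius 0.28*min(dim)) spans nearly the full gain range
      cy <- spec$center[1] * h; cx <- spec$center[2] * w
      s <- 0.095 * min(h, w)
      bmin + (bmax - bmin) * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
    },
    polynomial = {
      u <- (xs - 1) / (w - 1); v <- (ys - 1) / (h - 1)
      raw <- 0.6 * u + 0.4 * v - 0.5 * u * v + 0.3 * u^2
      bmin + (bmax - bmin) * (raw - min(raw)) / (max(raw) - min(raw))
    })
}

#' Generate a bias-field phantom with exact ground truth
#'
#' Builds `image = clip(base(mask) * bias + noise, 0, 1)` where `base` is
#' the piecewise-constant image of the object spec, `bias` the smooth
#' multiplicative field and `noise` additive Gaussian noise. The RNG state
#' is restored afterwards, so generation is reproducible per seed and does
#' not disturb the caller's random stream.
#'
#' @param spec Specification from [phantom_spec()]; alternatively named
#'   arguments forwarded to [phantom_spec()].
#' @param ... Forwarded to [phantom_spec()] when `spec` is missing.
#' @return List with `image` (matrix in \[0, 1\]), `mask` (integer 0/1
#'   ground truth), `bias` (the field itself) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(...), ...) {
  stopifnot(inherits(spec, "acseg_phantom_spec"))
  mask <- phantom_object_mask(spec)
  if (!any(mask)) stop("object does not fit the grid", call. = FALSE)
  base <- matrix(spec$background_intensity, spec$size[1], spec$size[2])
  base[mask] <- spec$object_intensity
  bias <- phantom_bias_field(spec)
  noise <- with_preserved_seed(spec$seed, {
    matrix(rnorm(length(base), sd = spec$noise_sd), nrow(base), ncol(base))
  })
  img <- pmin(pmax(base * bias + noise, 0), 1)
  list(image = img, mask = matrix(as.integer(mask), nrow(mask)),
       bias = bias, spec = spec)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic grid of initial-contour placements
#'
#' Produces `n_inits` distinct, in-bounds initial regions at varied
#' offsets and scales relative to the object: centered, shifted,
#' corner-placed, enclosing and strictly interior — the protocol used to
#' probe initialization sensitivity.
#'
#' @param mask Ground-truth 0/1 matrix (object support).
#' @param n_inits Number of placements (>= 1).
#' @return List of region specifications usable by
#'   [initialize_levelset()].
#' @export
generate_init_grid <- function(mask, n_inits = 5L) {
  stopifnot(n_inits >= 1)
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  ry <- range(idx[, 1]); rx <- range(idx[, 2])
  cy <- mean(ry); cx <- mean(rx)
  hy <- (ry[2] - ry[1]) / 2; hx <- (rx[2] - rx[1]) / 2
  clamp_rect <- function(x0, y0, x1, y1)
    list(type = "rect",
         x0 = max(1, round(x0)), y0 = max(1, round(y0)),
         x1 = min(w, round(x1)), y1 = min(h, round(y1)))
  # strictly interior circle: shrink until every pixel lies in the mask
  interior_circle <- function() {
    r <- 0.5 * min(hx, hy)
    repeat {
      reg <- list(type = "circle", cx = round(cx), cy = round(cy), r = r)
      m <- region_mask(c(h, w), reg)
      if (all(mask[m] != 0) || r < 2) return(reg)
      r <- r * 0.8
    }
  }
  # Varied offsets and scales relative to the object, all within the
  # capture envelope of the fixed-length global stage (see vignette):
  # centered, shifted, object-corner, enclosing, strictly interior.
  base <- list(
    clamp_rect(cx - 0.6 * hx, cy - 0.6 * hy, cx + 0.6 * hx, cy + 0.6 * hy),
    clamp_rect(cx - 1.4 * hx, cy - 0.6 * hy, cx + 0.6 * hx, cy + 1.4 * hy),
    clamp_rect(cx - 1.2 * hx, cy - 1.2 * hy, cx + 0.4 * hx, cy + 0.4 * hy),
    clamp_rect(cx - 1.15 * hx, cy - 1.15 * hy, cx + 1.15 * hx, cy + 1.15 * hy),
    interior_circle()
  )
  if (n_inits <= 5L) return(base[seq_len(n_inits)])
  extra <- lapply(seq_len(n_inits - 5L), function(k) {
    f <- 0.4 + 0.1 * k
    clamp_rect(cx - f * hx, cy - f * hy, cx + f * hx, cy + f * hy)
  })
  c(base, extra)
}
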