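#' Regularized Heaviside function
#'
#' Smooth step function used as the soft inside-indicator of the contour:
#' `H_eps(phi) = 1/2 * (1 + (2/pi) * atan(phi / epsilon))`. Values lie in
#' the open interval (0, 1) and increase strictly with `phi`.
#'
#' @param phi Numeric matrix (or vector), the level-set field.
#' @param epsilon Positive scalar controlling the transition width.
#' @return Object of the same shape as `phi` with values in (0, 1).
#' @seealso [dirac()] for its derivative.
#' @export
#' @examples
#' heaviside(0, 1)    # 0.5
#' heaviside(1, 1)    # 0.75
heaviside <- function(phi, epsilon) {
  check_positive(epsilon, "epsilon")
  0.5 * (1 + (2 / pi) * atan(phi / epsilon))
}

#' Regularized Dirac delta function
#'
#' Derivative of [heaviside()]:
#' `delta_eps(phi) = epsilon / (pi * (phi^2 + epsilon^2))`. Even in `phi`,
#' maximal at `phi = 0` where it equals `1 / (pi * epsilon)`.
#'
#' @inheritParams heaviside
#' @return Nonnegative field of the same shape as `phi`.
#' @export
dirac <- function(phi, epsilon) {
  check_positive(epsilon, "epsilon")
  epsilon / (pi * (phi^2 + epsilon^2))
}

#' Mean curvature of the level sets of a field
#'
#' Computes `div(grad(phi) / |grad(phi)|)` by central differences with
#' replicate borders. The gradient norm under the division is floored
#' (1e-8 added) so a locally flat field yields zero curvature rather than
#' 0/0; a constant field therefore returns all zeros.
#'
#' @param phi Numeric matrix with at least 3 pixels per axis.
#' @return Numeric matrix of the same shape.
#' @export
curvature <- function(phi) {
  if (nrow(phi) < 3L || ncol(phi) < 3L)
    stop("curvature() needs a field with at least 3 pixels per axis", call. = FALSE)
  px <- grad_x(phi); py <- grad_y(phi)
  n <- sqrt(px^2 + py^2) + 1e-8
  grad_x(px / n) + grad_y(py / n)
}

#' Binary-step level-set initialization
#'
#' Builds the initial level-set function from a region: `+rho` strictly
#' inside the region, `-rho` strictly outside, and 0 on the region's
#' boundary pixels (region pixels with a 4-neighbor outside). The sign
#' convention is inside = `phi > 0`, so `heaviside(phi)` is the inside
#' indicator.
#'
#' @param shape Integer vector `c(height, width)` of the pixel grid.
#' @param region Region specification: a list such as
#'   `list(type = "rect", x0, y0, x1, y1)` (1-based inclusive, x = column)
#'   or `list(type = "circle", cx, cy, r)`, a logical/0-1 mask matrix, or a
#'   string `"rect:x0,y0,x1,y1"` / `"circle:cx,cy,r"`.
#' @param rho Positive magnitude of the binary step.
#' @return Numeric matrix of dimension `shape` taking values in
#'   `{-rho, 0, +rho}`.
#' @export
initialize_levelset <- function(shape, region, rho) {
  check_positive(rho, "rho")
  mask <- region_mask(shape, region)
  if (!any(mask) || all(mask))
    stop("degenerate initialization: region is empty or covers the whole grid",
         call. = FALSE)
  boundary <- mask_boundary(mask)
  phi <- matrix(-rho, shape[1], shape[2])
  phi[mask] <- rho
  phi[boundary] <- 0
  if (!any(phi > 0))
    stop("degenerate initialization: region has no interior pixels", call. = FALSE)
  phi
}

#' Gaussian regularization of the level-set function
#'
#' Smooths `phi` with a Gaussian kernel of standard deviation `sigma_reg`
#' (replicate borders). Applied once per evolution step, this keeps the
#' level-set function regular and replaces signed-distance
#' re-initialization. `sigma_reg = 0` returns `phi` unchanged.
#'
#' @param phi Numeric matrix.
#' @param sigma_reg Nonnegative standard deviation in pixels.
#' @return Smoothed field, same shape as `phi`.
#' @export
regularize_levelset <- function(phi, sigma_reg) {
  if (!is.numeric(sigma_reg) || length(sigma_reg) != 1L || is.na(sigma_reg) ||
      sigma_reg < 0)
    stop("sigma_reg must be a nonnegative scalar", call. = FALSE)
  gauss_filter(phi, sigma_reg)
}

# ---- region helpers ---------------------------------------------------------

# Resolve any accepted region description into a logical mask on `shape`.
region_mask <- function(shape, region) {
  h <- shape[1]; w <- shape[2]
  if (is.character(region)) region <- parse_region_string(region)
  if (is.matrix(region)) {
    if (!identical(dim(region), as.integer(c(h, w))) &&
        !identical(dim(region), c(h, w)))
      stop("region mask dimensions do not match the grid", call. = FALSE)
    return(region != 0)
  }
  if (!is.list(region) || is.null(region$type))
    stop("region must be a mask matrix, a list with $type, or a string spec",
         call. = FALSE)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  m <- switch(region$type,
    rect = ,
    rectangle = {
      if (region$x0 < 1 || region$y0 < 1 || region$x1 > w || region$y1 > h ||
          region$x0 > region$x1 || region$y0 > region$y1)
        stop("rectangle region lies outside the grid", call. = FALSE)
      xs >= region$x0 & xs <= region$x1 & ys >= region$y0 & ys <= region$y1
    },
    circle = {
      if (region$cx - region$r < 1 || region$cx + region$r > w ||
          region$cy - region$r < 1 || region$cy + region$r > h)
        stop("circle region lies outside the grid", call. = FALSE)
      (xs - region$cx)^2 + (ys - region$cy)^2 <= region$r^2
    },
    stop("unknown region type: ", region$type, call. = FALSE)
  )
  m
}

# Pixels of `mask` with at least one 4-neighbor outside the mask.
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up    <- mask[c(1, 1:(h - 1)), , drop = FALSE]
  down  <- mask[c(2:h, h), , drop = FALSE]
  left  <- mask[, c(1, 1:(w - 1)), drop = FALSE]
  right <- mask[, c(2:w, w), drop = FALSE]
  mask & !(up & down & left & right)
}

parse_region_string <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("region string must look like 'rect:x0,y0,x1,y1', 'circle:cx,cy,r' or 'mask:path'",
         call. = FALSE)
  type <- parts[1]
  if (type == "mask") return(read_mask(parts[2]))
  vals <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  if (type %in% c("rect", "rectangle")) {
    stopifnot(length(vals) == 4L)
    list(type = "rect", x0 = vals[1], y0 = vals[2], x1 = vals[3], y1 = vals[4])
  } else if (type == "circle") {
    stopifnot(length(vals) == 3L)
    list(type = "circle", cx = vals[1], cy = vals[2], r = vals[3])
  } else stop("unknown region type: ", type, call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(name, " must be a positive scalar", call. = FALSE)
  invisible(x)
}
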