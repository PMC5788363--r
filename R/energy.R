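#' Edge stopping function of an image
#'
#' Computes `g = 1 / (1 + |grad(G_sigma * I)|)` where `G_sigma` is a
#' Gaussian of standard deviation `sigma_edge`. `g` is close to 1 in flat
#' regions and drops toward 0 at strong edges; it scales the region terms
#' and drives the geodesic edge term of both evolution stages.
#'
#' The gradient magnitude is taken on the image rescaled by `grad_gain`
#' (default 255), i.e. on the conventional 0-255 intensity scale, so that
#' parameter values quoted on that scale keep their meaning while the
#' image itself is stored in \[0, 1\].
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param sigma_edge Positive Gaussian pre-smoothing standard deviation
#'   (pixels).
#' @param grad_gain Multiplier applied to the intensity scale before the
#'   gradient (default 255).
#' @return Matrix of class `acseg_edgemap` with values in (0, 1\] and
#'   attributes `sigma_edge`, `grad_gain`.
#' @export
edge_stop_map <- function(image, sigma_edge, grad_gain = 255) {
  check_positive(sigma_edge, "sigma_edge")
  sm <- gauss_filter(image, sigma_edge)
  g <- 1 / (1 + grad_gain * grad_mag(sm))
  structure(g, class = c("acseg_edgemap", class(g)),
            sigma_edge = sigma_edge, grad_gain = grad_gain)
}

# Accept an edge map object, a plain matrix, or NULL (meaning g identically 1).
edge_values <- function(edge, shape) {
  if (is.null(edge)) return(matrix(1, shape[1], shape[2]))
  stopifnot(is.matrix(edge))
  unclass(edge)
}

DENOM_GUARD <- 1e-10

#' Edge-scaled global intensity means
#'
#' Global region descriptors of the first evolution stage: weighted means
#' of the image inside and outside the contour, with weights
#' `g * H_eps(phi)` and `g * (1 - H_eps(phi))`:
#' `c1 = sum(g I H) / sum(g H)`, `c2 = sum(g I (1-H)) / sum(g (1-H))`.
#' With `g` identically 1 these reduce exactly to the Chan-Vese means.
#'
#' A small guard (1e-10) is added to both denominators; if a denominator
#' underflows the guard (empty region), the corresponding mean falls back
#' to the global image mean and a warning is raised.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param phi Level-set field, same shape as `image`.
#' @param edge Edge map from [edge_stop_map()], a plain matrix of weights,
#'   or NULL for `g` identically 1.
#' @param epsilon Heaviside width.
#' @return List of class `acseg_globalfits` with elements `c1`, `c2`.
#' @export
global_edge_scaled_means <- function(image, phi, edge, epsilon) {
  stopifnot(identical(dim(image), dim(phi)))
  g <- edge_values(edge, dim(image))
  H <- heaviside(phi, epsilon)
  wi <- g * H
  wo <- g * (1 - H)
  di <- sum(wi); do <- sum(wo)
  c1 <- if (di < DENOM_GUARD) {
    warning("inside region empty; c1 falls back to the global image mean",
            call. = FALSE)
    mean(image)
  } else sum(wi * image) / (di + DENOM_GUARD)
  c2 <- if (do < DENOM_GUARD) {
    warning("outside region empty; c2 falls back to the global image mean",
            call. = FALSE)
    mean(image)
  } else sum(wo * image) / (do + DENOM_GUARD)
  structure(list(c1 = c1, c2 = c2), class = "acseg_globalfits")
}

#' Edge-scaled local intensity fits
#'
#' Local region descriptors of the second evolution stage: Gaussian-window
#' weighted fits of the image inside and outside the contour, edge-scaled,
#' `f1 = K_sigma * [H g I] / K_sigma * [H g]` and analogously `f2` with
#' `1 - H`. Both convolutions are zero-padded, so each fit is a
#' Gaussian-weighted mean over in-domain pixels only; `sigma_local`
#' controls the degree of localization, from a small neighborhood to (in
#' the large-sigma limit) the global means. With `g` identically 1 these
#' reduce exactly to the LBF fits.
#'
#' Pixels where a denominator underflows the guard fall back to the
#' corresponding edge-scaled global mean (reported once per call).
#'
#' @inheritParams global_edge_scaled_means
#' @param sigma_local Positive kernel standard deviation (pixels).
#' @return List of class `acseg_localfits` with matrices `f1`, `f2` and
#'   scalar `sigma_local`.
#' @export
local_edge_scaled_fits <- function(image, phi, edge, sigma_local, epsilon) {
  check_positive(sigma_local, "sigma_local")
  stopifnot(identical(dim(image), dim(phi)))
  g <- edge_values(edge, dim(image))
  H <- heaviside(phi, epsilon)
  wi <- H * g
  wo <- (1 - H) * g
  n1 <- gauss_filter_zero(wi * image, sigma_local)
  d1 <- gauss_filter_zero(wi, sigma_local)
  n2 <- gauss_filter_zero(wo * image, sigma_local)
  d2 <- gauss_filter_zero(wo, sigma_local)
  f1 <- n1 / (d1 + DENOM_GUARD)
  f2 <- n2 / (d2 + DENOM_GUARD)
  bad1 <- d1 < DENOM_GUARD
  bad2 <- d2 < DENOM_GUARD
  if (any(bad1) || any(bad2)) {
    gm <- suppressWarnings(global_edge_scaled_means(image, phi, g, epsilon))
    f1[bad1] <- gm$c1
    f2[bad2] <- gm$c2
    message("local fit denominator underflow at ", sum(bad1) + sum(bad2),
            " pixel(s); fell back to global means there")
  }
  structure(list(f1 = f1, f2 = f2, sigma_local = sigma_local),
            class = "acseg_localfits")
}

#' Chan-Vese global means
#'
#' Unscaled global region means (the Chan-Vese descriptors): the special
#' case of [global_edge_scaled_means()] with `g` identically 1.
#'
#' @inheritParams global_edge_scaled_means
#' @return List of class `acseg_globalfits`.
#' @export
chanvese_means <- function(image, phi, epsilon) {
  global_edge_scaled_means(image, phi, NULL, epsilon)
}

#' Local binary fitting (LBF) fits
#'
#' Unscaled local Gaussian-window fits: the special case of
#' [local_edge_scaled_fits()] with `g` identically 1.
#'
#' @inheritParams local_edge_scaled_fits
#' @return List of class `acseg_localfits`.
#' @export
lbf_fits <- function(image, phi, sigma_local, epsilon) {
  local_edge_scaled_fits(image, phi, NULL, sigma_local, epsilon)
}
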