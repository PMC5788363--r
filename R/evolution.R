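#' Configuration of one evolution stage
#'
#' Collects every scalar knob of a single level-set evolution stage.
#' Parameter values follow the conventional 0-255 intensity scale: region
#' forces internally multiply squared intensity residuals (computed on the
#' \[0, 1\] image) by `intensity_scale^2`, so values quoted on the 0-255
#' convention can be entered verbatim.
#'
#' @param w Region-vs-edge balance in \[0, 1\]; large `w` emphasizes the
#'   region force, small `w` the geodesic edge force.
#' @param v Area (stage 1) / length (stage 2, baselines) term weight.
#' @param lambda1,lambda2 Inside/outside region term weights.
#' @param sigma_local Local fitting kernel standard deviation (stage 2,
#'   LBF); `NA` for stages that use global means.
#' @param sigma_edge Gaussian pre-smoothing standard deviation of the edge
#'   stopping function (pixels).
#' @param epsilon Heaviside/Dirac width.
#' @param rho Binary-step initialization magnitude.
#' @param dt Explicit Euler time step.
#' @param max_iter Iteration cap (the fixed stage-1 count N_max, or the
#'   stage-2/baseline cap).
#' @param tol Convergence tolerance on the fraction of pixels whose sign
#'   flips per iteration.
#' @param sigma_reg Gaussian level-set regularization standard deviation
#'   applied after each step; 0 disables it.
#' @param mu Length weight (Chan-Vese) or distance-regularization weight
#'   (LBF); unused by the two proposed stages.
#' @param intensity_scale Intensity convention of the parameter values
#'   (default 255).
#' @param strict_flow If TRUE (default) the proposed-stage region and area
#'   terms are multiplied by both `|grad(phi)|` and `delta_eps(phi)`, as
#'   the flows are defined; FALSE drops the `|grad(phi)|` prefactor on the
#'   Dirac-weighted terms (the conventional form).
#' @return List of class `acseg_config`.
#' @export
stage_config <- function(w = 0.08, v = 1, lambda1 = 1, lambda2 = 1,
                         sigma_local = NA_real_, sigma_edge = 1.5,
                         epsilon = 1, rho = 2, dt = 0.1, max_iter = 10L,
                         tol = 1e-4, sigma_reg = 1, mu = 0,
                         intensity_scale = 255, strict_flow = TRUE) {
  if (!is.na(w) && (w < 0 || w > 1)) stop("w must lie in [0, 1]", call. = FALSE)
  check_positive(dt, "dt")
  check_positive(epsilon, "epsilon")
  check_positive(rho, "rho")
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (sigma_reg < 0) stop("sigma_reg must be >= 0", call. = FALSE)
  structure(list(w = w, v = v, lambda1 = lambda1, lambda2 = lambda2,
                 sigma_local = sigma_local, sigma_edge = sigma_edge,
                 epsilon = epsilon, rho = rho, dt = dt,
                 max_iter = as.integer(max_iter), tol = tol,
                 sigma_reg = sigma_reg, mu = mu,
                 intensity_scale = intensity_scale,
                 strict_flow = isTRUE(strict_flow)),
            class = "acseg_config")
}

step_diagnostics <- function(region, edge_term, phi_old, phi_new) {
  list(region_force_norm = mean(abs(region)),
       edge_force_norm = mean(abs(edge_term)),
       pixels_flipped = sum((phi_old > 0) != (phi_new > 0)))
}

check_step_finite <- function(terms, method) {
  for (nm in names(terms))
    if (!all(is.finite(terms[[nm]])))
      stop("numerical instability in ", method, " step: non-finite values in the ",
           nm, " term", call. = FALSE)
}

# Geodesic edge force shared by both proposed stages:
# g * div(grad phi / |grad phi|) + grad g . grad phi / |grad phi|.
geodesic_term <- function(phi, g) {
  px <- grad_x(phi); py <- grad_y(phi)
  n <- sqrt(px^2 + py^2) + 1e-8
  g * curvature(phi) + grad_x(g) * (px / n) + grad_y(g) * (py / n)
}

#' One explicit step of the global region-edge (GREAC) flow
#'
#' Advances the level-set field by one explicit Euler step of the stage-1
#' gradient-descent flow: the edge-scaled global region force (weighted
#' `w`), the geodesic edge force (weighted `1 - w`) and an area force
#' `-v * delta_eps(phi)`, all multiplied by `|grad(phi)|` as the flow is
#' defined, followed by Gaussian regularization of the field.
#'
#' @param phi Level-set field.
#' @param image Image matrix in \[0, 1\], same shape.
#' @param edge Edge map from [edge_stop_map()].
#' @param fits Global fits from [global_edge_scaled_means()] computed from
#'   the current `phi` (caller's responsibility).
#' @param cfg Stage configuration from [stage_config()].
#' @return List with the updated field `phi` and `diagnostics`
#'   (`region_force_norm`, `edge_force_norm`, `pixels_flipped`).
#' @export
greac_step <- function(phi, image, edge, fits, cfg) {
  g <- edge_values(edge, dim(image))
  s2 <- cfg$intensity_scale^2
  d <- dirac(phi, cfg$epsilon)
  region <- cfg$w * s2 *
    (-cfg$lambda1 * g * (image - fits$c1)^2 +
       cfg$lambda2 * g * (image - fits$c2)^2) * d
  edge_term <- (1 - cfg$w) * geodesic_term(phi, g)
  area <- -cfg$v * d
  gm <- grad_mag(phi)
  phi_new <- if (cfg$strict_flow)
    phi + cfg$dt * gm * (region + edge_term + area)
  else
    phi + cfg$dt * (region + area + gm * edge_term)
  check_step_finite(list(region = region, geodesic = edge_term, area = area,
                         update = phi_new), "GREAC")
  phi_new <- regularize_levelset(phi_new, cfg$sigma_reg)
  list(phi = phi_new,
       diagnostics = step_diagnostics(region, edge_term, phi, phi_new))
}

# K_sigma * |I(x) - f(y)|^2 dy expanded into three Gaussian filterings:
# I^2 (K*1) - 2 I (K*f) + K*(f^2).
local_sq_residual <- function(image, f, sigma_local) {
  ones <- gauss_filter(matrix(1, nrow(image), ncol(image)), sigma_local)
  image^2 * ones - 2 * image * gauss_filter(f, sigma_local) +
    gauss_filter(f^2, sigma_local)
}

#' One explicit step of the local region-edge (LREAC) flow
#'
#' Advances the level-set field by one explicit Euler step of the stage-2
#' flow: the edge-scaled local region force built from Gaussian-window
#' squared residuals against `f1`/`f2` (weighted `w`), the geodesic edge
#' force (weighted `1 - w`) and a length force
#' `v * delta_eps(phi) * div(grad phi/|grad phi|)`, all multiplied by
#' `|grad(phi)|` as defined, followed by Gaussian regularization. The two
#' local integrals are evaluated by three Gaussian filterings each; with
#' `w = 0` they are skipped entirely.
#'
#' @inheritParams greac_step
#' @param fits Local fits from [local_edge_scaled_fits()] computed from
#'   the current `phi`.
#' @export
lreac_step <- function(phi, image, edge, fits, cfg) {
  g <- edge_values(edge, dim(image))
  s2 <- cfg$intensity_scale^2
  d <- dirac(phi, cfg$epsilon)
  region <- if (cfg$w > 0) {
    e1 <- local_sq_residual(image, fits$f1, fits$sigma_local)
    e2 <- local_sq_residual(image, fits$f2, fits$sigma_local)
    -d * cfg$w * s2 * (cfg$lambda1 * g * e1 - cfg$lambda2 * g * e2)
  } else matrix(0, nrow(phi), ncol(phi))
  edge_term <- (1 - cfg$w) * geodesic_term(phi, g)
  len <- cfg$v * d * curvature(phi)
  gm <- grad_mag(phi)
  phi_new <- if (cfg$strict_flow)
    phi + cfg$dt * gm * (region + edge_term + len)
  else
    phi + cfg$dt * (region + len + gm * edge_term)
  check_step_finite(list(region = region, geodesic = edge_term, length = len,
                         update = phi_new), "LREAC")
  phi_new <- regularize_levelset(phi_new, cfg$sigma_reg)
  list(phi = phi_new,
       diagnostics = step_diagnostics(region, edge_term, phi, phi_new))
}

#' One explicit step of the Chan-Vese flow
#'
#' Baseline global region flow:
#' `phi' = phi + dt * delta_eps(phi) * (-lambda1 (I-c1)^2 +
#' lambda2 (I-c2)^2 + mu * curvature - v)`, followed by the same Gaussian
#' level-set regularization used by the proposed stages (no
#' re-initialization). `mu` plays the length-term role.
#'
#' @inheritParams greac_step
#' @param fits Global fits from [chanvese_means()].
#' @export
chanvese_step <- function(phi, image, fits, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- dirac(phi, cfg$epsilon)
  region <- d * s2 * (-cfg$lambda1 * (image - fits$c1)^2 +
                        cfg$lambda2 * (image - fits$c2)^2)
  reg_term <- d * (cfg$mu * curvature(phi) - cfg$v)
  phi_new <- phi + cfg$dt * (region + reg_term)
  check_step_finite(list(region = region, `length/area` = reg_term,
                         update = phi_new), "Chan-Vese")
  phi_new <- regularize_levelset(phi_new, cfg$sigma_reg)
  list(phi = phi_new,
       diagnostics = step_diagnostics(region, reg_term, phi, phi_new))
}

#' One explicit step of the LBF flow
#'
#' Baseline local-fitting flow: local region force from Gaussian-window
#' squared residuals, a length force `v * delta_eps * curvature`, and the
#' distance-regularization penalty `mu * (laplacian(phi) - curvature)`.
#' No Gaussian regularization is applied; the penalty term plays that
#' role.
#'
#' @inheritParams greac_step
#' @param fits Local fits from [lbf_fits()].
#' @export
lbf_step <- function(phi, image, fits, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- dirac(phi, cfg$epsilon)
  e1 <- local_sq_residual(image, fits$f1, fits$sigma_local)
  e2 <- local_sq_residual(image, fits$f2, fits$sigma_local)
  region <- -d * s2 * (cfg$lambda1 * e1 - cfg$lambda2 * e2)
  kappa <- curvature(phi)
  len <- cfg$v * d * kappa
  penalty <- cfg$mu * (laplacian(phi) - kappa)
  phi_new <- phi + cfg$dt * (region + len + penalty)
  check_step_finite(list(region = region, length = len, penalty = penalty,
                         update = phi_new), "LBF")
  list(phi = phi_new,
       diagnostics = step_diagnostics(region, len + penalty, phi, phi_new))
}
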