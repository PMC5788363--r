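#' Full run configuration with named presets
#'
#' Bundles the stage-1 and stage-2 configurations of the two-stage method
#' (or the single-stage configuration of a baseline). The `default` preset
#' carries the method's reference parameter set (per-method force, length, kernel,
#' initialization, Dirac, time-step and balance constants); `ph2` and
#' `brats` carry the dermoscopy and brain-MRI parameter presets.
#'
#' @param preset One of `"default"`, `"ph2"`, `"brats"`.
#' @param method One of `"proposed"`, `"chanvese"`, `"lbf"`.
#' @param ... Named overrides applied to both stages (e.g. `max_iter`,
#'   `sigma_reg`, `strict_flow`).
#' @return List of class `acseg_runconfig` with elements `stage1`,
#'   `stage2` (NULL for baselines), `preset`, `method`.
#' @export
run_config <- function(preset = c("default", "ph2", "brats"),
                       method = c("proposed", "chanvese", "lbf"), ...) {
  preset <- match.arg(preset)
  method <- match.arg(method)
  overrides <- list(...)
  mk <- function(...) {
    args <- list(...)
    args[names(overrides)] <- overrides
    do.call(stage_config, args)
  }
  cfg <- if (method == "proposed") {
    switch(preset,
      default = list(
        stage1 = mk(w = 0.08, v = 1, lambda1 = 1, lambda2 = 1,
                    epsilon = 1, rho = 2, dt = 0.1, max_iter = 10L),
        stage2 = mk(w = 0.01, v = 0.1e-4, lambda1 = 1, lambda2 = 1,
                    sigma_local = 3, epsilon = 1, rho = 2, dt = 0.1,
                    max_iter = 200L, sigma_reg = 0.5)),
      ph2 = list(
        stage1 = mk(w = 0.9, v = 0.0001 * 255 * 255, epsilon = 1, rho = 2,
                    dt = 0.1, max_iter = 10L),
        stage2 = mk(w = 0.001, v = 0.00001 * 255 * 255, sigma_local = 0.3,
                    epsilon = 1, rho = 2, dt = 0.1, max_iter = 200L,
                    sigma_reg = 0.5)),
      brats = list(
        stage1 = mk(w = 0.6, v = 1, epsilon = 1, rho = 2, dt = 0.1,
                    max_iter = 10L),
        stage2 = mk(w = 0.751, v = 0.0001 * 255 * 255, sigma_local = 3,
                    epsilon = 1, rho = 2, dt = 0.1, max_iter = 200L,
                    sigma_reg = 0.5))
    )
  } else if (method == "chanvese") {
    list(stage1 = mk(w = NA_real_, v = 0, lambda1 = 1, lambda2 = 1,
                     epsilon = 1, rho = 2, dt = 0.1, mu = 0.1 * 255^2,
                     max_iter = 200L),
         stage2 = NULL)
  } else {
    list(stage1 = mk(w = NA_real_, v = 0.001 * 255 * 255, lambda1 = 1,
                     lambda2 = 1, sigma_local = 3, epsilon = 1, rho = 2,
                     dt = 0.1, mu = 1, max_iter = 200L),
         stage2 = NULL)
  }
  structure(list(stage1 = cfg$stage1, stage2 = cfg$stage2,
                 preset = preset, method = method),
            class = "acseg_runconfig")
}

#' Convergence check on the iteration history
#'
#' The evolution is declared converged when the fraction of pixels whose
#' sign flipped in an iteration stays below `tol` for `window` consecutive
#' iterations (the trailing `window` entries of the history).
#'
#' @param flip_fraction Numeric vector: per-iteration fraction of sign
#'   flips (`pixels_flipped / total pixels`).
#' @param tol Tolerance on the flip fraction.
#' @param window Number of consecutive qualifying iterations required.
#' @return TRUE if converged, FALSE otherwise (including when fewer than
#'   `window` iterations are recorded).
#' @export
check_convergence <- function(flip_fraction, tol = 1e-4, window = 5L) {
  n <- length(flip_fraction)
  if (n < window) return(FALSE)
  all(flip_fraction[(n - window + 1L):n] < tol)
}

bind_history <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  do.call(rbind, lapply(rows, as.data.frame))
}

default_init_region <- function(shape) {
  h <- shape[1]; w <- shape[2]
  # centered rectangle covering 40% of each dimension
  list(type = "rect",
       x0 = floor(w / 2 - 0.2 * w) + 1, y0 = floor(h / 2 - 0.2 * h) + 1,
       x1 = ceiling(w / 2 + 0.2 * w), y1 = ceiling(h / 2 + 0.2 * h))
}

new_result <- function(phi_final, phi_stage1, it1, it2, converged, history,
                       method) {
  structure(list(mask = matrix(as.integer(phi_final > 0), nrow(phi_final)),
                 phi_final = phi_final, phi_stage1 = phi_stage1,
                 iterations_stage1 = it1, iterations_stage2 = it2,
                 converged = converged, history = history, method = method),
            class = "acseg_result")
}

#' Run the two-stage segmentation
#'
#' Stage 1 evolves the level set under the global region-edge (GREAC) flow
#' for exactly `stage1$max_iter` iterations (no convergence test),
#' recomputing the edge-scaled global means each iteration; the edge
#' stopping map is computed once per stage from the image. Stage 2 takes
#' the stage-1 level set as its initialization and evolves under the local
#' region-edge (LREAC) flow until [check_convergence()] fires or
#' `stage2$max_iter` is reached.
#'
#' @param image Numeric matrix in \[0, 1\] (see [as_image()]); color/raw
#'   inputs should be loaded with [read_image()].
#' @param init_region Initial-contour region (see [initialize_levelset()]);
#'   NULL uses a centered rectangle covering 40% of each dimension.
#' @param cfg Run configuration from [run_config()].
#' @return Object of class `acseg_result`: binary `mask` (1 = inside),
#'   `phi_final`, `phi_stage1`, per-stage iteration counts, `converged`
#'   flag and a per-iteration `history` data frame.
#' @export
run_two_stage <- function(image, init_region = NULL, cfg = run_config()) {
  image <- as_image(image)
  if (is.null(init_region)) init_region <- default_init_region(dim(image))
  s1 <- cfg$stage1; s2 <- cfg$stage2
  stopifnot(!is.null(s2))
  n_pix <- length(image)
  phi <- initialize_levelset(dim(image), init_region, s1$rho)

  edge1 <- edge_stop_map(image, s1$sigma_edge)
  hist_rows <- vector("list", s1$max_iter + s2$max_iter)
  for (n in seq_len(s1$max_iter)) {
    fits <- global_edge_scaled_means(image, phi, edge1, s1$epsilon)
    st <- greac_step(phi, image, edge1, fits, s1)
    phi <- st$phi
    hist_rows[[n]] <- c(stage = 1, iteration = n, st$diagnostics)
  }
  phi_stage1 <- phi

  edge2 <- edge_stop_map(image, s2$sigma_edge)
  flips <- numeric(0)
  converged <- FALSE
  it2 <- 0L
  for (n in seq_len(s2$max_iter)) {
    fits <- local_edge_scaled_fits(image, phi, edge2, s2$sigma_local,
                                   s2$epsilon)
    st <- lreac_step(phi, image, edge2, fits, s2)
    phi <- st$phi
    it2 <- n
    flips <- c(flips, st$diagnostics$pixels_flipped / n_pix)
    hist_rows[[s1$max_iter + n]] <- c(stage = 2, iteration = n,
                                      st$diagnostics)
    if (check_convergence(flips, s2$tol)) { converged <- TRUE; break }
  }
  history <- bind_history(hist_rows)
  new_result(phi, phi_stage1, s1$max_iter, it2, converged, history,
             "proposed")
}

#' Run a single-stage baseline segmentation
#'
#' Evolves the level set under the Chan-Vese or LBF flow with the same
#' initialization and convergence logic as the two-stage driver.
#'
#' @inheritParams run_two_stage
#' @param method `"chanvese"` or `"lbf"`; defaults to `cfg$method`.
#' @return Object of class `acseg_result` (with `phi_stage1 = NULL` and
#'   `iterations_stage1 = 0`).
#' @export
run_baseline <- function(image, init_region = NULL, cfg = NULL,
                         method = c("chanvese", "lbf")) {
  if (is.null(cfg)) {
    method <- match.arg(method)
    cfg <- run_config(method = method)
  } else method <- cfg$method
  stopifnot(method %in% c("chanvese", "lbf"))
  image <- as_image(image)
  if (is.null(init_region)) init_region <- default_init_region(dim(image))
  s <- cfg$stage1
  n_pix <- length(image)
  phi <- initialize_levelset(dim(image), init_region, s$rho)
  flips <- numeric(0)
  converged <- FALSE
  hist_rows <- vector("list", s$max_iter)
  it <- 0L
  for (n in seq_len(s$max_iter)) {
    st <- if (method == "chanvese") {
      fits <- chanvese_means(image, phi, s$epsilon)
      chanvese_step(phi, image, fits, s)
    } else {
      fits <- lbf_fits(image, phi, s$sigma_local, s$epsilon)
      lbf_step(phi, image, fits, s)
    }
    phi <- st$phi
    it <- n
    flips <- c(flips, st$diagnostics$pixels_flipped / n_pix)
    hist_rows[[n]] <- c(stage = 1, iteration = n, st$diagnostics)
    if (check_convergence(flips, s$tol)) { converged <- TRUE; break }
  }
  history <- bind_history(hist_rows)
  new_result(phi, NULL, 0L, it, converged, history, method)
}

#' @export
print.acseg_result <- function(x, ...) {
  cat("<acseg_result>", x$method, "segmentation\n")
  cat("  grid:", paste(dim(x$mask), collapse = " x "),
      " inside pixels:", sum(x$mask), "\n")
  cat("  iterations: stage1 =", x$iterations_stage1,
      ", stage2 =", x$iterations_stage2,
      ", converged =", x$converged, "\n")
  invisible(x)
}

#' Plot a segmentation result
#'
#' Displays the image in grayscale with the final contour (zero level set)
#' overlaid, and optionally the stage-1 contour.
#'
#' @param x `acseg_result`.
#' @param image The image that was segmented (matrix in \[0, 1\]).
#' @param stage1 If TRUE, also draw the stage-1 contour (dashed).
#' @param ... Passed to [graphics::image()].
#' @export
plot.acseg_result <- function(x, image = NULL, stage1 = FALSE, ...) {
  h <- nrow(x$mask); w <- ncol(x$mask)
  if (!is.null(image))
    graphics::image(seq_len(w), seq_len(h), t(image[h:1, ]),
                    col = gray(seq(0, 1, length.out = 256)),
                    xlab = "", ylab = "", asp = 1, ...)
  graphics::contour(seq_len(w), seq_len(h), t(x$phi_final[h:1, ]),
                    levels = 0, add = !is.null(image), col = "red",
                    drawlabels = FALSE)
  if (stage1 && !is.null(x$phi_stage1))
    graphics::contour(seq_len(w), seq_len(h), t(x$phi_stage1[h:1, ]),
                      levels = 0, add = TRUE, col = "orange", lty = 2,
                      drawlabels = FALSE)
  invisible(x)
}

# ---- configuration serialization -------------------------------------------

#' Save / load a run configuration as YAML
#'
#' The YAML mirrors the per-stage parameter names (`lambda1`, `lambda2`,
#' `v`, `sigma_local`, `sigma_edge`, `rho`, `epsilon`, `dt`, `w`, ...).
#' A round-tripped configuration reproduces identical results.
#'
#' @param cfg `acseg_runconfig`.
#' @param path File path.
#' @return `load_config()` returns an `acseg_runconfig`.
#' @export
save_config <- function(cfg, path) {
  strip <- function(s) if (is.null(s)) NULL else unclass(s)
  yaml::write_yaml(list(preset = cfg$preset, method = cfg$method,
                        stage1 = strip(cfg$stage1),
                        stage2 = strip(cfg$stage2)), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(s) if (is.null(s)) NULL else {
    s$sigma_local <- if (is.null(s$sigma_local)) NA_real_ else s$sigma_local
    s$w <- if (is.null(s$w)) NA_real_ else s$w
    do.call(stage_config, s)
  }
  structure(list(stage1 = mk(y$stage1), stage2 = mk(y$stage2),
                 preset = y$preset, method = y$method),
            class = "acseg_runconfig")
}
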