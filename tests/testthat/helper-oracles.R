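# Independent naive implementations used as oracles. Everything here is
# written with explicit scalar loops and index clamping, deliberately
# sharing no code with the package internals.

o_clamp <- function(i, n) min(max(i, 1L), n)

# Direct 2-D Gaussian convolution, replicate borders, radius ceil(4*sigma).
o_gauss_conv <- function(m, sigma) {
  if (sigma == 0) return(m)
  r <- ceiling(4 * sigma)
  k1 <- dnorm(-r:r, sd = sigma)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in -r:r) for (b in -r:r)
      s <- s + K[a + r + 1, b + r + 1] * m[o_clamp(i + a, h), o_clamp(j + b, w)]
    out[i, j] <- s
  }
  out
}

# Central differences with replicate borders, scalar loops.
o_gx <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- (m[i, o_clamp(j + 1, w)] - m[i, o_clamp(j - 1, w)]) / 2
  out
}
o_gy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- (m[o_clamp(i + 1, h), j] - m[o_clamp(i - 1, h), j]) / 2
  out
}
o_gmag <- function(m) sqrt(o_gx(m)^2 + o_gy(m)^2)

o_curvature <- function(phi) {
  px <- o_gx(phi); py <- o_gy(phi)
  n <- sqrt(px^2 + py^2) + 1e-8
  o_gx(px / n) + o_gy(py / n)
}

o_laplacian <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- m[o_clamp(i + 1, h), j] + m[o_clamp(i - 1, h), j] +
      m[i, o_clamp(j + 1, w)] + m[i, o_clamp(j - 1, w)] - 4 * m[i, j]
  out
}

o_heaviside <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
o_dirac <- function(phi, eps) eps / (pi * (phi^2 + eps^2))

# Direct O(N^2) evaluation of int K_sigma(x - y) |I(x) - f(y)|^2 dy with
# the same truncated kernel and replicate (clamped-index) handling.
o_local_sq_residual <- function(I, f, sigma) {
  r <- ceiling(4 * sigma)
  k1 <- dnorm(-r:r, sd = sigma)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  h <- nrow(I); w <- ncol(I)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      fy <- f[o_clamp(i + a, h), o_clamp(j + b, w)]
      s <- s + K[a + r + 1, b + r + 1] * (I[i, j] - fy)^2
    }
    out[i, j] <- s
  }
  out
}

# Term-by-term evaluation of the stage-1 (global region-edge) flow.
o_greac_step <- function(phi, I, g, c1, c2, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- o_dirac(phi, cfg$epsilon)
  region <- cfg$w * s2 * (-cfg$lambda1 * g * (I - c1)^2 +
                            cfg$lambda2 * g * (I - c2)^2) * d
  px <- o_gx(phi); py <- o_gy(phi)
  n <- sqrt(px^2 + py^2) + 1e-8
  geo <- (1 - cfg$w) * (g * o_curvature(phi) +
                          o_gx(g) * px / n + o_gy(g) * py / n)
  area <- -cfg$v * d
  phi2 <- phi + cfg$dt * o_gmag(phi) * (region + geo + area)
  o_gauss_conv(phi2, cfg$sigma_reg)
}

# Term-by-term evaluation of the stage-2 (local region-edge) flow with
# direct-sum local integrals.
o_lreac_step <- function(phi, I, g, f1, f2, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- o_dirac(phi, cfg$epsilon)
  e1 <- o_local_sq_residual(I, f1, cfg$sigma_local)
  e2 <- o_local_sq_residual(I, f2, cfg$sigma_local)
  region <- -d * cfg$w * s2 * (cfg$lambda1 * g * e1 - cfg$lambda2 * g * e2)
  px <- o_gx(phi); py <- o_gy(phi)
  n <- sqrt(px^2 + py^2) + 1e-8
  geo <- (1 - cfg$w) * (g * o_curvature(phi) +
                          o_gx(g) * px / n + o_gy(g) * py / n)
  len <- cfg$v * d * o_curvature(phi)
  phi2 <- phi + cfg$dt * o_gmag(phi) * (region + geo + len)
  o_gauss_conv(phi2, cfg$sigma_reg)
}

o_chanvese_step <- function(phi, I, c1, c2, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- o_dirac(phi, cfg$epsilon)
  upd <- d * (s2 * (-cfg$lambda1 * (I - c1)^2 + cfg$lambda2 * (I - c2)^2) +
                cfg$mu * o_curvature(phi) - cfg$v)
  o_gauss_conv(phi + cfg$dt * upd, cfg$sigma_reg)
}

o_lbf_step <- function(phi, I, f1, f2, cfg) {
  s2 <- cfg$intensity_scale^2
  d <- o_dirac(phi, cfg$epsilon)
  e1 <- o_local_sq_residual(I, f1, cfg$sigma_local)
  e2 <- o_local_sq_residual(I, f2, cfg$sigma_local)
  region <- -d * s2 * (cfg$lambda1 * e1 - cfg$lambda2 * e2)
  kap <- o_curvature(phi)
  phi + cfg$dt * (region + cfg$v * d * kap +
                    cfg$mu * (o_laplacian(phi) - kap))
}
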