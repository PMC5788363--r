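# Small fixtures built in code, shared across test files.

# 5x5 two-level image with a bright 3x3 block, plus a matching binary-step
# level set. Used for term-by-term step-equivalence checks.
fixture_5x5 <- function(rho = 2) {
  I <- matrix(0.2, 5, 5)
  I[2:4, 2:4] <- 0.8
  phi <- matrix(-rho, 5, 5)
  phi[2:4, 2:4] <- rho
  list(image = I, phi = phi)
}

# Deterministic pseudo-random matrix (seeded locally, restores RNG).
fixture_random_field <- function(h, w, seed, lo = 0, hi = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

# Signed distance to a circle centered on an odd-sized grid.
fixture_circle_sdf <- function(n, r) {
  c0 <- (n + 1) / 2
  xs <- matrix(rep(1:n, each = n), n, n)
  ys <- matrix(rep(1:n, times = n), n, n)
  sqrt((xs - c0)^2 + (ys - c0)^2) - r
}
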