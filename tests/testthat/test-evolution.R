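# Every step operation is checked against an independent, naively coded
# term-by-term oracle on small fixtures.

test_that("one GREAC step matches the term-by-term oracle on the 5x5 fixture", {
  fx <- fixture_5x5()
  cfg <- stage_config(w = 0.08, v = 1, dt = 0.1, epsilon = 1, sigma_reg = 1)
  g <- edge_stop_map(fx$image, cfg$sigma_edge)
  fits <- global_edge_scaled_means(fx$image, fx$phi, g, cfg$epsilon)
  st <- greac_step(fx$phi, fx$image, g, fits, cfg)
  oracle <- o_greac_step(fx$phi, fx$image, unclass(g), fits$c1, fits$c2, cfg)
  expect_equal(st$phi, oracle, tolerance = 1e-12)
  # and on a random 8x8 field
  I <- fixture_random_field(8, 8, seed = 31)
  phi <- fixture_random_field(8, 8, seed = 32, lo = -3, hi = 3)
  g <- edge_stop_map(I, 1.5)
  fits <- global_edge_scaled_means(I, phi, g, 1)
  st <- greac_step(phi, I, g, fits, cfg)
  expect_equal(st$phi, o_greac_step(phi, I, unclass(g), fits$c1, fits$c2, cfg),
               tolerance = 1e-10)
})

test_that("GREAC weight algebra: w = 1 removes the geodesic branch; plane phi is a fixed point on constant images", {
  fx <- fixture_5x5()
  g <- edge_stop_map(fx$image, 1.5)
  cfg1 <- stage_config(w = 1, v = 0, sigma_reg = 0)
  fits <- global_edge_scaled_means(fx$image, fx$phi, g, cfg1$epsilon)
  st <- greac_step(fx$phi, fx$image, g, fits, cfg1)
  expect_equal(st$diagnostics$edge_force_norm, 0)
  # constant image, v = 0: update reduces to the curvature branch; a plane
  # has straight level lines so it does not move (regularization off)
  I <- matrix(0.5, 9, 9)
  plane <- matrix(rep(seq(-4, 4), each = 9), 9, 9)
  cfg <- stage_config(w = 0.08, v = 0, sigma_reg = 0)
  g <- edge_stop_map(I, cfg$sigma_edge)
  fits <- global_edge_scaled_means(I, plane, g, cfg$epsilon)
  st <- greac_step(plane, I, g, fits, cfg)
  # fixed up to the 1e-8 gradient floor engaging at the border columns
  expect_lt(max(abs(st$phi - plane)), 1e-6)
})

test_that("one LREAC step matches the direct-sum oracle on the 5x5 fixture", {
  fx <- fixture_5x5()
  cfg <- stage_config(w = 0.01, v = 0.1e-4, sigma_local = 3, dt = 0.1,
                      sigma_reg = 0.5)
  g <- edge_stop_map(fx$image, cfg$sigma_edge)
  fits <- local_edge_scaled_fits(fx$image, fx$phi, g, cfg$sigma_local,
                                 cfg$epsilon)
  st <- lreac_step(fx$phi, fx$image, g, fits, cfg)
  oracle <- o_lreac_step(fx$phi, fx$image, unclass(g), fits$f1, fits$f2, cfg)
  expect_equal(st$phi, oracle, tolerance = 1e-10)
})

test_that("LREAC on a constant image is a pure curvature/edge flow and w = 0 short-circuits the region term", {
  I <- matrix(0.5, 7, 7)
  phi <- fixture_random_field(7, 7, seed = 41, lo = -2, hi = 2)
  g <- edge_stop_map(I, 1.5)
  cfg <- stage_config(w = 0.01, v = 0, sigma_local = 2, sigma_reg = 0)
  fits <- local_edge_scaled_fits(I, phi, g, 2, 1)
  st <- lreac_step(phi, I, g, fits, cfg)
  expect_equal(st$diagnostics$region_force_norm, 0, tolerance = 1e-12)
  # w = 0: identical to a step whose region force is exactly zero
  cfg0 <- stage_config(w = 0, v = 0.1e-4, sigma_local = 3, sigma_reg = 0.5)
  I2 <- fixture_random_field(6, 6, seed = 42)
  phi2 <- fixture_random_field(6, 6, seed = 43, lo = -2, hi = 2)
  g2 <- edge_stop_map(I2, 1.5)
  fits2 <- local_edge_scaled_fits(I2, phi2, g2, 3, 1)
  st0 <- lreac_step(phi2, I2, g2, fits2, cfg0)
  expect_equal(st0$diagnostics$region_force_norm, 0)
  d <- dirac(phi2, 1)
  manual <- phi2 + cfg0$dt * acseg:::grad_mag(phi2) *
    ((1 - 0) * acseg:::geodesic_term(phi2, unclass(g2)) +
       cfg0$v * d * curvature(phi2))
  expect_equal(st0$phi, regularize_levelset(manual, 0.5), tolerance = 1e-12)
})

test_that("the local-integral convolution expansion equals O(N^2) direct summation", {
  for (s in 1:3) {
    I <- fixture_random_field(6, 6, seed = 50 + s)
    f <- fixture_random_field(6, 6, seed = 60 + s)
    for (sigma in c(1, 3)) {
      expect_equal(acseg:::local_sq_residual(I, f, sigma),
                   o_local_sq_residual(I, f, sigma), tolerance = 1e-10)
    }
  }
})

test_that("one Chan-Vese step matches the elementwise oracle and has the right force signs", {
  fx <- fixture_5x5()
  cfg <- stage_config(w = NA_real_, v = 0, mu = 0.1 * 255^2, dt = 0.1,
                      sigma_reg = 1)
  fits <- chanvese_means(fx$image, fx$phi, cfg$epsilon)
  st <- chanvese_step(fx$phi, fx$image, fits, cfg)
  expect_equal(st$phi, o_chanvese_step(fx$phi, fx$image, fits$c1, fits$c2, cfg),
               tolerance = 1e-10)
  # pixel with I closer to c1 than c2 receives positive region force
  I <- fixture_random_field(8, 8, seed = 71)
  phi <- fixture_random_field(8, 8, seed = 72, lo = -2, hi = 2)
  fits <- chanvese_means(I, phi, 1)
  s2 <- cfg$intensity_scale^2
  region <- dirac(phi, 1) * s2 * (-(I - fits$c1)^2 + (I - fits$c2)^2)
  closer_c1 <- abs(I - fits$c1) < abs(I - fits$c2)
  expect_true(all(region[closer_c1] > 0))
  expect_true(all(region[!closer_c1] <= 0))
  # c1 = c2 kills the region force
  cst <- matrix(0.5, 5, 5)
  fits0 <- chanvese_means(cst, fx$phi, 1)
  st0 <- chanvese_step(fx$phi, cst, fits0, cfg)
  expect_equal(st0$diagnostics$region_force_norm, 0, tolerance = 1e-12)
})

test_that("one LBF step matches the direct-sum oracle, including the pure-fitting case", {
  fx <- fixture_5x5()
  cfg <- stage_config(w = NA_real_, v = 0.001 * 255^2, sigma_local = 3,
                      mu = 1, dt = 0.1, sigma_reg = 0)
  fits <- lbf_fits(fx$image, fx$phi, cfg$sigma_local, cfg$epsilon)
  st <- lbf_step(fx$phi, fx$image, fits, cfg)
  expect_equal(st$phi, o_lbf_step(fx$phi, fx$image, fits$f1, fits$f2, cfg),
               tolerance = 1e-10)
  # mu = 0, v = 0: pure local-fitting flow
  cfg0 <- stage_config(w = NA_real_, v = 0, sigma_local = 2, mu = 0, dt = 0.1,
                       sigma_reg = 0)
  fits0 <- lbf_fits(fx$image, fx$phi, 2, 1)
  st0 <- lbf_step(fx$phi, fx$image, fits0, cfg0)
  expect_equal(st0$phi, o_lbf_step(fx$phi, fx$image, fits0$f1, fits0$f2, cfg0),
               tolerance = 1e-10)
  # constant image: no region force
  cst <- matrix(0.5, 5, 5)
  fitsc <- lbf_fits(cst, fx$phi, 2, 1)
  stc <- lbf_step(fx$phi, cst, fitsc, cfg)
  expect_equal(stc$diagnostics$region_force_norm, 0, tolerance = 1e-9)
})

test_that("a half-plane on a constant image with v = 0 is a 100-step fixed point of the mask", {
  img <- matrix(0.4, 30, 30)
  phi <- matrix(rep(c(rep(2, 15), rep(-2, 15)), each = 30), 30, 30)
  cfg <- stage_config(w = 0.08, v = 0)
  e <- edge_stop_map(img, cfg$sigma_edge)
  m0 <- phi > 0
  for (i in 1:100) {
    f <- global_edge_scaled_means(img, phi, e, cfg$epsilon)
    phi <- greac_step(phi, img, e, f, cfg)$phi
  }
  expect_identical(phi > 0, m0)
})

test_that("a pure area force shrinks the inside monotonically", {
  img <- matrix(0.5, 24, 24)  # constant: region force vanishes
  cfg <- stage_config(w = 1, v = 2)  # w = 1 disables the geodesic branch
  phi <- initialize_levelset(c(24, 24), list(type = "circle", cx = 12, cy = 12,
                                             r = 8), cfg$rho)
  e <- edge_stop_map(img, cfg$sigma_edge)
  # the zero-valued boundary ring of the binary-step init resolves to a
  # sign at the first smoothing; the area force then shrinks monotonically
  areas <- integer(40)
  for (i in 1:40) {
    f <- global_edge_scaled_means(img, phi, e, cfg$epsilon)
    phi <- greac_step(phi, img, e, f, cfg)$phi
    areas[i] <- sum(phi > 0)
  }
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[40], areas[1])
})

test_that("halving the time step and doubling iterations changes the stage-1 mask by under 1%", {
  ph <- generate_phantom(phantom_spec(size = c(64, 64), seed = 1))
  run_stage1 <- function(dt, iters) {
    s <- stage_config(dt = dt, max_iter = iters)
    p <- initialize_levelset(dim(ph$image),
                             acseg:::default_init_region(dim(ph$image)), s$rho)
    e <- edge_stop_map(ph$image, s$sigma_edge)
    for (i in seq_len(iters)) {
      f <- global_edge_scaled_means(ph$image, p, e, s$epsilon)
      p <- greac_step(p, ph$image, e, f, s)$phi
    }
    p > 0
  }
  mA <- run_stage1(0.1, 10)
  mB <- run_stage1(0.05, 20)
  expect_lt(mean(mA != mB), 0.01)
})

test_that("numerical instability is reported with the offending term named", {
  fx <- fixture_5x5()
  cfg <- stage_config()
  g <- edge_stop_map(fx$image, cfg$sigma_edge)
  fits <- global_edge_scaled_means(fx$image, fx$phi, g, cfg$epsilon)
  fits$c1 <- NaN
  expect_error(greac_step(fx$phi, fx$image, g, fits, cfg), "region")
})
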