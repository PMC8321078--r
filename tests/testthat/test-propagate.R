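test_that("three-transform convolution matches the direct double-sum oracle", {
  g <- make_grid(16, 16, matched_pixel_pitch(16, 0.02, qpi_lambda), qpi_lambda)
  set.seed(4)
  f <- complex_field(matrix(complex(real = runif(1024), imaginary = runif(1024)),
                            32, 32), g, "sample")
  for (kind in c("spherical", "quadratic")) {
    k <- if (kind == "spherical") spherical_kernel(g, 0.02)
         else quadratic_phase(g, 1 / 0.02)
    got <- propagate(f, k)$values
    want <- brute_convolve(f$values, k$values)
    want <- want * sqrt(sum(Mod(f$values)^2) / sum(Mod(want)^2))
    expect_lt(rel_rms(got, want), 1e-6)
  }
})

test_that("propagation conserves total power and shape", {
  fx <- ring_fixture(n = 64, d2 = 0.05)
  f <- apply_phase_object(point_source_illumination(fx$grid, Inf), fx$reference)
  out <- propagate(f, spherical_kernel(fx$grid, 0.05))
  expect_identical(dim(out$values), dim(f$values))
  expect_equal(sum(Mod(out$values)^2), sum(Mod(f$values)^2))
  expect_error(propagate(f, spherical_kernel(make_grid(32, 32, 1e-6, qpi_lambda), 0.05)),
               "different")
})

test_that("round-trip propagation (+d then -d) restores the central region", {
  fx <- ring_fixture(n = 128)
  f <- apply_phase_object(point_source_illumination(fx$grid, Inf), fx$reference)
  rt <- propagate(propagate(f, spherical_kernel(fx$grid, fx$d2)),
                  spherical_kernel(fx$grid, -fx$d2))
  err <- rel_rms(crop_central(rt$values, fx$grid), crop_central(f$values, fx$grid))
  expect_lt(err, 0.05)
})

test_that("a uniform field propagates to uniform central intensity", {
  g <- make_grid(64, 64, matched_pixel_pitch(64, 0.05, qpi_lambda), qpi_lambda)
  f <- point_source_illumination(g, Inf)
  out <- propagate(f, spherical_kernel(g, 0.05))
  q <- Mod(out$values[(64 - 15):(64 + 16), (64 - 15):(64 + 16)])^2
  expect_lt(diff(range(q)) / mean(q), 0.01)
})

test_that("spherical and quadratic propagation agree in the paraxial regime", {
  fx <- ring_fixture(n = 64, d2 = 0.5)   # grid extent << d
  f <- apply_phase_object(point_source_illumination(fx$grid, Inf), fx$reference)
  a <- propagate(f, spherical_kernel(fx$grid, fx$d2))
  b <- propagate(f, quadratic_phase(fx$grid, 1 / fx$d2))
  ia <- Mod(crop_central(a$values, fx$grid))^2
  ib <- Mod(crop_central(b$values, fx$grid))^2
  expect_lt(sqrt(mean((ia - ib)^2)) / sqrt(mean(ia^2)), 0.01)
})

test_that("sensor intensity is normalized, non-negative and matches the oracle", {
  g <- make_grid(16, 16, matched_pixel_pitch(16, 0.02, qpi_lambda), qpi_lambda)
  set.seed(5)
  phase <- matrix(runif(16 * 16, 0, 1), 16, 16)
  f <- apply_phase_object(point_source_illumination(g, Inf), phase)
  got <- sensor_intensity(f, 0.02)
  expect_identical(dim(got), c(16L, 16L))
  expect_gte(min(got), 0)
  expect_equal(max(got), 1)
  k <- spherical_kernel(g, 0.02)
  want <- brute_convolve(f$values, k$values)
  want <- Mod(want[9:24, 9:24])^2
  want <- want / max(want)
  expect_lt(rel_rms(got, want), 1e-6)
  expect_error(sensor_intensity(f, -0.1), "positive")
})

test_that("illumination is unit-modulus and tends to a plane wave for a far source", {
  g <- make_grid(64, 64, 4.65e-6, qpi_lambda)
  f <- point_source_illumination(g, 2.0)
  expect_lt(max(abs(Mod(f$values) - 1)), 1e-12)
  # far source: phase variation across the grid below 0.1 rad
  extent2 <- (max(g$X)^2 + max(g$Y)^2)
  far <- 100 * extent2 / qpi_lambda
  pf <- point_source_illumination(g, far)
  spread <- diff(range(Arg(pf$values * Conj(pf$values[65, 65]))))
  expect_lt(spread, 0.1)
  # phase at the grid edge matches the scalar formula
  edge <- exp(1i * 2 * pi * sqrt(g$X[1, 1]^2 + g$Y[1, 1]^2 + 4) / qpi_lambda)
  expect_equal(f$values[1, 1], edge)
  expect_error(point_source_illumination(g, -1), "positive")
})

test_that("phase objects modulate phase only and compose invertibly", {
  fx <- ring_fixture(n = 64)
  f <- point_source_illumination(fx$grid, Inf)
  mod <- apply_phase_object(f, fx$reference)
  expect_equal(Mod(mod$values), Mod(f$values))
  back <- apply_phase_object(mod, phase_map(-fx$reference$values))
  expect_equal(back$values, f$values)
  expect_equal(apply_phase_object(f, matrix(0, 64, 64))$values, f$values)
  expect_error(apply_phase_object(f, matrix(0, 5, 5)), "matches neither")
})
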