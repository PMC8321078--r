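test_that("binary phase steps follow 2*pi*t*(n-1)/lambda and scale linearly", {
  mask <- builtin_phantom("disc", 64)
  # 530 nm of n = 1.5 material at 530 nm -> exactly pi
  pm <- binary_phase_from_mask(mask, 530e-9, 1.5, 530e-9)
  expect_equal(max(pm$values), pi)
  expect_equal(sort(unique(as.vector(pm$values))), c(0, pi))
  # 800 nm -> about 1.5 pi
  pm2 <- binary_phase_from_mask(mask, 800e-9, 1.5, 530e-9)
  expect_equal(max(pm2$values) / pi, 800 / 530, tolerance = 1e-12)
  # linear in t and in (n - 1)
  expect_equal(max(binary_phase_from_mask(mask, 2 * 530e-9, 1.5, 530e-9)$values),
               2 * max(pm$values))
  expect_equal(max(binary_phase_from_mask(mask, 530e-9, 2.0, 530e-9)$values),
               2 * max(pm$values))
  expect_equal(max(binary_phase_from_mask(mask, 0, 1.5, 530e-9)$values), 0)
  expect_error(binary_phase_from_mask(mask * 0.5, 530e-9, 1.5, 530e-9), "binary")
})

test_that("the linear ramp spans 0..max_phase and wraps into 4 fringes at 8*pi", {
  pm <- linear_ramp_phase(128, 8 * pi)
  expect_equal(max(pm$values), 8 * pi)
  expect_equal(min(pm$values), 0)
  w <- linear_ramp_phase(128, 8 * pi, wrapped = TRUE)
  expect_true(w$wrapped)
  expect_gte(min(w$values), 0)
  expect_lt(max(w$values), 2 * pi)
  # 4 sawtooth periods: falling edges along a mid row of the region (the
  # endpoint at exactly 8*pi wraps back to 0, giving the 4th edge)
  mid <- w$values[64, w$support[64, ]]
  expect_equal(sum(diff(mid) < -pi), 4)
  # wrap/unwrap inverse on the noiseless ramp
  u <- unwrap_phase(w)
  expect_equal(max(u$values[u$support]), 8 * pi, tolerance = 1e-9)
  expect_equal(linear_ramp_phase(64, 0)$values, matrix(0, 64, 64))
})

test_that("the scattering layer is deterministic and concentrates far-field power", {
  sl <- scattering_layer(200, 0.12, iterations = 50, seed = 7)
  sl2 <- scattering_layer(200, 0.12, iterations = 50, seed = 7)
  expect_identical(sl$values, sl2$values)
  expect_gte(min(sl$values), 0)
  expect_lt(max(sl$values), 2 * pi)
  expect_gte(farfield_power_ratio(sl, 0.12), 0.8)
  # error-reduction behaviour: target-support power non-decreasing early on
  hist <- attr(sl, "power_history")
  expect_true(all(diff(hist[1:10]) >= -1e-12))
  # sigma = 0 degenerates to a flat layer
  expect_equal(scattering_layer(64, 0, seed = 1)$values, matrix(0, 64, 64))
  expect_error(scattering_layer(64, 1.2), "sigma")
})

test_that("builtin phantoms are binary, deterministic and sized as drawn", {
  for (nm in c("disc", "annulus", "star", "silhouette")) {
    m <- builtin_phantom(nm, 256)
    expect_true(all(m %in% c(0, 1)), info = nm)
    expect_identical(m, builtin_phantom(nm, 256), info = nm)
    expect_gt(sum(m), 0)
  }
  # disc area matches pi * r^2 within 2 %
  m <- builtin_phantom("disc", 256)
  expect_equal(sum(m), pi * (0.25 * 256)^2, tolerance = 0.02)
  expect_error(builtin_phantom("nonesuch", 64), "unknown")
})

test_that("two-plane objects compose the forward model through both planes", {
  n <- 64L
  d2 <- 0.05
  px <- matched_pixel_pitch(n, d2, qpi_lambda)
  g <- make_grid(n, n, px, qpi_lambda)
  pa <- phase_map(0.5 * ring_mask(n))
  pb <- phase_map(0.5 * builtin_phantom("disc", n))
  obj <- two_plane_object(pa, pb, d1 = Inf, delta_d = 0.05, d2 = d2)
  expect_s3_class(obj, "qpi_thick")
  expect_equal(obj$sensor_distances, c(0.10, 0.05))
  # an empty second plane reduces to a single object at delta_d + d2
  # (two sequential sampled-chirp convolutions equal one long-distance
  #  convolution only up to discretization error)
  obj0 <- two_plane_object(pa, phase_map(matrix(0, n, n)), Inf, 0.05, d2)
  i_two <- simulate_intensity(obj0, g)
  i_one <- simulate_intensity(pa, g, d2 = 0.10, d1 = Inf)
  expect_lt(rel_rms(i_two, i_one), 0.05)
  # both planes empty: uniform central intensity
  obj00 <- two_plane_object(phase_map(matrix(0, n, n)),
                            phase_map(matrix(0, n, n)), Inf, 0.05, d2)
  ii <- simulate_intensity(obj00, g)
  q <- ii[(n/2 - 15):(n/2 + 16), (n/2 - 15):(n/2 + 16)]
  expect_lt(diff(range(q)) / mean(q), 0.02)
  expect_error(two_plane_object(pa, pb, Inf, -0.1, d2), "positive")
})

test_that("wrapped maps stay in [0, 2*pi) and phase_map validates input", {
  x <- matrix(seq(-10, 10, length.out = 25), 5)
  w <- wrap_phase(x)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_equal((w - x) %% (2 * pi), matrix(0, 5, 5), tolerance = 1e-12)
  expect_error(phase_map(matrix(c(1, NA, 2, 3), 2)), "finite")
  expect_error(phase_map(matrix(7, 2, 2), wrapped = TRUE), "wrapped")
})
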