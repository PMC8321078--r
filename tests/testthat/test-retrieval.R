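test_that("the sensor amplitude is normalized, square-rooted and zero-padded", {
  g <- make_grid(8, 8, 1e-6, qpi_lambda)
  a <- prepare_sensor_amplitude(matrix(1, 8, 8), g)
  expect_identical(dim(a$values), c(16L, 16L))
  expect_equal(Mod(a$values[5:12, 5:12]), matrix(1, 8, 8))
  expect_equal(sum(Mod(a$values)), 64)   # border all zero
  # scale invariance of the normalization
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  expect_equal(prepare_sensor_amplitude(img, g)$values,
               prepare_sensor_amplitude(7.3 * img, g)$values)
  # total power equals the sum of the normalized intensity
  expect_equal(sum(Mod(prepare_sensor_amplitude(img, g)$values)^2),
               sum(img / max(img)))
  expect_error(prepare_sensor_amplitude(img - 1, g), "non-negative")
  expect_error(prepare_sensor_amplitude(matrix(0, 8, 8), g), "zero")
})

test_that("retrieval is deterministic and flat for a zero-phase object", {
  fx <- ring_fixture(n = 128)
  flat <- simulate_intensity(phase_map(matrix(0, 128, 128)), fx$grid,
                             d2 = fx$d2, d1 = Inf, amplitude = fx$aperture)
  cfg <- retrieval_config(fx$d2, max_iterations = 20, stop_tolerance = 0)
  r1 <- gsa_retrieve(flat, cfg, fx$grid, sample_amplitude = fx$aperture)
  r2 <- gsa_retrieve(flat, cfg, fx$grid, sample_amplitude = fx$aperture)
  expect_identical(r1$phase$values, r2$phase$values)
  expect_lt(sd(r1$phase$values[fx$aperture > 0]), 0.1)
})

test_that("the sensor-amplitude error is non-increasing and the correlation rises", {
  fx <- ring_fixture(n = 128)
  cfg <- retrieval_config(fx$d2, max_iterations = 40, stop_tolerance = 0)
  res <- gsa_retrieve(fx$intensity, cfg, fx$grid, reference_phase = fx$reference,
                      sample_amplitude = fx$aperture)
  expect_equal(res$iterations_run, 40)
  expect_length(res$error_history, 40)
  expect_length(res$correlation_history, 40)
  expect_true(all(diff(res$error_history) <= 1e-9 * res$error_history[1]))
  # rise-and-stabilize: clearly above the start, small late drift
  corr <- res$correlation_history
  expect_gt(tail(corr, 1), 2 * corr[1])
  expect_lt(max(abs(diff(tail(corr, 10)))), 0.01)
})

test_that("a pi/2 line object is recovered within tolerance at the module scale", {
  fx <- ring_fixture(n = 128, step = pi / 2)
  cfg <- retrieval_config(fx$d2, max_iterations = 50, stop_tolerance = 0)
  res <- gsa_retrieve(fx$intensity, cfg, fx$grid, sample_amplitude = fx$aperture)
  est <- step_height(res$phase$values, support = fx$mask > 0,
                     background = fx$aperture > 0 & fx$mask == 0,
                     circular = TRUE)
  expect_lt(abs(est - pi / 2) / (pi / 2), 0.15)
})

test_that("the stopping rule halts before the iteration cap on a stable score", {
  fx <- ring_fixture(n = 128)
  cfg <- retrieval_config(fx$d2, max_iterations = 100, stop_tolerance = 1e-3,
                          stop_window = 5)
  res <- gsa_retrieve(fx$intensity, cfg, fx$grid, reference_phase = fx$reference,
                      sample_amplitude = fx$aperture)
  expect_true(res$converged)
  expect_lt(res$iterations_run, 100)
})

test_that("effective_distance implements (1/d2 - 1/d1)^-1 with its limits", {
  expect_equal(effective_distance(2.0, 0.2), 1 / (1 / 0.2 - 1 / 2.0))
  expect_equal(round(100 * effective_distance(2.0, 0.2), 1), 22.2)
  expect_equal(effective_distance(0.10, 0.05), 0.10)
  expect_equal(effective_distance(Inf, 0.2), 0.2)
  expect_error(effective_distance(0.1, 0.2), "d2 < d1")
  expect_error(effective_distance(0.2, 0.2), "d2 < d1")
  expect_error(effective_distance(2, -1), "positive")
})

test_that("retrieval at the corrected distance beats the raw distance under spherical illumination", {
  fx <- ring_fixture(n = 128)
  isph <- simulate_intensity(fx$reference, fx$grid, d2 = fx$d2, d1 = 2,
                             illumination = "spherical", amplitude = fx$aperture)
  cfg <- function(d) retrieval_config(d, max_iterations = 30, stop_tolerance = 0)
  raw <- gsa_retrieve(isph, cfg(fx$d2), fx$grid, reference_phase = fx$reference,
                      sample_amplitude = fx$aperture)
  cor <- gsa_retrieve(isph, cfg(effective_distance(2, fx$d2)), fx$grid,
                      reference_phase = fx$reference, sample_amplitude = fx$aperture)
  expect_gt(tail(cor$correlation_history, 1), tail(raw$correlation_history, 1))
})

test_that("a single-plane refocus scan scores best at the true distance", {
  fx <- ring_fixture(n = 128)
  cfg <- retrieval_config(fx$d2, max_iterations = 20, stop_tolerance = 0)
  scan <- refocus_scan(fx$intensity, cfg, fx$grid,
                       distances = c(0.8, 1, 1.2) * fx$d2,
                       sample_amplitude = fx$aperture)
  expect_equal(scan$best, fx$d2)
  expect_identical(nrow(scan$summary), 3L)
  expect_error(refocus_scan(fx$intensity, cfg, fx$grid, numeric(0)),
               "at least one")
  expect_error(refocus_scan(fx$intensity, cfg, fx$grid, c(0.1, -0.2)),
               "positive")
})
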