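#' Phase-only-filter cross-correlation of two phase maps
#'
#' Measures the similarity between a reference phase map and a
#' reconstruction: the 2D cross-correlation is computed through Fourier
#' transforms with a phase-only filter applied to the test map's spectrum
#' (the spectrum is divided by its modulus, floor-guarded), and the squared
#' modulus at zero lag is reported.  The score is normalized by the
#' reference's own autocorrelation value computed the same way, so that a
#' map correlated with itself scores exactly 1.
#'
#' @param reference Reference phase map (`qpi_phase` or matrix, radians).
#' @param test Test phase map of the same dimensions.
#' @param keep_surface Retain the full correlation surface (centred).
#' @param floor Relative floor for the phase-only filter's modulus guard.
#' @return An object of class `qpi_correlation`: `value_at_origin`,
#'   `autocorrelation_reference`, `normalized_score`, and optionally
#'   `surface`.
#' @export
phase_correlation <- function(reference, test, keep_surface = FALSE,
                              floor = 1e-12) {
  ref <- phase_values(reference)
  tst <- phase_values(test)
  if (!all(dim(ref) == dim(tst)))
    stop("reference and test maps must have the same dimensions", call. = FALSE)
  if (all(ref == 0) || all(tst == 0))
    stop("degenerate input: all-zero phase map", call. = FALSE)
  Fr <- fft2(ref)
  pof_corr0 <- function(Ft) {
    pof <- Ft / pmax(Mod(Ft), floor)
    S <- ifft2(Fr * Conj(pof))
    list(S = S, value = Mod(S[1, 1])^2)
  }
  cross <- pof_corr0(fft2(tst))
  auto <- pof_corr0(Fr)$value
  structure(
    list(value_at_origin = cross$value,
         autocorrelation_reference = auto,
         normalized_score = cross$value / auto,
         surface = if (keep_surface) fftshift2(Mod(cross$S)^2)),
    class = "qpi_correlation")
}

#' @export
print.qpi_correlation <- function(x, ...) {
  cat(sprintf("<qpi_correlation> normalized score %.4f (C(0,0) = %.4g, auto = %.4g)\n",
              x$normalized_score, x$value_at_origin,
              x$autocorrelation_reference))
  invisible(x)
}

#' Convert between phase and physical thickness
#'
#' For a sample of refractive index `n` in air, a thickness `t` delays the
#' phase by `2*pi*t*(n - 1)/lambda`.  `thickness_from_phase()` is the exact
#' inverse.  E.g. t = 530 nm at n = 1.5 and lambda = 530 nm gives pi rad.
#'
#' @param t Thickness in metres (>= 0, vectorized).
#' @param phase Phase in radians (vectorized).
#' @param n Refractive index (> 1).
#' @param wavelength Wavelength in metres (> 0).
#' @return Phase in radians, or thickness in metres.
#' @export
phase_from_thickness <- function(t, n, wavelength) {
  check_material(n, wavelength)
  if (any(t < 0)) stop("thickness must be >= 0", call. = FALSE)
  2 * pi * t * (n - 1) / wavelength
}

#' @rdname phase_from_thickness
#' @export
thickness_from_phase <- function(phase, n, wavelength) {
  check_material(n, wavelength)
  phase * wavelength / (2 * pi * (n - 1))
}

check_material <- function(n, wavelength) {
  if (!is.numeric(n) || n <= 1)
    stop("refractive index must exceed 1", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Imaging geometry and its figures of merit
#'
#' Bundles the pinhole-sample distance `d1`, sample-sensor distance `d2`
#' and the sensor diameter `D`, from which the geometric-projection
#' magnification `M = 1 + d2/d1`, the numerical aperture
#' `NA = D / (2*(d1 + d2))` and the illumination-corrected reconstruction
#' distance `d2'` follow.
#'
#' @param d1 Source-to-sample distance in metres.
#' @param d2 Sample-to-sensor distance in metres.
#' @param sensor_diameter Sensor diameter `D` in metres; derived as
#'   `pixel * max(n1, n2)` when a grid is given instead.
#' @param grid Optional `qpi_grid` used to derive `D` and the pixel pitch.
#' @param pixel Pixel pitch in metres (optional when `grid` is given).
#' @return An object of class `qpi_geometry` with fields `d1`, `d2`, `D`,
#'   `pixel`, `magnification`, `na`, `effective_d2`.
#' @export
imaging_geometry <- function(d1, d2, sensor_diameter = NULL, grid = NULL,
                             pixel = NULL) {
  if (!is.numeric(d1) || d1 <= 0 || !is.numeric(d2) || d2 <= 0)
    stop("distances must be positive", call. = FALSE)
  if (is.null(sensor_diameter)) {
    if (is.null(grid)) stop("either sensor_diameter or grid is required", call. = FALSE)
    sensor_diameter <- grid$pixel * max(grid$n1, grid$n2)
    pixel <- grid$pixel
  }
  structure(
    list(d1 = d1, d2 = d2, D = sensor_diameter, pixel = pixel,
         magnification = magnification(d1, d2),
         na = sensor_diameter / (2 * (d1 + d2)),
         effective_d2 = if (d2 < d1) effective_distance(d1, d2) else NA_real_),
    class = "qpi_geometry")
}

#' @export
print.qpi_geometry <- function(x, ...) {
  cat(sprintf("<qpi_geometry> d1 = %.4g m, d2 = %.4g m, D = %.4g mm\n",
              x$d1, x$d2, x$D * 1e3))
  cat(sprintf("  M = %.4g, NA = %.4g, effective d2' = %.4g m\n",
              x$magnification, x$na, x$effective_d2))
  invisible(x)
}

#' Geometric-projection magnification
#'
#' `M = 1 + d2/d1`; tends to 1 as the sample approaches the sensor or the
#' source recedes to infinity.
#'
#' @param d1 Source-to-sample distance in metres (> 0, may be `Inf`).
#' @param d2 Sample-to-sensor distance in metres (> 0).
#' @return The magnification (>= 1).
#' @export
magnification <- function(d1, d2) {
  if (!is.numeric(d1) || d1 <= 0 || !is.numeric(d2) || d2 < 0)
    stop("distances must be positive", call. = FALSE)
  1 + d2 / d1
}

#' Numerical aperture of the lensless geometry
#'
#' `NA = D / (2*(d1 + d2))` for sensor diameter `D`.
#'
#' @param geometry A `qpi_geometry`.
#' @return The numerical aperture.
#' @export
numerical_aperture <- function(geometry) {
  stopifnot(inherits(geometry, "qpi_geometry"))
  geometry$na
}

#' Two-pass 2D phase unwrapping
#'
#' Removes modulo-2*pi discontinuities with a separable scheme built from
#' repeated 1D unwrapping: the first column is unwrapped top to bottom,
#' then every row is unwrapped left to right and shifted so its first
#' sample agrees with the unwrapped anchor column.  Exact for noiseless
#' maps whose true pixel-to-pixel increments stay below pi along the
#' unwrapping paths; noisy maps may unwrap imperfectly (no error is
#' raised — quality is for the caller to judge).  The output differs from
#' the input by integer multiples of 2*pi at every pixel.
#'
#' @param wrapped A `qpi_phase` or matrix of wrapped phase (radians).
#' @return An unwrapped `qpi_phase` (or matrix, matching the input type).
#' @export
unwrap_phase <- function(wrapped) {
  v <- phase_values(wrapped)
  anchor <- signal::unwrap(v[, 1L])
  u <- t(apply(v, 1L, signal::unwrap))
  u <- u + (anchor - u[, 1L])
  if (inherits(wrapped, "qpi_phase")) {
    out <- wrapped
    out$values <- u
    out$wrapped <- FALSE
    out
  } else u
}
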