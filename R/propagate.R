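#' Propagate a field by FFT-based convolution with a kernel
#'
#' Free-space propagation is a 2D convolution of the field with a sampled
#' propagation kernel, computed as three Fourier transforms:
#' `conv(f, k) = IFFT(FFT(f) * FFT(k))`.  Both operands are stored with the
#' origin at the grid centre; the kernel is rolled to the DFT origin before
#' transforming so the convolution is centred.  Because the sampled chirp
#' kernel is not exactly energy-preserving, the output is rescaled so that
#' total output power equals total input power (set `normalize = FALSE` for
#' the raw circular convolution).
#'
#' @param field A `qpi_field`.
#' @param kernel A `qpi_kernel` on a grid of the same dimensions.
#' @param normalize Rescale output power to input power (default `TRUE`).
#' @return The propagated `qpi_field`.
#' @export
propagate <- function(field, kernel, normalize = TRUE) {
  stopifnot(inherits(field, "qpi_field"), inherits(kernel, "qpi_kernel"))
  if (!all(dim(field$values) == dim(kernel$values)))
    stop("field and kernel are sampled on different computational spaces",
         call. = FALSE)
  out <- ifft2(fft2(field$values) * fft2(ifftshift2(kernel$values)))
  if (normalize) {
    p_in <- sum(Mod(field$values)^2)
    p_out <- sum(Mod(out)^2)
    if (p_out > 0) out <- out * sqrt(p_in / p_out)
  }
  complex_field(out, field$grid, plane = field$plane)
}

#' Intensity recorded by the sensor
#'
#' Propagates the post-sample field a distance `d2` to the sensor plane,
#' takes the squared modulus, crops the central sensor-sized block, and
#' normalizes the peak to 1 (the forward model drops absolute intensity
#' constants).
#'
#' @param field_at_sample A `qpi_field` just after the sample.
#' @param d2 Sample-to-sensor distance in metres (> 0).
#' @param kind Propagation kernel: exact `"spherical"` (default) or paraxial
#'   `"quadratic"`.
#' @return An `n1 x n2` real matrix with values in `[0, 1]` and max 1.
#' @export
sensor_intensity <- function(field_at_sample, d2,
                             kind = c("spherical", "quadratic")) {
  stopifnot(inherits(field_at_sample, "qpi_field"))
  kind <- match.arg(kind)
  if (!is.numeric(d2) || length(d2) != 1L || !is.finite(d2) || d2 <= 0)
    stop("sample-to-sensor distance d2 must be positive", call. = FALSE)
  grid <- field_at_sample$grid
  kernel <- switch(kind,
    spherical = spherical_kernel(grid, d2),
    quadratic = quadratic_phase(grid, 1 / d2))
  at_sensor <- propagate(field_at_sample, kernel)
  intensity <- Mod(crop_central(at_sensor$values, grid))^2
  peak <- max(intensity)
  if (peak > 0) intensity <- intensity / peak
  intensity
}

#' Simulate the recorded intensity of a phase object
#'
#' Convenience composition of the full forward model: point-source
#' illumination at distance `d1`, pure-phase modulation by the object, and
#' propagation by `d2` to the sensor.  For a two-plane thick object the
#' field is modulated by the first plane, propagated across the plane
#' spacing, modulated by the second plane and then propagated to the sensor.
#'
#' @param object A [phase_map()] (or phase matrix), or a [two_plane_object()].
#' @param grid A `qpi_grid`.
#' @param ... Passed on to methods.
#' @return An `n1 x n2` intensity matrix, peak-normalized to 1.
#' @export
simulate_intensity <- function(object, grid, ...) UseMethod("simulate_intensity")

#' @rdname simulate_intensity
#' @param d1 Source-to-sample distance in metres (`Inf` for plane-wave
#'   illumination).
#' @param d2 Sample-to-sensor distance in metres.
#' @param illumination Illumination kind, see [point_source_illumination()].
#' @param kernel Sensor propagation kernel kind, see [sensor_intensity()].
#' @param amplitude Optional transmission mask applied together with the
#'   phase (amplitude objects); `NULL` for a pure phase object.
#' @export
simulate_intensity.qpi_phase <- function(object, grid, d2, d1 = Inf,
                                         illumination = "spherical",
                                         kernel = "spherical",
                                         amplitude = NULL, ...) {
  field <- point_source_illumination(grid, d1, kind = if (is.infinite(d1)) "plane" else illumination)
  field <- apply_phase_object(field, object)
  if (!is.null(amplitude)) field <- apply_amplitude_mask(field, amplitude)
  sensor_intensity(field, d2, kind = kernel)
}

#' @rdname simulate_intensity
#' @export
simulate_intensity.matrix <- function(object, grid, d2, d1 = Inf,
                                      illumination = "spherical",
                                      kernel = "spherical",
                                      amplitude = NULL, ...) {
  simulate_intensity.qpi_phase(object, grid, d2 = d2, d1 = d1,
                               illumination = illumination, kernel = kernel,
                               amplitude = amplitude, ...)
}

#' @rdname simulate_intensity
#' @export
simulate_intensity.qpi_thick <- function(object, grid,
                                         illumination = "spherical",
                                         kernel = "spherical",
                                         amplitude = NULL, ...) {
  d1 <- object$d1
  field <- point_source_illumination(grid, d1, kind = if (is.infinite(d1)) "plane" else illumination)
  if (!is.null(amplitude)) field <- apply_amplitude_mask(field, amplitude)
  field <- apply_phase_object(field, object$planes[[1]]$phase)
  spacing <- diff(vapply(object$planes, `[[`, numeric(1), "z"))
  for (i in seq_along(spacing)) {
    step <- switch(kernel,
      spherical = spherical_kernel(grid, spacing[i]),
      quadratic = quadratic_phase(grid, 1 / spacing[i]))
    field <- propagate(field, step)
    field <- apply_phase_object(field, object$planes[[i + 1L]]$phase)
  }
  sensor_intensity(field, object$d2, kind = kernel)
}
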