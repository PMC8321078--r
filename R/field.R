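#' Construct a complex optical field on a grid
#'
#' @param values Complex (or real) matrix over the full computational space.
#' @param grid A `qpi_grid`.
#' @param plane Free-text plane label ("sample", "sensor", ...).
#' @return An object of class `qpi_field`.
#' @export
complex_field <- function(values, grid, plane = "other") {
  stopifnot(inherits(grid, "qpi_grid"))
  if (!is.matrix(values) || !all(dim(values) == grid_dim(grid)))
    stop("field values must be a matrix over the full computational space",
         call. = FALSE)
  if (!all(is.finite(Mod(values))))
    stop("field amplitude must be finite everywhere", call. = FALSE)
  storage.mode(values) <- "complex"
  structure(list(values = values, grid = grid, plane = plane),
            class = "qpi_field")
}

#' @export
print.qpi_field <- function(x, ...) {
  cat(sprintf("<qpi_field> plane '%s', %d x %d samples, total power %.4g\n",
              x$plane, nrow(x$values), ncol(x$values), sum(Mod(x$values)^2)))
  invisible(x)
}

#' Illumination from a pinhole point source
#'
#' The diverging wave from a pinhole a distance `d1` upstream of the sample
#' plane, with unit amplitude.  By default the exact spherical phase
#' `exp(j*2*pi*R(d1)/lambda)` is used; `kind = "quadratic"` selects the
#' paraxial Fresnel approximation and `kind = "plane"` (or `d1 = Inf`) a
#' plane wave, the far-source limit.
#'
#' @param grid A `qpi_grid`.
#' @param d1 Source-to-sample distance in metres (> 0, may be `Inf`).
#' @param kind One of `"spherical"`, `"quadratic"`, `"plane"`.
#' @return A `qpi_field` at the sample plane with unit modulus everywhere.
#' @export
point_source_illumination <- function(grid, d1,
                                      kind = c("spherical", "quadratic", "plane")) {
  stopifnot(inherits(grid, "qpi_grid"))
  kind <- match.arg(kind)
  if (!is.numeric(d1) || length(d1) != 1L || is.na(d1) || d1 <= 0)
    stop("source distance d1 must be positive", call. = FALSE)
  if (is.infinite(d1)) kind <- "plane"
  values <- switch(kind,
    plane     = matrix(1 + 0i, grid_dim(grid)[1], grid_dim(grid)[2]),
    spherical = exp(1i * 2 * pi * sqrt(grid$X^2 + grid$Y^2 + d1^2) /
                      grid$wavelength),
    quadratic = exp(1i * pi * (grid$X^2 + grid$Y^2) / (grid$wavelength * d1))
  )
  complex_field(values, grid, plane = "sample")
}

#' Modulate a field by a pure phase object
#'
#' A transparent sample of thickness `t(x, y)` and refractive index `n`
#' delays the wavefront by `phi = 2*pi*t*(n - 1)/lambda`; the transmitted
#' field is the incident field times `exp(-j*phi)`.  The modulus of the
#' field is unchanged (no absorption).
#'
#' @param field A `qpi_field` at the sample plane.
#' @param phase A [phase_map()], or a plain matrix of phase in radians,
#'   either sensor-sized (`n1 x n2`, embedded centrally with zero phase
#'   outside) or full computational-space sized.
#' @return The modulated `qpi_field`.
#' @export
apply_phase_object <- function(field, phase) {
  stopifnot(inherits(field, "qpi_field"))
  grid <- field$grid
  pm <- phase_values(phase)
  if (all(dim(pm) == c(grid$n1, grid$n2))) {
    pm <- embed_central(pm, grid)
  } else if (!all(dim(pm) == grid_dim(grid))) {
    stop("phase map matches neither the sensor nor the computational space",
         call. = FALSE)
  }
  complex_field(field$values * exp(-1i * pm), grid, plane = "sample")
}

# accept a qpi_phase or a bare matrix
phase_values <- function(phase) {
  if (inherits(phase, "qpi_phase")) phase$values
  else if (is.matrix(phase) && is.numeric(phase)) phase
  else stop("expected a phase_map or a numeric matrix of radians", call. = FALSE)
}

#' Apply an amplitude (transmission) mask to a field
#'
#' Used for binary amplitude objects and finite illumination footprints:
#' the field is multiplied elementwise by a real transmission in `[0, 1]`.
#' Sensor-sized masks are embedded centrally with transmission `fill`
#' outside the central block.
#'
#' @param field A `qpi_field`.
#' @param mask Real matrix in `[0, 1]`, sensor-sized or full-sized.
#' @param fill Transmission outside the central block for sensor-sized masks.
#' @return The masked `qpi_field`.
#' @export
apply_amplitude_mask <- function(field, mask, fill = 0) {
  stopifnot(inherits(field, "qpi_field"))
  grid <- field$grid
  if (all(dim(mask) == c(grid$n1, grid$n2))) mask <- embed_central(mask, grid, fill = fill)
  if (!all(dim(mask) == grid_dim(grid)))
    stop("mask matches neither the sensor nor the computational space", call. = FALSE)
  if (min(mask) < 0 || max(mask) > 1)
    stop("transmission mask must lie in [0, 1]", call. = FALSE)
  complex_field(field$values * mask, grid, plane = field$plane)
}
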