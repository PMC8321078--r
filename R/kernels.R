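#' Spherical (non-paraxial) free-space propagation kernel
#'
#' Samples the exact spherical phase factor `exp(j*2*pi*R(d)/lambda)` with
#' `R(d) = sqrt(x^2 + y^2 + d^2)` on the computational grid.  A negative
#' distance gives the backward propagator, the elementwise complex conjugate
#' of the forward one.  The kernel has unit modulus at every sample.
#'
#' @param grid A `qpi_grid`.
#' @param d Signed propagation distance in metres; must be non-zero.
#' @return An object of class `qpi_kernel` with fields `values` (complex
#'   matrix), `distance` and `kind = "spherical"`.
#' @examples
#' g <- make_grid(16, 16, 2e-6, 530e-9)
#' k <- spherical_kernel(g, 0.05)
#' all.equal(Mod(k$values), matrix(1, 32, 32))
#' @export
spherical_kernel <- function(grid, d) {
  stopifnot(inherits(grid, "qpi_grid"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d == 0)
    stop("propagation distance must be a non-zero finite number", call. = FALSE)
  R <- sqrt(grid$X^2 + grid$Y^2 + d^2)
  values <- exp(1i * sign(d) * 2 * pi * R / grid$wavelength)
  structure(list(values = values, distance = d, kind = "spherical", grid = grid),
            class = "qpi_kernel")
}

#' Quadratic (Fresnel) phase kernel
#'
#' Samples the paraxial quadratic phase factor `exp(j*pi*b*R^2/lambda)` with
#' `R^2 = x^2 + y^2` and curvature `b = 1/d`.  `b = 0` gives the all-ones
#' field (no propagation); a sign change conjugates the kernel.
#'
#' @param grid A `qpi_grid`.
#' @param b Curvature in inverse metres (finite).
#' @return A `qpi_kernel` of kind `"quadratic"`.
#' @export
quadratic_phase <- function(grid, b) {
  stopifnot(inherits(grid, "qpi_grid"))
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("curvature b must be a finite number", call. = FALSE)
  values <- exp(1i * pi * b * (grid$X^2 + grid$Y^2) / grid$wavelength)
  structure(list(values = values,
                 distance = if (b != 0) 1 / b else Inf,
                 kind = "quadratic", grid = grid),
            class = "qpi_kernel")
}

#' @export
print.qpi_kernel <- function(x, ...) {
  cat(sprintf("<qpi_kernel> %s, d = %.4g m, %d x %d samples\n",
              x$kind, x$distance, nrow(x$values), ncol(x$values)))
  invisible(x)
}
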