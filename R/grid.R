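#' Define the computational grid
#'
#' The simulation works on a computational space twice the sensor size in
#' each dimension (`2*n1 x 2*n2` samples) so that the recorded intensity can
#' be zero-padded before FFT-based convolution.  Coordinates are centred on
#' the origin sample: the integer index along each axis runs from `-N` to
#' `N - 1` and physical coordinates are index times the pixel pitch.
#'
#' @param n1 Sensor height in pixels (even, >= 8).
#' @param n2 Sensor width in pixels (even, >= 8).
#' @param pixel Pixel pitch in metres.
#' @param wavelength Illumination wavelength in metres.
#'
#' @return An object of class `qpi_grid` with fields `n1`, `n2`, `pixel`,
#'   `wavelength`, integer index vectors `x` (rows) and `y` (columns), and
#'   coordinate matrices `X`, `Y` (metres) over the `2*n1 x 2*n2` space.
#'
#' @examples
#' g <- make_grid(64, 64, 4.65e-6, 530e-9)
#' dim(g$X)              # 128 128
#' g$X[g$n1 + 1, 1]      # 0 at the origin row
#' @export
make_grid <- function(n1, n2, pixel, wavelength) {
  stopifnot(is.numeric(n1), is.numeric(n2), length(n1) == 1L, length(n2) == 1L)
  if (n1 < 8 || n2 < 8 || n1 %% 2 != 0 || n2 %% 2 != 0)
    stop("sensor dimensions must be even and at least 8 pixels", call. = FALSE)
  if (!is.numeric(pixel) || pixel <= 0)
    stop("pixel pitch must be positive", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  x <- seq.int(-n1, n1 - 1L)
  y <- seq.int(-n2, n2 - 1L)
  X <- matrix(x * pixel, nrow = 2L * n1, ncol = 2L * n2)
  Y <- matrix(y * pixel, nrow = 2L * n1, ncol = 2L * n2, byrow = TRUE)
  structure(
    list(n1 = n1, n2 = n2, pixel = pixel, wavelength = wavelength,
         x = x, y = y, X = X, Y = Y),
    class = "qpi_grid"
  )
}

#' @export
print.qpi_grid <- function(x, ...) {
  cat(sprintf(
    "<qpi_grid> sensor %d x %d px, computational space %d x %d, pitch %.3g um, lambda %.4g nm\n",
    x$n1, x$n2, 2L * x$n1, 2L * x$n2, x$pixel * 1e6, x$wavelength * 1e9))
  invisible(x)
}

grid_dim <- function(grid) c(2L * grid$n1, 2L * grid$n2)

#' Index range of the central sensor-sized block
#'
#' The recorded intensity occupies the central `n1 x n2` block of the
#' computational space.  These helpers return the row/column indices of
#' that block and embed/crop matrices accordingly.
#'
#' @param grid A `qpi_grid`.
#' @return Integer index vectors.
#' @keywords internal
central_rows <- function(grid) (grid$n1 %/% 2L + 1L):(3L * grid$n1 %/% 2L)

#' @rdname central_rows
#' @keywords internal
central_cols <- function(grid) (grid$n2 %/% 2L + 1L):(3L * grid$n2 %/% 2L)

#' Embed a sensor-sized matrix into the computational space
#'
#' @param m An `n1 x n2` matrix.
#' @param grid A `qpi_grid`.
#' @param fill Value used outside the central block.
#' @return A `2*n1 x 2*n2` matrix.
#' @export
embed_central <- function(m, grid, fill = 0) {
  if (!all(dim(m) == c(grid$n1, grid$n2)))
    stop("matrix does not match the sensor dimensions of the grid", call. = FALSE)
  out <- matrix(fill, 2L * grid$n1, 2L * grid$n2)
  out[central_rows(grid), central_cols(grid)] <- m
  out
}

#' Crop the central sensor-sized block out of the computational space
#'
#' @param m A `2*n1 x 2*n2` matrix.
#' @param grid A `qpi_grid`.
#' @return An `n1 x n2` matrix.
#' @export
crop_central <- function(m, grid) {
  if (!all(dim(m) == grid_dim(grid)))
    stop("matrix does not match the computational space of the grid", call. = FALSE)
  m[central_rows(grid), central_cols(grid)]
}

# -- FFT helpers ------------------------------------------------------------
# Fields and kernels are stored with the origin at the grid centre
# (index n + 1 along an axis of length 2n); the DFT assumes the origin at
# [1, 1], so kernels are rolled before transforming.  All computational-space
# dimensions are even, making fftshift and ifftshift identical.

circshift2 <- function(m, s) {
  d <- dim(m)
  i <- ((seq_len(d[1]) - 1L - s[1]) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L - s[2]) %% d[2]) + 1L
  m[i, j, drop = FALSE]
}

fftshift2 <- function(m) circshift2(m, dim(m) %/% 2L)

ifftshift2 <- function(m) circshift2(m, -(dim(m) %/% 2L))

fft2 <- function(m) stats::fft(m)

ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)
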