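#' Construct a phase map
#'
#' A 2D real array of phase in radians, optionally carrying the material
#' context (refractive index, wavelength) that permits conversion to a
#' physical thickness, and an optional support mask marking the object
#' region (used by step-height and ramp evaluation helpers).
#'
#' @param values Real matrix of phase in radians, finite everywhere.
#' @param pixel Pixel pitch in metres (optional).
#' @param wavelength Wavelength in metres (optional).
#' @param n Refractive index (optional).
#' @param wrapped Logical; `TRUE` declares values to lie in `[0, 2*pi)`.
#' @param support Optional logical matrix marking the object region.
#' @return An object of class `qpi_phase`.
#' @export
phase_map <- function(values, pixel = NA_real_, wavelength = NA_real_,
                      n = NA_real_, wrapped = FALSE, support = NULL) {
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values)))
    stop("phase values must be a finite numeric matrix", call. = FALSE)
  if (wrapped && (min(values) < 0 || max(values) >= 2 * pi))
    stop("a wrapped phase map must lie in [0, 2*pi)", call. = FALSE)
  if (!is.null(support) && !all(dim(support) == dim(values)))
    stop("support mask must match the phase map dimensions", call. = FALSE)
  structure(list(values = values, pixel = pixel, wavelength = wavelength,
                 n = n, wrapped = wrapped, support = support),
            class = "qpi_phase")
}

#' @export
print.qpi_phase <- function(x, ...) {
  cat(sprintf("<qpi_phase> %d x %d px, range [%.4g, %.4g] rad%s\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              if (isTRUE(x$wrapped)) ", wrapped" else ""))
  invisible(x)
}

#' Wrap phase into [0, 2*pi)
#'
#' @param x Numeric vector, matrix or `qpi_phase`.
#' @return Same shape, values reduced modulo `2*pi`.
#' @export
wrap_phase <- function(x) {
  if (inherits(x, "qpi_phase")) {
    x$values <- x$values %% (2 * pi)
    x$wrapped <- TRUE
    return(x)
  }
  x %% (2 * pi)
}

#' Binary phase object from a mask and a physical step
#'
#' A binary relief of thickness `t` in a material of refractive index `n`
#' imparts a phase step `2*pi*t*(n - 1)/lambda` (in air) on the masked
#' pixels and zero elsewhere.  For example t = 530 nm of n = 1.5 material at
#' 530 nm wavelength gives a step of exactly pi radians.
#'
#' @param mask Binary matrix (logical or 0/1).
#' @param t Step thickness in metres (>= 0).
#' @param n Refractive index of the relief material (> 1).
#' @param wavelength Wavelength in metres.
#' @return A `qpi_phase` with the mask as its support.
#' @export
binary_phase_from_mask <- function(mask, t, n, wavelength) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- if (is.logical(mask)) mask + 0 else mask
  if (!all(m %in% c(0, 1)))
    stop("mask must be binary (values 0/1 or logical)", call. = FALSE)
  if (!is.numeric(t) || t < 0) stop("thickness t must be >= 0", call. = FALSE)
  step <- phase_from_thickness(t, n, wavelength)
  phase_map(step * m, wavelength = wavelength, n = n, support = m > 0)
}

#' Linear phase ramp embedded in a zero-phase surround
#'
#' A linear gradient from 0 to `max_phase` running left to right across a
#' centred square region (half the side length by default), with zero phase
#' and unit amplitude outside.  With `wrapped = TRUE` the values are reduced
#' modulo 2*pi, giving `max_phase / (2*pi)` fringe periods across the region.
#'
#' @param size Side length in pixels of the full map.
#' @param max_phase Maximum phase in radians (>= 0).
#' @param wrapped Return the modulo-2*pi representation.
#' @param region_frac Side of the ramp region as a fraction of `size`.
#' @return A `qpi_phase`; its `support` marks the ramp region.
#' @export
linear_ramp_phase <- function(size, max_phase, wrapped = FALSE,
                              region_frac = 0.5) {
  stopifnot(size >= 4, is.numeric(max_phase))
  if (max_phase < 0) stop("max_phase must be >= 0", call. = FALSE)
  values <- matrix(0, size, size)
  w <- max(2L, round(size * region_frac))
  r0 <- (size - w) %/% 2L
  rows <- (r0 + 1L):(r0 + w)
  ramp <- max_phase * (seq_len(w) - 1L) / (w - 1L)
  values[rows, rows] <- matrix(ramp, w, w, byrow = TRUE)
  support <- matrix(FALSE, size, size)
  support[rows, rows] <- TRUE
  if (wrapped) {
    values <- values %% (2 * pi)
    # the endpoint of an exact multiple of 2*pi wraps to 0
  }
  phase_map(values, wrapped = wrapped, support = support)
}

#' Synthesize a phase-only scattering layer by a Fourier-domain GSA
#'
#' Designs a diffuser: a unit-amplitude layer whose far field concentrates
#' its power in a centred disc occupying a fraction `sigma` of the Fourier
#' samples (the scattering ratio).  The layer is found by alternating
#' projections: enforce the target amplitude (uniform in the disc, zero
#' outside) in the Fourier plane and the phase-only constraint in the layer
#' plane, starting from seeded random phase.  Deterministic given `seed`.
#'
#' @param size Side length in pixels.
#' @param sigma Scattering ratio in `[0, 1]` — fraction of Fourier-plane
#'   samples inside the target support.
#' @param iterations Number of alternating-projection iterations (>= 1).
#' @param seed Integer seed for the initial random phase.
#' @return A wrapped `qpi_phase`; attribute `"power_history"` records the
#'   fraction of far-field power inside the target support per iteration.
#' @export
scattering_layer <- function(size, sigma, iterations = 50L, seed = 1L) {
  stopifnot(size > 0, iterations >= 1)
  if (!is.numeric(sigma) || sigma < 0 || sigma > 1)
    stop("scattering ratio sigma must lie in [0, 1]", call. = FALSE)
  if (sigma == 0) {
    out <- phase_map(matrix(0, size, size), wrapped = TRUE)
    attr(out, "power_history") <- rep(1, iterations)
    return(out)
  }
  target <- scatter_support(size, sigma)
  phi <- with_seed(seed, matrix(stats::runif(size^2, 0, 2 * pi), size, size))
  history <- numeric(iterations)
  for (p in seq_len(iterations)) {
    G <- fftshift2(fft2(exp(1i * phi)))
    history[p] <- sum(Mod(G[target])^2) / sum(Mod(G)^2)
    G2 <- matrix(0 + 0i, size, size)
    G2[target] <- exp(1i * Arg(G[target]))
    g <- ifft2(ifftshift2(G2))
    phi <- Arg(g)
  }
  out <- phase_map(phi %% (2 * pi), wrapped = TRUE)
  attr(out, "power_history") <- history
  out
}

# centred disc covering fraction sigma of the Fourier samples
scatter_support <- function(size, sigma) {
  u <- seq.int(-(size %/% 2L), size - size %/% 2L - 1L)
  U <- matrix(u, size, size)
  V <- matrix(u, size, size, byrow = TRUE)
  r <- size * sqrt(sigma / pi)
  U^2 + V^2 <= r^2
}

#' Fraction of far-field power inside the scattering target support
#'
#' Independent figure of merit for a designed scattering layer: the
#' unit-amplitude layer `exp(j*phi)` is Fourier transformed and the fraction
#' of spectral power falling inside the centred target disc of ratio
#' `sigma` is returned.
#'
#' @param phase A `qpi_phase` or phase matrix (radians).
#' @param sigma Scattering ratio defining the target support.
#' @return A number in `[0, 1]`.
#' @export
farfield_power_ratio <- function(phase, sigma) {
  phi <- phase_values(phase)
  target <- scatter_support(nrow(phi), sigma)
  G <- fftshift2(fft2(exp(1i * phi)))
  sum(Mod(G[target])^2) / sum(Mod(G)^2)
}

#' Two-plane thick phase object
#'
#' A thick object composed of two thin phase objects separated axially by
#' `delta_d`: illumination travels from the pinhole (distance `d1` to the
#' first plane), through plane A, across `delta_d` to plane B, and then
#' `d2` to the sensor.  Plane B therefore sits at distance `d2` from the
#' sensor and plane A at `d2 + delta_d`.
#'
#' @param phase_a First (upstream) thin phase object.
#' @param phase_b Second thin phase object.
#' @param d1 Source-to-first-plane distance in metres (`Inf` for plane wave).
#' @param delta_d Plane spacing in metres (> 0).
#' @param d2 Second-plane-to-sensor distance in metres (> 0).
#' @return An object of class `qpi_thick` usable with
#'   [simulate_intensity()]; `$sensor_distances` gives the per-plane
#'   distances to the sensor (`c(d2 + delta_d, d2)`).
#' @export
two_plane_object <- function(phase_a, phase_b, d1, delta_d, d2) {
  if (!is.numeric(delta_d) || delta_d <= 0)
    stop("plane spacing delta_d must be positive", call. = FALSE)
  if (!is.numeric(d2) || d2 <= 0) stop("d2 must be positive", call. = FALSE)
  pa <- if (inherits(phase_a, "qpi_phase")) phase_a else phase_map(phase_a)
  pb <- if (inherits(phase_b, "qpi_phase")) phase_b else phase_map(phase_b)
  structure(
    list(planes = list(list(phase = pa, z = 0), list(phase = pb, z = delta_d)),
         d1 = d1, delta_d = delta_d, d2 = d2,
         sensor_distances = c(d2 + delta_d, d2)),
    class = "qpi_thick")
}

#' Procedurally drawn binary test masks
#'
#' Deterministic stand-ins for logo-style binary test objects: a disc, an
#' annulus, a multi-pointed star and a blobby animal-like silhouette.  All
#' masks contain only 0/1 values.
#'
#' @param name One of `"disc"`, `"annulus"`, `"star"`, `"silhouette"`.
#' @param size Side length in pixels.
#' @return A `size x size` binary (0/1) matrix.
#' @export
builtin_phantom <- function(name, size) {
  stopifnot(size >= 16)
  u <- (seq_len(size) - (size / 2 + 0.5)) / size   # centred, roughly [-0.5, 0.5)
  X <- matrix(u, size, size)
  Y <- matrix(u, size, size, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  m <- switch(name,
    disc = r <= 0.25,
    annulus = r <= 0.28 & r >= 0.18,
    star = r <= (0.10 + 0.18 * pmax(cos(5 * th), 0)),
    silhouette = {
      body <- ((X + 0.05)^2 / 0.20^2 + Y^2 / 0.12^2) <= 1
      head <- ((X - 0.20)^2 + (Y - 0.10)^2) <= 0.08^2
      ear  <- ((X - 0.26)^2 / 0.03^2 + (Y - 0.17)^2 / 0.06^2) <= 1
      tail <- ((X + 0.26)^2 / 0.10^2 + (Y + 0.08)^2 / 0.035^2) <= 1
      leg1 <- (abs(X + 0.10) <= 0.025) & (Y <= 0) & (Y >= -0.22)
      leg2 <- (abs(X - 0.08) <= 0.025) & (Y <= 0) & (Y >= -0.22)
      body | head | ear | tail | leg1 | leg2
    },
    stop("unknown phantom name '", name, "'", call. = FALSE)
  )
  m + 0
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
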