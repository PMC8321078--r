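# Shared fixtures.  Simulated geometries follow the study conditions of the
# package: wavelength 530 nm, sample-sensor distance 20 cm, pixel pitch from
# the kernel-sampling rule (matched_pixel_pitch), a pinhole-cone footprint
# of 0.3-0.4 of the sensor, and thin line-art binary objects.

qpi_lambda <- 530e-9

# thin ring mask (line-art style object), radii as fractions of n
ring_mask <- function(n, r_in = 0.10, r_out = 0.14) {
  u <- seq_len(n) - (n / 2 + 0.5)
  R <- sqrt(outer(u^2, u^2, `+`))
  (R <= r_out * n & R >= r_in * n) + 0
}

# standard retrieval fixture: grid, footprint and a ring phase object
ring_fixture <- function(n = 128L, d2 = 0.2, step = pi / 2, ap_frac = 0.30) {
  px <- matched_pixel_pitch(n, d2, qpi_lambda)
  grid <- make_grid(n, n, px, qpi_lambda)
  aperture <- disc_aperture(n, n, ap_frac)
  mask <- ring_mask(n)
  reference <- phase_map(step * mask, pixel = px, wavelength = qpi_lambda,
                         support = mask > 0)
  intensity <- simulate_intensity(reference, grid, d2 = d2, d1 = Inf,
                                  amplitude = aperture)
  list(grid = grid, aperture = aperture, mask = mask,
       reference = reference, intensity = intensity, d2 = d2, step = step)
}

# direct double-sum circular convolution with a centre-origin kernel,
# matching the layout used by propagate(); O(n^4), for tiny grids only
brute_convolve <- function(f, k) {
  d <- dim(f)
  k0 <- k[c((d[1] %/% 2 + 1):d[1], 1:(d[1] %/% 2)),
          c((d[2] %/% 2 + 1):d[2], 1:(d[2] %/% 2))]  # roll origin to [1,1]
  out <- matrix(0 + 0i, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      ii <- ((i - seq_len(d[1])) %% d[1]) + 1L
      jj <- ((j - seq_len(d[2])) %% d[2]) + 1L
      out[i, j] <- sum(f * k0[ii, jj])
    }
  }
  out
}

rel_rms <- function(a, b) sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
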