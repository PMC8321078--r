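# lensqpi

Lensless incoherent quantitative phase imaging (QPI) in R: a
scalar-diffraction simulator of the pinhole → phase sample → bare sensor
geometry, and an iterative Gerchberg–Saxton phase retrieval algorithm that
recovers 2D and multi-plane (3D) quantitative phase maps from a single
recorded intensity image.

QPI measures optical path delay — the phase $\Phi_s = 2\pi t(n-1)/\lambda$
imparted by a transparent sample of thickness $t$ and refractive index $n$
— which ordinary intensity imaging cannot see. The lensless variant needs
only an LED, a pinhole and a camera sensor: light diverging from the
pinhole (distance $d_1$ to the sample) is phase-modulated by the sample and
its diffraction pattern is recorded a distance $d_2$ downstream,

$$I = \bigl|\,Q(1/d_1)\,e^{-j\Phi_s} \otimes S[R(d_2)]\,\bigr|^2,$$

with $S[R(d)] = \exp[j2\pi\sqrt{x^2+y^2+d^2}/\lambda]$ the spherical
free-space kernel. The phase is recovered by alternating amplitude
constraints between the sensor plane (measured $\sqrt{I}$, zero-padded)
and the sample plane (assumed amplitude), carrying the phase through
back-and-forth propagation until the sensor-amplitude mismatch stops
improving. Multi-plane objects are refocused by re-running the retrieval
over a scan of reconstruction distances. The package is aimed at
microscopy/biophotonics researchers prototyping lensless QPI and at
teaching computational imaging.

## What's in the box

* `grid/optics` — centred computational grids (`make_grid()`), spherical
  and Fresnel kernels, FFT convolution propagation (`propagate()`), the
  full forward model (`simulate_intensity()`, `sensor_intensity()`).
* `phantoms` — procedurally drawn binary masks (`builtin_phantom()`),
  physical phase steps (`binary_phase_from_mask()`), wrapped ramps
  (`linear_ramp_phase()`), Fourier-designed scattering layers
  (`scattering_layer()`), two-plane thick objects (`two_plane_object()`).
* `retrieval` — `gsa_retrieve()`, `refocus_scan()`,
  `effective_distance()` (the $d_2' = (1/d_2 - 1/d_1)^{-1}$ correction for
  diverging illumination), `retrieval_config()`.
* `analysis` — phase-only-filter correlation (`phase_correlation()`),
  phase↔thickness conversion, magnification/NA, 2D unwrapping
  (`unwrap_phase()`), step and focus metrics.
* `io/pipeline` — PNG/TIFF image I/O with YAML sidecars, unit-suffixed
  configs, the `run_pipeline()` simulate→retrieve→report pipeline, and a
  CLI (`inst/cli/qpi.R`) with `phantom`, `simulate`, `retrieve` and
  `refocus` subcommands.

`tidy()`, `glance()` and `autoplot()` methods expose convergence histories
and refocus summaries as tibbles and ggplots.

## Worked example

A π/2 phase ring (the kind of line-art relief an electron-beam-written
resist sample provides), imaged at $d_2 = 20$ cm with 530 nm light under a
plane-wave-like illumination footprint, then retrieved from its intensity
alone:

```r
library(lensqpi)

N  <- 256
px <- matched_pixel_pitch(N, 0.2, 530e-9)   # 14.4 um: kernel-sampling rule
g  <- make_grid(N, N, px, 530e-9)
ap <- disc_aperture(N, N, 0.3)              # pinhole-cone footprint

u    <- seq_len(N) - (N/2 + 0.5)
R    <- sqrt(outer(u^2, u^2, `+`))
mask <- (R <= 0.14*N & R >= 0.10*N) + 0     # thin ring
obj  <- phase_map(pi/2 * mask, support = mask > 0)

I   <- simulate_intensity(obj, g, d2 = 0.2, d1 = Inf, amplitude = ap)
res <- gsa_retrieve(I, retrieval_config(0.2, max_iterations = 50,
                                        stop_tolerance = 0),
                    g, reference_phase = obj, sample_amplitude = ap)
res
#> <qpi_retrieval> d = 0.2 m, 50 iteration(s), final sensor error 0.0809
#>   final normalized correlation 0.4239

step_height(res$phase$values, support = mask > 0,
            background = ap > 0 & mask == 0, circular = TRUE)
#> [1] 1.509228
```

The retrieved step, 1.509 rad against a true π/2 = 1.571 rad, is a 3.9 %
error after 50 iterations; `thickness_from_phase(1.509, 1.5, 530e-9)`
converts it back to a 255 nm relief estimate (true: 265 nm). The
correlation history (`tidy(res)`, `autoplot(res)`) shows the
rise-and-stabilize signature of the converging iteration, and the
sensor-amplitude error is non-increasing throughout.

The same machinery handles the analytic relations directly:

```r
effective_distance(2.0, 0.2)                  # 0.2222 m corrected distance
phase_from_thickness(800e-9, 1.5, 530e-9)/pi  # 1.509 (about 1.5 pi)
thickness_from_phase(pi, 1.5, 530e-9)         # 5.3e-07 m (530 nm)
```

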