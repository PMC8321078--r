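---
title: "Lensless quantitative phase imaging by iterative phase retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lensless quantitative phase imaging by iterative phase retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensqpi)
```

## The imaging model

A light-emitting diode behind a pinhole illuminates a transparent sample a
distance $d_1$ downstream; a bare image sensor records the diffracted
intensity a further distance $d_2$ away.  A sample of thickness $t(x,y)$ and
refractive index $n$ (in air) delays the wavefront by

$$\Phi_s(x,y) = \frac{2\pi\, t(x,y)\,(n-1)}{\lambda},$$

so the field just after the sample is $Q(1/d_1)\,e^{-j\Phi_s}$, where
$Q(b) = \exp[j\pi b (x^2+y^2)/\lambda]$ is the paraxial quadratic phase of
the diverging illumination.  Free-space propagation to the sensor is a 2D
convolution with a propagation kernel; at the short distances used here the
exact spherical factor
$S[R(d)] = \exp[j 2\pi R(d)/\lambda]$, $R(d) = (x^2+y^2+d^2)^{1/2}$,
is used rather than its paraxial approximation.  The sensor records

$$I(x,y) \;=\; \bigl|\,Q(1/d_1)\,e^{-j\Phi_s} \otimes S[R(d_2)]\,\bigr|^2 .$$

The geometry also fixes the projection magnification $M = 1 + d_2/d_1$ and
the numerical aperture $\mathrm{NA} = D/2(d_1+d_2)$ for sensor diameter $D$
(`magnification()`, `numerical_aperture()`, `imaging_geometry()`).

## Discretization and sampling

All computations run on a $2N_1 \times 2N_2$ computational space sampled at
the sensor pitch $\Delta$, with the recorded $N_1 \times N_2$ intensity
zero-padded into the central block (`make_grid()`,
`prepare_sensor_amplitude()`).  Kernels are sampled in real space with the
origin at the grid centre and the convolution is computed as three FFTs,
$f \otimes S = \mathcal{F}^{-1}[\mathcal{F}(f)\,\mathcal{F}(S)]$, with the
output rescaled to conserve total power (`propagate()`).

The sampled chirp kernel imposes a real sampling constraint: its local
spatial frequency at the edge of the grid, $N\Delta/(\lambda d)$, must reach
the object's band without exceeding the Nyquist limit $1/(2\Delta)$.
Equality gives the matched pitch

$$N\,\Delta^2 = \tfrac{1}{2}\lambda d,$$

exposed as `matched_pixel_pitch()`.  Coarser pitches band-limit the
propagation (fine object detail is silently lost); finer pitches alias the
kernel.  Every simulated study in this package and its tests picks its
pitch with this rule; for reference, a 1024-pixel sensor with 4.65 µm
pixels is matched near $d = 5$ cm at 530 nm — essentially the experimental
geometry this class of instrument uses.

## Phase retrieval

`gsa_retrieve()` implements the alternating amplitude-constraint loop.  The
measured amplitude $A_1 = \sqrt{I/\max I}$ (zero outside the sensor block)
is paired with a uniform initial phase; each iteration back-propagates with
$S[-R(d)]$, replaces the sample-plane amplitude with the assumed $A_2$
while carrying the phase, forward-propagates with $S[R(d)]$, and restores
the measured amplitude.  Per iteration the scale-optimal relative RMS
mismatch between the propagated and measured sensor amplitudes is recorded,
and, when a reference map is available, the normalized phase-only-filter
cross-correlation (`phase_correlation()`) between the current
reconstruction and the reference.  Iteration stops at `max_iterations` or
when the convergence score changes by less than `stop_tolerance`
(default $10^{-3}$) over a `stop_window` of 5 iterations.

Three choices deserve comment:

* **Sample-plane amplitude.**  The textbook constraint is the uniform
  $A_2 = 1$, and that is the default.  In the physical instrument the
  pinhole cone illuminates a finite footprint, and when that footprint is
  known, passing it as `sample_amplitude` adds a support constraint that
  markedly accelerates and stabilizes convergence — without it, the
  zero-padding of $A_1$ asserts darkness outside the sensor that a
  full-field simulation contradicts, and the iteration stalls at a high
  error floor.  Simulated studies here always use an explicit footprint
  (`disc_aperture()`), typically 0.3–0.45 of the sensor, which also keeps
  ≥ 98 % of the diffracted light on the sensor.
* **Sign.**  The sample modulates by $e^{-j\Phi_s}$, so the carried phase
  estimates $-\Phi_s$; the returned map is negated to estimate the object
  phase directly.  For a binary $\pi$ object the sign is unobservable
  modulo $2\pi$.
* **Scoring mask.**  Outside the illuminated footprint the retrieved phase
  is the argument of near-zero amplitudes — pure noise.  With a footprint,
  the correlation score is computed after anchoring the background median
  and masking to the footprint; otherwise the raw maps are correlated.

With a diverging source the best reconstruction distance is not $d_2$ but
the corrected $d_2' = (1/d_2 - 1/d_1)^{-1}$ (`effective_distance()`);
retrieval at $d_2'$ measurably beats retrieval at $d_2$ on spherical-
illumination fixtures (a property test covers this).

## Phantoms: what the generator emulates

`builtin_phantom()` draws deterministic binary masks (disc, annulus, star,
silhouette) standing in for the logo-style lithographic test objects this
method is normally demonstrated on.  `binary_phase_from_mask()` converts a
mask and a physical step ($t$, $n$) into radians — 530 nm of $n = 1.5$
material at 530 nm is exactly $\pi$.  `linear_ramp_phase()` builds the
greyscale test object: a linear ramp to `max_phase` (optionally wrapped
modulo $2\pi$) in a zero-phase surround.  `scattering_layer()` synthesizes
a phase-only diffuser by a Fourier-domain alternating projection: the
scattering ratio $\sigma$ is *defined* here as the fraction of
Fourier-plane samples inside a centred disc support with uniform target
amplitude — the far-field power fraction inside that support
(`farfield_power_ratio()`) exceeds 0.8 after 50 iterations and its history
is non-decreasing early on, the classical error-reduction signature.
`two_plane_object()` composes two thin objects separated by `delta_d` into
a thick object for 3D studies.

These fixtures emulate *noiseless, monochromatic, pixel-limited* recordings
of binary or smooth phase objects under a finite illumination footprint.
They do not emulate: shot or read noise, the 33 nm spectral width of a real
LED (treated as monochromatic at the centre wavelength), partial spatial
coherence of a 100 µm pinhole, sensor nonlinearity, or substrate
reflections.  Passing tests therefore certify the computational pipeline,
not robustness to those physical effects.

## What converges, and what does not

Extensive fixture studies shaped the defaults, and the honest summary is:

* **Line-art objects converge; dense strong objects creep.**  A thin-ring
  $\pi/2$ object reaches ~4 % step error in 50 iterations; a filled disc of
  the same step needs ~150.  Step heights are estimated robustly as the
  median difference between object and background regions
  (`step_height()`, circularly wrapped).
* **Binary $\pi$ steps stagnate.**  A 0/$\pi$ object makes the transmitted
  field real-valued; its inline intensity is nearly conjugation-invariant
  and plain error-reduction iterations stay near a symmetric fixed point
  (~30 % step error after 50 iterations, creeping thereafter).  Random
  restarts do not rescue it.  This mirrors the experimental literature,
  where measured $\pi$-class steps are reported qualitatively and often
  under-estimated.
* **Smooth tilts are the hardest.**  A wrapped 8$\pi$ ramp occupying 0.2 of
  the sensor (≈ 13 px per fringe) is recovered within 10 % of its maximum
  after 20 iterations and 2D unwrapping; wider/shallower blazes put the
  grating frequency where the retrieval systematically loses the outermost
  fringe.
* **Refocusing a two-plane object is asymmetric.**  Scanning the
  reconstruction distance (`refocus_scan()`) localizes the *near* plane by
  the blind focus score and the *far* plane by the reference correlation,
  but the near-plane reconstruction always carries the upstream plane's
  diffracted background, which no blind metric we tested fully separates.

## Numerical choices

* Focus score: negative mean gradient magnitude of the retrieved phase
  (`focus_metric()`).  For *phase* reconstructions, defocus manifests as
  high-frequency ringing, so roughness falls — not rises — at best focus;
  gradient-variance "sharpness" metrics select garbage distances here.
* Unwrapping (`unwrap_phase()`): 1D unwrapping of the first column as an
  anchor, then each row anchored to it.  Exact for noiseless surfaces whose
  true increments stay below $\pi$ along those paths; congruence (output −
  input ≡ 0 mod 2$\pi$) holds by construction.
* Phase-only filter: the test spectrum is divided by its modulus with a
  $10^{-12}$ floor; the score is normalized by the reference
  autocorrelation so that self-correlation is exactly 1.
* Degenerate inputs: all-zero intensities, all-zero phase maps, non-binary
  masks, colour images and non-physical geometries raise immediate errors;
  non-convergent retrievals return the best-so-far result with
  `converged = FALSE` rather than failing.
* Determinism: the only randomness (random initial phase, diffuser seeds)
  is seeded and restores the RNG state; uniform-start retrievals are
  bit-reproducible, and `run_pipeline()` artifacts are checksum-identical
  across runs.

## Problem sizes

Module tests run at 64–128 px sensors; the full simulated studies (step
recovery, error monotonicity, two-plane refocus, ramp recovery) run at
256 × 256 — the scale at which the convergence behaviour above was
characterized and a comfortable desktop workload (the complete suite runs
in a few minutes).

## A minimal session

```{r example, eval = FALSE}
N  <- 256
px <- matched_pixel_pitch(N, 0.2, 530e-9)
g  <- make_grid(N, N, px, 530e-9)
ap <- disc_aperture(N, N, 0.3)

mask <- builtin_phantom("annulus", N)
obj  <- binary_phase_from_mask(mask, 530e-9 / 2, 1.5, 530e-9)  # pi/2 step

I   <- simulate_intensity(obj, g, d2 = 0.2, d1 = Inf, amplitude = ap)
res <- gsa_retrieve(I, retrieval_config(0.2, max_iterations = 50),
                    g, reference_phase = obj, sample_amplitude = ap)

step_height(res$phase$values, support = mask > 0,
            background = ap > 0 & mask == 0, circular = TRUE)
tidy(res)       # per-iteration error and correlation
autoplot(res)   # convergence plot
```

## Known limitations

Single-frame, single-wavelength error reduction is the paper-and-pencil
baseline of this field: no relaxation (HIO), no multi-height or
multi-wavelength diversity, no pixel super-resolution, no learned priors —
all deliberately out of scope.  The limitations catalogued above (binary
$\pi$ stagnation, tilt fringe loss, near-plane background in thick
objects) are properties of that baseline algorithm, faithfully reproduced,
not of this implementation.
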