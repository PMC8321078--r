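#' Zero-padded sensor amplitude for phase retrieval
#'
#' Normalizes the recorded intensity to unit peak, takes its square root,
#' and embeds it in the central sensor-sized block of an otherwise zero
#' computational-space array.  This is the fixed amplitude constraint at the
#' sensor plane.
#'
#' @param intensity An `n1 x n2` non-negative intensity matrix.
#' @param grid A `qpi_grid` whose sensor dimensions match `intensity`.
#' @return A `qpi_field` at the sensor plane (real-valued amplitude).
#' @export
prepare_sensor_amplitude <- function(intensity, grid) {
  stopifnot(inherits(grid, "qpi_grid"))
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  if (min(intensity) < 0)
    stop("intensity must be non-negative", call. = FALSE)
  peak <- max(intensity)
  if (peak == 0)
    stop("intensity image is identically zero", call. = FALSE)
  a <- sqrt(intensity / peak)
  complex_field(embed_central(a, grid) + 0i, grid, plane = "sensor")
}

#' Retrieval settings
#'
#' @param d Sensor-to-sample propagation distance in metres.  For a
#'   diverging (spherical) illumination use the corrected
#'   [effective_distance()] of the geometry.
#' @param max_iterations Iteration cap (default 100).
#' @param initial_phase `"uniform"` (zero everywhere, the default — it
#'   converges faster) or `"random"` (seeded).
#' @param seed Seed for the random initial phase.
#' @param stop_tolerance Relative change of the convergence score below
#'   which iteration stops (default `1e-3`); set to 0 to always run
#'   `max_iterations`.
#' @param stop_window Number of iterations over which the change is
#'   measured (default 5).
#' @return A list of class `qpi_config`.
#' @export
retrieval_config <- function(d, max_iterations = 100L,
                             initial_phase = c("uniform", "random"),
                             seed = 1L, stop_tolerance = 1e-3,
                             stop_window = 5L) {
  if (!is.numeric(d) || d <= 0 || !is.finite(d))
    stop("propagation distance d must be positive and finite", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (stop_tolerance < 0) stop("stop_tolerance must be >= 0", call. = FALSE)
  structure(list(d = d, max_iterations = as.integer(max_iterations),
                 initial_phase = match.arg(initial_phase), seed = seed,
                 stop_tolerance = stop_tolerance,
                 stop_window = as.integer(stop_window)),
            class = "qpi_config")
}

#' Gerchberg-Saxton phase retrieval from a single intensity image
#'
#' Alternates between the sensor and sample planes: starting from the
#' measured sensor amplitude with a uniform initial phase, the field is
#' back-propagated (convolution with the conjugate spherical kernel
#' `S[-R(d)]`), its amplitude replaced by the assumed sample-plane
#' amplitude while the phase is kept, forward-propagated (`S[R(d)]`), and
#' its amplitude replaced by the measured one.  Each iteration records the
#' sensor-amplitude mismatch and, when a reference phase is supplied, the
#' normalized phase-only-filter correlation of the current reconstruction
#' with it.
#'
#' The default sample-plane amplitude is the uniform unit function.  When
#' the illuminated region is known (the pinhole cone covers a finite
#' footprint), passing it as `sample_amplitude` constrains the sample-plane
#' support and markedly improves convergence; the retrieved phase is then
#' meaningful only inside that footprint, and the correlation score is
#' evaluated over it.
#'
#' Because the sample modulates the field by `exp(-j*phi_s)`, the carried
#' sample-plane phase estimates `-phi_s` (plus a constant); the returned
#' map is negated so that it estimates the object phase directly
#' (`negate = FALSE` returns the raw carried phase).
#'
#' @param amplitude_sensor A `qpi_field` from [prepare_sensor_amplitude()],
#'   or a raw `n1 x n2` intensity matrix (prepared automatically).
#' @param config A [retrieval_config()].
#' @param grid A `qpi_grid`.
#' @param reference_phase Optional `n1 x n2` reference phase map; enables
#'   the correlation history.
#' @param sample_amplitude Optional known amplitude at the sample plane
#'   (`n1 x n2` or full-size matrix in `[0, 1]`); `NULL` means the uniform
#'   unit amplitude.
#' @param score_support Optional logical `n1 x n2` mask over which the
#'   correlation score is evaluated; defaults to the positive region of
#'   `sample_amplitude` when that is given, else the full block.
#' @param negate Return the object-phase estimate (default) instead of the
#'   raw carried sample-plane phase.
#' @return An object of class `qpi_retrieval`: `phase` (a `qpi_phase` over
#'   the central sensor block), `error_history`, `correlation_history`,
#'   `iterations_run`, `converged`.
#' @export
gsa_retrieve <- function(amplitude_sensor, config, grid,
                         reference_phase = NULL, sample_amplitude = NULL,
                         score_support = NULL, negate = TRUE) {
  stopifnot(inherits(config, "qpi_config"), inherits(grid, "qpi_grid"))
  if (is.matrix(amplitude_sensor) && is.numeric(amplitude_sensor) &&
      !is.complex(amplitude_sensor))
    amplitude_sensor <- prepare_sensor_amplitude(amplitude_sensor, grid)
  stopifnot(inherits(amplitude_sensor, "qpi_field"))
  A1 <- Mod(amplitude_sensor$values)
  ref <- if (!is.null(reference_phase)) phase_values(reference_phase)

  A2 <- expand_sample_amplitude(sample_amplitude, grid)
  if (is.null(score_support) && !is.null(sample_amplitude))
    score_support <- crop_central(A2, grid) > 0.5
  if (!is.null(score_support))
    stopifnot(all(dim(score_support) == c(grid$n1, grid$n2)))

  P1 <- switch(config$initial_phase,
    uniform = matrix(0, nrow(A1), ncol(A1)),
    random  = with_seed(config$seed,
                        matrix(stats::runif(length(A1), 0, 2 * pi),
                               nrow(A1), ncol(A1))))
  # precomputed kernel spectra: three FFTs per half-propagation collapse to one
  Kb <- fft2(ifftshift2(spherical_kernel(grid, -config$d)$values))
  Kf <- fft2(ifftshift2(spherical_kernel(grid, config$d)$values))

  C1 <- A1 * exp(1i * P1)
  err <- numeric(config$max_iterations)
  corr <- if (!is.null(ref)) numeric(config$max_iterations)
  P2 <- NULL
  iters <- 0L
  converged <- FALSE
  a1_norm <- sqrt(mean(A1^2))
  for (p in seq_len(config$max_iterations)) {
    C2 <- ifft2(fft2(C1) * Kb)           # to the sample plane
    P2 <- Arg(C2)
    C2 <- A2 * exp(1i * P2)              # sample-plane amplitude constraint
    C1f <- ifft2(fft2(C2) * Kf)          # back to the sensor plane
    P1 <- Arg(C1f)
    amp <- Mod(C1f)
    # amplitude mismatch at the sensor, scale-optimal (intensity scale is gauge)
    s <- sum(amp * A1) / sum(amp^2)
    err[p] <- sqrt(mean((s * amp - A1)^2)) / a1_norm
    if (!is.null(ref)) {
      est <- crop_central(if (negate) -P2 else P2, grid)
      corr[p] <- scored_correlation(ref, est, score_support)
    }
    C1 <- A1 * exp(1i * P1)              # amplitude constraint at the sensor
    iters <- p
    score <- if (!is.null(ref)) corr else err
    w <- config$stop_window
    if (config$stop_tolerance > 0 && p > w) {
      rel <- abs(score[p] - score[p - w]) / max(abs(score[p]), .Machine$double.eps)
      if (rel < config$stop_tolerance) { converged <- TRUE; break }
    }
  }
  phase <- crop_central(if (negate) -P2 else P2, grid)
  structure(
    list(phase = phase_map(phase, pixel = grid$pixel,
                           wavelength = grid$wavelength,
                           support = score_support),
         error_history = err[seq_len(iters)],
         correlation_history = if (!is.null(ref)) corr[seq_len(iters)],
         iterations_run = iters, converged = converged,
         config = config, grid = grid),
    class = "qpi_retrieval")
}

# accept NULL / sensor-sized / full-sized sample amplitude, return full-sized
expand_sample_amplitude <- function(sample_amplitude, grid) {
  if (is.null(sample_amplitude))
    return(matrix(1, 2L * grid$n1, 2L * grid$n2))
  m <- sample_amplitude
  if (is.logical(m)) m <- m + 0
  if (all(dim(m) == c(grid$n1, grid$n2))) m <- embed_central(m, grid)
  if (!all(dim(m) == grid_dim(grid)))
    stop("sample_amplitude matches neither the sensor nor the computational space",
         call. = FALSE)
  if (min(m) < 0 || max(m) > 1)
    stop("sample_amplitude must lie in [0, 1]", call. = FALSE)
  m
}

# correlation of a reconstruction against the reference, optionally masked
# to the illuminated footprint: the estimate is anchored to the reference's
# zero (background) level, wrapped to (-pi, pi], and zeroed outside the mask
scored_correlation <- function(ref, est, support = NULL) {
  if (!is.null(support)) {
    bg <- support & (ref == 0)
    if (!any(bg)) bg <- support
    est <- Arg(exp(1i * (est - stats::median(est[bg])))) * support
  }
  phase_correlation(ref, est)$normalized_score
}

#' @export
print.qpi_retrieval <- function(x, ...) {
  cat(sprintf("<qpi_retrieval> d = %.4g m, %d iteration(s)%s, final sensor error %.3g\n",
              x$config$d, x$iterations_run,
              if (x$converged) " (converged)" else "",
              x$error_history[x$iterations_run]))
  if (!is.null(x$correlation_history))
    cat(sprintf("  final normalized correlation %.4f\n",
                x$correlation_history[x$iterations_run]))
  invisible(x)
}

#' Refocus scan: retrieval over a set of candidate distances
#'
#' Runs [gsa_retrieve()] independently at each distance and scores each
#' reconstruction with the autofocus metric of [focus_metric()].  When
#' reference phase maps are supplied (simulation studies), the summary also
#' reports the per-reference masked correlation at every distance — the
#' quantitative counterpart of judging which plane of a thick object is in
#' focus.
#'
#' @param amplitude_sensor Prepared sensor amplitude or raw intensity.
#' @param config A [retrieval_config()]; its `d` is replaced per scan point.
#' @param grid A `qpi_grid`.
#' @param distances Numeric vector of candidate distances in metres (at
#'   least one, all positive).
#' @param reference_phase Optional single reference forwarded to
#'   [gsa_retrieve()] for the correlation history.
#' @param reference_planes Optional named list of `n1 x n2` reference phase
#'   maps; each contributes a `corr_<name>` column to the summary.
#' @param sample_amplitude,score_support Forwarded to [gsa_retrieve()].
#' @return An object of class `qpi_refocus`: `results` (list of
#'   `qpi_retrieval`), `summary` (data frame of distance, focus score,
#'   final sensor error and any per-reference correlations) and `best`
#'   (distance with the highest focus score).
#' @export
refocus_scan <- function(amplitude_sensor, config, grid, distances,
                         reference_phase = NULL, reference_planes = NULL,
                         sample_amplitude = NULL, score_support = NULL) {
  if (length(distances) < 1L)
    stop("at least one scan distance is required", call. = FALSE)
  if (any(!is.finite(distances) | distances <= 0))
    stop("all scan distances must be positive", call. = FALSE)
  if (is.matrix(amplitude_sensor) && !is.complex(amplitude_sensor))
    amplitude_sensor <- prepare_sensor_amplitude(amplitude_sensor, grid)
  if (is.null(score_support) && !is.null(sample_amplitude))
    score_support <- crop_central(expand_sample_amplitude(sample_amplitude, grid),
                                  grid) > 0.5
  results <- lapply(distances, function(d) {
    cfg <- config
    cfg$d <- d
    gsa_retrieve(amplitude_sensor, cfg, grid, reference_phase = reference_phase,
                 sample_amplitude = sample_amplitude,
                 score_support = score_support)
  })
  focus <- vapply(results, function(r)
    focus_metric(r$phase$values, support = score_support), numeric(1))
  err <- vapply(results, function(r) r$error_history[r$iterations_run], numeric(1))
  summary <- data.frame(distance = distances, focus = focus, final_error = err)
  for (nm in names(reference_planes)) {
    ref <- phase_values(reference_planes[[nm]])
    summary[[paste0("corr_", nm)]] <- vapply(results, function(r)
      scored_correlation(ref, r$phase$values, score_support), numeric(1))
  }
  structure(list(results = results, summary = summary,
                 best = distances[which.max(focus)]),
            class = "qpi_refocus")
}

#' @export
print.qpi_refocus <- function(x, ...) {
  cat(sprintf("<qpi_refocus> %d distance(s), best focus at %.4g m\n",
              nrow(x$summary), x$best))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Autofocus score of a retrieved phase image
#'
#' Negative mean gradient magnitude of the phase image.  An in-focus
#' reconstruction of a piecewise-flat phase object is smooth apart from its
#' edges, while a defocused one is filled with diffraction ringing, so the
#' score is highest (least negative) near best focus.
#'
#' @param phase A phase matrix or `qpi_phase`.
#' @param support Optional logical mask restricting the evaluation region.
#' @return A non-positive number; higher means better focus.
#' @export
focus_metric <- function(phase, support = NULL) {
  v <- phase_values(phase)
  gx <- v[-1, -1] - v[-nrow(v), -1]
  gy <- v[-1, -1] - v[-1, -ncol(v)]
  g <- sqrt(gx^2 + gy^2)
  if (!is.null(support)) g <- g[support[-1, -1]]
  -mean(g)
}

#' Illumination-corrected reconstruction distance
#'
#' With a diverging spherical illumination from a source at distance `d1`,
#' the best reconstruction of a sample at distance `d2` from the sensor is
#' obtained by propagating not by `d2` but by
#' `d2' = (1/d2 - 1/d1)^-1` (paraxial regime).  As `d1 -> Inf` (plane-wave
#' illumination) `d2'` tends to `d2`.
#'
#' @param d1 Source-to-sample distance in metres (> d2; may be `Inf`).
#' @param d2 Sample-to-sensor distance in metres (> 0).
#' @return The corrected distance in metres.
#' @examples
#' effective_distance(2.0, 0.2)   # 0.2222 m
#' @export
effective_distance <- function(d1, d2) {
  if (!is.numeric(d1) || !is.numeric(d2) || d2 <= 0)
    stop("distances must be positive numbers", call. = FALSE)
  if (d2 >= d1)
    stop("requires d2 < d1 (sample between source and sensor)", call. = FALSE)
  if (is.infinite(d1)) return(d2)
  1 / (1 / d2 - 1 / d1)
}

#' Step height between the object and background regions of a phase map
#'
#' Robust step estimate: the difference of the median phase inside the
#' support mask and the median outside it (within `background` when given).
#' With `circular = TRUE` the difference is wrapped to `(-pi, pi]`, which
#' removes whole-fringe offsets when comparing against steps of at most pi.
#'
#' @param phase A `qpi_phase` or phase matrix.
#' @param support Logical mask of the object region; defaults to the phase
#'   map's own support.
#' @param background Optional logical mask of the background region;
#'   defaults to the complement of `support`.
#' @param circular Wrap the difference to `(-pi, pi]`.
#' @return Step height in radians (signed).
#' @export
step_height <- function(phase, support = NULL, background = NULL,
                        circular = FALSE) {
  v <- phase_values(phase)
  if (is.null(support) && inherits(phase, "qpi_phase")) support <- phase$support
  if (is.null(support)) stop("a support mask is required", call. = FALSE)
  if (is.null(background)) background <- !support
  d <- stats::median(v[support]) - stats::median(v[background])
  if (circular) Arg(exp(1i * d)) else d
}
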