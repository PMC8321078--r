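#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration convergence history of a retrieval
#'
#' @param x A `qpi_retrieval`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`,
#'   `sensor_error` and (when a reference was supplied) `correlation`.
#' @export
tidy.qpi_retrieval <- function(x, ...) {
  out <- tibble::tibble(iteration = seq_len(x$iterations_run),
                        sensor_error = x$error_history)
  if (!is.null(x$correlation_history)) out$correlation <- x$correlation_history
  out
}

#' One-row summary of a retrieval
#'
#' @param x A `qpi_retrieval`.
#' @param ... Unused.
#' @return A one-row tibble: iterations run, convergence flag, final
#'   sensor error and final correlation (`NA` without a reference).
#' @export
glance.qpi_retrieval <- function(x, ...) {
  tibble::tibble(
    iterations_run = x$iterations_run,
    converged = x$converged,
    final_error = x$error_history[x$iterations_run],
    final_correlation = if (!is.null(x$correlation_history))
      x$correlation_history[x$iterations_run] else NA_real_,
    distance = x$config$d)
}

#' Tidy a refocus scan
#'
#' @param x A `qpi_refocus`.
#' @param ... Unused.
#' @return A tibble with one row per scanned distance.
#' @export
tidy.qpi_refocus <- function(x, ...) tibble::as_tibble(x$summary)

#' Convergence-history plot for a retrieval
#'
#' @param object A `qpi_retrieval`.
#' @param ... Unused.
#' @return A ggplot of the sensor-error (and correlation) histories.
#' @export
autoplot.qpi_retrieval <- function(object, ...) {
  df <- tidy.qpi_retrieval(object)
  long <- do.call(rbind, lapply(setdiff(names(df), "iteration"), function(nm)
    data.frame(iteration = df$iteration, metric = nm, value = df[[nm]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Phase retrieval convergence")
}

#' Phase-map image plot
#'
#' @param object A `qpi_phase`.
#' @param ... Unused.
#' @return A ggplot raster of the phase in radians.
#' @export
autoplot.qpi_phase <- function(object, ...) {
  v <- object$values
  df <- data.frame(row = rep(seq_len(nrow(v)), ncol(v)),
                   col = rep(seq_len(ncol(v)), each = nrow(v)),
                   phase = as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "rad")
}

#' Focus-score plot for a refocus scan
#'
#' @param object A `qpi_refocus`.
#' @param ... Unused.
#' @return A ggplot of focus score versus reconstruction distance.
#' @export
autoplot.qpi_refocus <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$distance, y = .data$focus)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "reconstruction distance (m)", y = "focus score")
}

#' Base-graphics image of a phase map
#'
#' @param x A `qpi_phase`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.qpi_phase <- function(x, ...) {
  graphics::image(t(x$values)[, nrow(x$values):1], asp = 1, axes = FALSE, ...)
  invisible(x)
}
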