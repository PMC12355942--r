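#' Quick-look EEM heat map
#'
#' @param object An [new_eem()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eem
#' @export
autoplot.eem <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ex, y = .data$em,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "excitation (nm)", y = "emission (nm)",
                  fill = "intensity", title = object$sample_id) +
    ggplot2::theme_minimal()
}

#' Absorbance spectrum plot
#'
#' @param object An [new_abs_spectrum()] object.
#' @param log_y Plot absorbance on a log scale (natural for exponential
#'   CDOM spectra).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abs_spectrum
#' @export
autoplot.abs_spectrum <- function(object, log_y = FALSE, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength,
                                       y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "decadic absorbance",
                  title = object$sample_id) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Scatter-plus-line plot of a simple regression fit
#'
#' @param object A `dom_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dom_fit
#' @export
autoplot.dom_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$fitted, residual = object$residuals)
  d$y <- d$x + d$residual
  b0 <- if (is.na(object$intercept)) 0 else object$intercept
  # recover x on the original scale from the fitted line
  d$x <- (d$x - b0) / object$slope
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = b0,
                         colour = "steelblue") +
    ggplot2::labs(x = if (is.null(object$index)) "x" else object$index,
                  y = if (is.null(object$response)) "y" else object$response,
                  subtitle = sprintf("%s: slope %.3f, R2 %.3f, RMSE %.3f",
                                     object$method, object$slope,
                                     object$r_squared, object$rmse)) +
    ggplot2::theme_minimal()
}

#' RMSE and information-criterion overview of a model comparison
#'
#' @param object A `doc_model_comparison`.
#' @param ... Unused.
#' @return A ggplot (per-model RMSE bars, preferred model highlighted).
#' @method autoplot doc_model_comparison
#' @export
autoplot.doc_model_comparison <- function(object, ...) {
  d <- object$summary
  d$preferred <- d$model == object$preferred
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$model,
                                                     .data$rmse),
                                  y = .data$rmse,
                                  fill = .data$preferred)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "RMSE (mg/L DOC)",
                  title = "DOC model comparison",
                  subtitle = paste("preferred:", object$preferred)) +
    ggplot2::theme_minimal()
}

#' Histogram of simulated regression RMSEs
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot with the median (and observed RMSE, if supplied) marked.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rmse)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_rmse,
                        colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "per-run RMSE (m^2/gC)", y = "runs",
                  title = "Measurement-error simulation") +
    ggplot2::theme_minimal()
  if (!is.null(object$observed_rmse)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_rmse,
                                 colour = "firebrick", linetype = 2)
  }
  p
}
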