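#' Specify Gaussian measurement-error magnitudes
#'
#' A noise model holds one error spec per measured variable — DOC, ARIX and
#' A254 — each either `absolute` (adds `N(0, sd)` in the variable's units)
#' or `relative` (multiplies the true value by `1 + N(0, sd)`). Errors are
#' zero-mean, mirroring how random instrument error is usually reported.
#'
#' The defaults are placeholders at magnitudes typical of routine
#' laboratory practice (DOC 5% relative; ARIX 0.05 absolute; A254 2%
#' relative); calibrate them to your own instruments before interpreting
#' simulation output quantitatively.
#'
#' @param doc,arix,a254 Each a list `list(mode = "absolute"|"relative",
#'   sd = <non-negative>)`.
#' @return A `noise_model` object.
#' @export
noise_model <- function(doc = list(mode = "relative", sd = 0.05),
                        arix = list(mode = "absolute", sd = 0.05),
                        a254 = list(mode = "relative", sd = 0.02)) {
  spec <- list(doc = doc, arix = arix, a254 = a254)
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (!is.list(s) || !all(c("mode", "sd") %in% names(s)) ||
        !s$mode %in% c("absolute", "relative") ||
        !is.numeric(s$sd) || s$sd < 0) {
      stop("noise spec for ", nm,
           " must be list(mode = 'absolute'|'relative', sd >= 0)",
           call. = FALSE)
    }
  }
  structure(spec, class = "noise_model")
}

perturb <- function(x, spec) {
  if (spec$sd == 0) return(x)
  if (spec$mode == "absolute") {
    x + stats::rnorm(length(x), 0, spec$sd)
  } else {
    x * (1 + stats::rnorm(length(x), 0, spec$sd))
  }
}

#' Build the error-free counterpart of a sample table
#'
#' Starting point of the measurement-error simulation: DOC, SUVA and ARIX
#' keep their observed values, while A254 is recomputed as
#' `(beta1 * ARIX + beta0) * DOC` so that every sample falls exactly on the
#' reference SUVA-vs-ARIX regression line (SUVA = A254/DOC then equals the
#' line by construction, and a refit returns RMSE 0). The resulting table
#' keeps the observed distribution of DOC and ARIX but carries no scatter.
#'
#' @param table Sample table with `doc` and `arix` columns.
#' @param beta1,beta0 Reference regression coefficients (defaults: the
#'   global whole-water SUVA-from-ARIX calibration, 6.1 and -0.7).
#' @return The table with `a254` and `suva` replaced; reference line stored
#'   in attribute `ref_line`.
#' @export
build_error_free <- function(table, beta1 = 6.1, beta0 = -0.7) {
  stopifnot(is.data.frame(table))
  need_cols(table, c("doc", "arix"))
  suva_line <- beta1 * table$arix + beta0
  bad <- suva_line < 0
  if (any(bad, na.rm = TRUE)) {
    ids <- if ("sample_id" %in% names(table)) {
      table$sample_id[which(bad)]
    } else {
      which(bad)
    }
    stop("negative implied A254 for samples with ARIX below ",
         signif(-beta0 / beta1, 4), ": ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(table)
  out$a254 <- suva_line * out$doc
  out$suva <- out$a254 / out$doc
  attr(out, "ref_line") <- c(beta0 = beta0, beta1 = beta1)
  out
}

#' Monte Carlo measurement-error propagation into SUVA-vs-ARIX scatter
#'
#' Estimates how much of the scatter in a SUVA-versus-ARIX regression could
#' be produced by random measurement error alone. Each run perturbs DOC,
#' ARIX and A254 of the error-free table with independent Gaussian errors
#' from the [noise_model()], recomputes `SUVA = A254 / DOC`, refits the
#' model I regression of SUVA on ARIX, and records its RMSE. The summary is
#' the median RMSE across runs and, when an observed RMSE is supplied, the
#' percent ratio `100 * median / observed` — the share of observed scatter
#' attributable to random error.
#'
#' Perturbed DOC values at or below zero are resampled (bounded retries)
#' rather than truncated, to keep the error distribution approximately
#' zero-mean. With `refit = FALSE` each run scores SUVA against the fixed
#' reference line of [build_error_free()] instead of refitting; refitting is
#' the default because prediction error is conventionally reported from
#' fitted models.
#'
#' @param table An error-free table from [build_error_free()].
#' @param noise A [noise_model()].
#' @param runs Number of simulation runs (default 100).
#' @param observed_rmse Observed RMSE to compare against (optional).
#' @param seed Random seed; required for reproducibility.
#' @param refit Refit the regression each run (`TRUE`) or score against the
#'   fixed reference line.
#' @param max_retries Per-run cap on DOC resampling attempts.
#' @return A `sensitivity_result`: list with `rmse_runs`, `median_rmse`,
#'   `observed_rmse`, `ratio_pct`, `runs`, `retries`, `noise`, `seed`.
#' @export
run_sensitivity <- function(table, noise = noise_model(), runs = 100,
                            observed_rmse = NULL, seed = NULL, refit = TRUE,
                            max_retries = 100) {
  stopifnot(is.data.frame(table), inherits(noise, "noise_model"), runs >= 1)
  need_cols(table, c("doc", "arix", "a254"))
  if (!is.null(seed)) set.seed(seed)
  ref <- attr(table, "ref_line")
  if (!refit && is.null(ref)) {
    stop("refit = FALSE needs the reference line; build the table with ",
         "build_error_free()", call. = FALSE)
  }
  retries <- 0L
  rmse_runs <- vapply(seq_len(runs), function(run) {
    doc <- perturb(table$doc, noise$doc)
    for (i in which(doc <= 0)) {
      tries <- 0L
      while (doc[i] <= 0 && tries < max_retries) {
        doc[i] <- perturb(table$doc[i], noise$doc)
        tries <- tries + 1L
        retries <<- retries + 1L
      }
      if (doc[i] <= 0) {
        stop("could not draw positive DOC for sample ", i, " after ",
             max_retries, " retries; noise sd too large for this DOC",
             call. = FALSE)
      }
    }
    arix <- perturb(table$arix, noise$arix)
    a254 <- perturb(table$a254, noise$a254)
    suva <- a254 / doc
    if (refit) {
      ols_fit(arix, suva, intercept = TRUE)$rmse
    } else {
      pred <- ref[["beta0"]] + ref[["beta1"]] * arix
      sqrt(sum((suva - pred)^2) / (length(suva) - 2))
    }
  }, numeric(1))
  med <- stats::median(rmse_runs)
  structure(
    list(rmse_runs = rmse_runs, median_rmse = med,
         observed_rmse = observed_rmse,
         ratio_pct = if (is.null(observed_rmse)) NA_real_ else
           100 * med / observed_rmse,
         runs = runs, retries = retries, noise = noise, seed = seed,
         refit = refit),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d runs, median RMSE %.4g", x$runs,
              x$median_rmse))
  if (!is.na(x$ratio_pct)) {
    cat(sprintf(" = %.1f%% of observed (%.4g)", x$ratio_pct,
                x$observed_rmse))
  }
  cat("\n")
  invisible(x)
}
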