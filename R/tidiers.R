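#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a simple-regression fit
#'
#' One row per coefficient, broom-style.
#'
#' @param x A `dom_fit` from [ols_fit()], [gm_fit()] or [fit_suva_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy dom_fit
#' @export
tidy.dom_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
  out[!is.na(out$estimate), ]
}

#' @rdname tidy.dom_fit
#' @method glance dom_fit
#' @export
glance.dom_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, rmse = x$rmse, nobs = x$n,
                 df.residual = x$df, method = x$method)
}

#' Tidy a DOC-model fit
#'
#' One row per model coefficient (e.g. `b0`, `b1`, `b2` for the interaction
#' model; `C`, `M` for the Pan-Arctic model; `phi`, `doc_cor` for the
#' UV-slope models).
#'
#' @param x A fit from [fit_doc_model()] or [doc_uv_model()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @method tidy doc_model_fit
#' @export
tidy.doc_model_fit <- function(x, ...) {
  terms <- intersect(c("b0", "b1", "b2", "C", "M", "phi", "doc_cor"),
                     names(x))
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x[[t]], numeric(1)),
    std.error = vapply(terms, function(t) {
      se <- x[[paste0(t, "_se")]]
      if (is.null(se)) NA_real_ else se
    }, numeric(1))
  )
}

#' @rdname tidy.doc_model_fit
#' @method glance doc_model_fit
#' @export
glance.doc_model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    proxy = if (is.null(x$proxy)) NA_character_ else x$proxy,
    r.squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
    rmse = if (is.null(x$rmse)) NA_real_ else x$rmse,
    nobs = if (is.null(x$n)) NA_integer_ else x$n,
    k = x$k
  )
}

#' Tidy a spectral-slope fit
#'
#' @param x A `slope_fit` from [spectral_slope()].
#' @param ... Unused.
#' @return A one-row tibble with the slope in both 1/nm and 1/um views.
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(
    band_lo = x$band[1], band_hi = x$band[2], method = x$method,
    s_per_nm = x$S, s_per_um = x$S * 1000, a_ref = x$a_ref,
    lambda_ref = x$lambda_ref, r.squared = x$r_squared, rmse = x$rmse,
    n = x$n
  )
}

#' Tidy a model-comparison report
#'
#' @param x A `doc_model_comparison` from [compare_doc_models()].
#' @param ... Unused.
#' @return The per-model summary tibble.
#' @method tidy doc_model_comparison
#' @export
tidy.doc_model_comparison <- function(x, ...) x$summary

#' @rdname tidy.doc_model_comparison
#' @method glance doc_model_comparison
#' @export
glance.doc_model_comparison <- function(x, ...) {
  tibble::tibble(preferred = x$preferred, n_models = nrow(x$summary),
                 nobs = x$n, ties = length(x$ties))
}

#' Tidy a sensitivity-simulation result
#'
#' @param x A `sensitivity_result` from [run_sensitivity()].
#' @param ... Unused.
#' @return A tibble with one row per simulation run.
#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  tibble::tibble(run = seq_along(x$rmse_runs), rmse = x$rmse_runs)
}

#' @rdname tidy.sensitivity_result
#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(median_rmse = x$median_rmse,
                 observed_rmse = if (is.null(x$observed_rmse)) NA_real_ else
                   x$observed_rmse,
                 ratio_pct = x$ratio_pct, runs = x$runs,
                 retries = x$retries)
}
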