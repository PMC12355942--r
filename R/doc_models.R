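# Unit conventions used throughout this module (each fit object records its
# own; cross-unit inputs are rejected, never converted silently):
#   doc       mg/L (= g/m^3)
#   a254      decadic absorption coefficient, 1/m
#   a275,a350 Napierian absorption coefficients, 1/m
#   s275_295, s380_443  spectral slopes, 1/nm (the interaction proxy uses
#                       1/S with S in 1/um; the UV-slope formulas use 1/nm,
#                       where their constants 0.078 and 0.0084 live)
#   suva      m^2/gC

MG_PER_UMOL_C <- 12.011 / 1000

#' Fit a DOC prediction model to a sample table
#'
#' Four model families predict DOC concentration from absorbance:
#'
#' * `base`: `DOC = b0 + b1 * A254`, ordinary least squares.
#' * `arint` (aromaticity interaction): `DOC = b0 + b1 * A254 +
#'   b2 * A254 * P`, where the aromaticity proxy `P` enters only through the
#'   interaction — never as a main effect, because the proxy is undefined
#'   when absorbance is zero. `P` is ARIX, `1/S275-295` (S in 1/um), or SUVA
#'   (the perfect-proxy reference case). The intercept `b0` is uncolored DOC;
#'   `b1` is positive and `b2` negative in the regime these models describe,
#'   so the DOC gained per unit absorbance falls as aromaticity rises.
#' * `pan_arctic`: OLS of `log10(DOC / a350)` on `S275-295` (1/um),
#'   estimating `C` (intercept) and `M` (slope).
#' * `doc_ls`: the UV-slope formula `DOC_uM = Phi * a275 * (S275-295 +
#'   0.078 * S380-443 - 0.0084) + DOC_cor` (slopes in 1/nm, DOC in umol/L)
#'   with `Phi` and `DOC_cor` fitted by least squares. The global preset with
#'   `Phi = 1507` and `DOC_cor = 32.2` fixed is [doc_uv_model()].
#'
#' @param table Sample table. Required columns by model: base/arint `doc`,
#'   `a254` (+ the proxy column); pan_arctic `doc`, `a350`, `s275_295`;
#'   doc_ls `doc`, `a275`, `s275_295`, `s380_443`.
#' @param model One of `"base"`, `"arint"`, `"pan_arctic"`, `"doc_ls"`.
#' @param proxy ARINT only: `"arix"`, `"inv_s275"` or `"suva"`.
#' @return A fit object of class `c("<model>_fit", "doc_model_fit")` with
#'   coefficients, their standard errors, residuals and fitted values in DOC
#'   space (mg/L), `r_squared`, `rmse` (df denominator), `n`, and the
#'   parameter count `k` used for information criteria (2, 3, 2, 2). For the
#'   base and interaction fits the standard errors are
#'   heteroscedasticity-consistent (HC3), since DOC measurement error
#'   typically scales with concentration.
#' @export
fit_doc_model <- function(table, model = c("base", "arint", "pan_arctic",
                                           "doc_ls"),
                          proxy = c("arix", "inv_s275", "suva")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(table))
  switch(model,
    base = fit_doc_base(table),
    arint = fit_arint(table, match.arg(proxy)),
    pan_arctic = fit_pan_arctic(table),
    doc_ls = fit_doc_ls(table)
  )
}

need_cols <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

proxy_values <- function(table, proxy) {
  switch(proxy,
    arix = {
      need_cols(table, "arix")
      table$arix
    },
    inv_s275 = {
      need_cols(table, "s275_295")
      1 / (table$s275_295 * 1000)  # 1/S with S in 1/um
    },
    suva = {
      need_cols(table, "suva")
      table$suva
    },
    stop("unknown proxy kind: ", proxy, call. = FALSE)
  )
}

doc_space_stats <- function(fit, doc, fitted, k) {
  resid <- doc - fitted
  tss <- sum((doc - mean(doc))^2)
  fit$fitted <- fitted
  fit$residuals <- resid
  fit$n <- length(doc)
  fit$k <- k
  fit$r_squared <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  fit$rmse <- sqrt(sum(resid^2) / (length(doc) - k))
  fit
}

# Classical OLS standard errors (homoscedastic), used where the response
# is variance-stabilized (log-ratio and micromolar fits).
classical_se <- function(X, residuals) {
  sigma2 <- sum(residuals^2) / (nrow(X) - ncol(X))
  sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
}

# HC3 sandwich standard errors. DOC measurement error scales with
# concentration, so the homoscedastic OLS variance is anti-conservative for
# the concentration-space fits; HC3 keeps the 3-SE intervals honest.
hc3_se <- function(X, residuals) {
  XtXinv <- chol2inv(chol(crossprod(X)))
  h <- rowSums((X %*% XtXinv) * X)
  meat <- t(X) %*% (X * (residuals^2 / (1 - h)^2))
  sqrt(diag(XtXinv %*% meat %*% XtXinv))
}

fit_doc_base <- function(table) {
  need_cols(table, c("doc", "a254"))
  ok <- is.finite(table$doc) & is.finite(table$a254)
  doc <- table$doc[ok]; a254 <- table$a254[ok]
  if (length(doc) < 3) stop("need >= 3 complete records", call. = FALSE)
  X <- cbind(1, a254)
  f <- stats::lm.fit(X, doc)
  cf <- f$coefficients
  se <- hc3_se(X, f$residuals)
  fit <- structure(
    list(model = "base", b0 = unname(cf[1]), b1 = unname(cf[2]),
         b0_se = unname(se[1]), b1_se = unname(se[2])),
    class = c("doc_base_fit", "doc_model_fit"))
  doc_space_stats(fit, doc, doc - f$residuals, k = 2L)
}

fit_arint <- function(table, proxy) {
  need_cols(table, c("doc", "a254"))
  p_all <- proxy_values(table, proxy)
  ok <- is.finite(table$doc) & is.finite(table$a254) & is.finite(p_all)
  doc <- table$doc[ok]; a254 <- table$a254[ok]; p <- p_all[ok]
  if (length(doc) < 4) stop("need >= 4 complete records for arint",
                            call. = FALSE)
  X <- cbind(1, a254, a254 * p)
  if (qr(X)$rank < 3) {
    stop("rank-deficient design: constant proxy makes A254 and A254*P ",
         "collinear", call. = FALSE)
  }
  f <- stats::lm.fit(X, doc)
  cf <- f$coefficients
  se <- hc3_se(X, f$residuals)
  fit <- structure(
    list(model = "arint", proxy = proxy,
         b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]),
         b0_se = unname(se[1]), b1_se = unname(se[2]), b2_se = unname(se[3]),
         b2_unit = switch(proxy, arix = "g/m^2", suva = "g^2/m^4",
                          inv_s275 = "Mg/m")),
    class = c("arint_fit", "doc_model_fit"))
  doc_space_stats(fit, doc, doc - f$residuals, k = 3L)
}

fit_pan_arctic <- function(table) {
  need_cols(table, c("doc", "a350", "s275_295"))
  ok <- is.finite(table$doc) & is.finite(table$a350) &
    is.finite(table$s275_295)
  doc <- table$doc[ok]; a350 <- table$a350[ok]
  s_um <- table$s275_295[ok] * 1000
  if (any(doc <= 0 | a350 <= 0)) {
    stop("pan_arctic requires positive DOC and a350 (log-ratio model)",
         call. = FALSE)
  }
  if (length(doc) < 3) stop("need >= 3 complete records", call. = FALSE)
  X <- cbind(1, s_um)
  f <- stats::lm.fit(X, log10(doc / a350))
  cf <- f$coefficients
  se <- classical_se(X, f$residuals)
  fit <- structure(
    list(model = "pan_arctic", C = unname(cf[1]), M = unname(cf[2]),
         C_se = unname(se[1]), M_se = unname(se[2]), s_unit = "1/um"),
    class = c("pan_arctic_fit", "doc_model_fit"))
  doc_space_stats(fit, doc, a350 * 10^(drop(X %*% cf)), k = 2L)
}

uv_slope_term <- function(table) {
  table$a275 * (table$s275_295 + 0.078 * table$s380_443 - 0.0084)
}

fit_doc_ls <- function(table) {
  need_cols(table, c("doc", "a275", "s275_295", "s380_443"))
  x_all <- uv_slope_term(table)
  ok <- is.finite(table$doc) & is.finite(x_all)
  doc_um <- table$doc[ok] / MG_PER_UMOL_C
  x <- x_all[ok]
  if (length(x) < 3) stop("need >= 3 complete records", call. = FALSE)
  X <- cbind(1, x)
  f <- stats::lm.fit(X, doc_um)
  cf <- f$coefficients
  se <- classical_se(X, f$residuals)
  fit <- structure(
    list(model = "doc_ls", phi = unname(cf[2]), doc_cor = unname(cf[1]),
         phi_se = unname(se[2]), doc_cor_se = unname(se[1])),
    class = c("doc_ls_fit", "doc_model_fit"))
  doc_space_stats(fit, table$doc[ok],
                  drop(X %*% cf) * MG_PER_UMOL_C, k = 2L)
}

#' The fixed global UV-slope DOC model
#'
#' The externally calibrated preset of the UV-slope formula with
#' `Phi = 1507 m nm umol/L` and `DOC_cor = 32.2 umol/L` fixed; no parameters
#' are estimated from the data (`k = 0`), which makes it the most
#' parsimonious entry in information-criterion comparisons.
#'
#' @return A fit-like object of class `c("doc_uv_model", "doc_model_fit")`.
#' @export
doc_uv_model <- function() {
  structure(
    list(model = "doc_uv", phi = 1507, doc_cor = 32.2, k = 0L),
    class = c("doc_uv_model", "doc_model_fit"))
}

#' Predict DOC from a fitted (or preset) DOC model
#'
#' Applies the model formula to new samples. ARINT fits refuse a table
#' whose proxy column does not match the fitted proxy kind. UV-slope
#' predictions are converted from umol/L to mg/L via 12.011 g/mol.
#'
#' @param fit A fit from [fit_doc_model()] or [doc_uv_model()].
#' @param table Sample table with the model's required input columns.
#' @return Numeric vector of predicted DOC, mg/L.
#' @export
predict_doc <- function(fit, table) {
  UseMethod("predict_doc")
}

#' @export
predict_doc.doc_base_fit <- function(fit, table) {
  need_cols(table, "a254")
  fit$b0 + fit$b1 * table$a254
}

#' @export
predict_doc.arint_fit <- function(fit, table) {
  need_cols(table, "a254")
  p <- proxy_values(table, fit$proxy)
  fit$b0 + fit$b1 * table$a254 + fit$b2 * table$a254 * p
}

#' @export
predict_doc.pan_arctic_fit <- function(fit, table) {
  need_cols(table, c("a350", "s275_295"))
  table$a350 * 10^(fit$C + fit$M * table$s275_295 * 1000)
}

#' @export
predict_doc.doc_ls_fit <- function(fit, table) {
  need_cols(table, c("a275", "s275_295", "s380_443"))
  (fit$phi * uv_slope_term(table) + fit$doc_cor) * MG_PER_UMOL_C
}

#' @export
predict_doc.doc_uv_model <- function(fit, table) {
  need_cols(table, c("a275", "s275_295", "s380_443"))
  (fit$phi * uv_slope_term(table) + fit$doc_cor) * MG_PER_UMOL_C
}

#' @export
print.doc_model_fit <- function(x, ...) {
  cat("<", x$model, " DOC model>\n", sep = "")
  cf <- x[names(x) %in% c("b0", "b1", "b2", "C", "M", "phi", "doc_cor")]
  for (nm in names(cf)) cat(sprintf("  %-8s %.6g\n", nm, cf[[nm]]))
  if (!is.null(x$rmse)) {
    cat(sprintf("  n = %d, R2 = %.4f, RMSE = %.4f mg/L\n", x$n, x$r_squared,
                x$rmse))
  }
  invisible(x)
}

#' Invert the interaction model for A254
#'
#' The interaction model rearranges to `A254 = (DOC - b0) / (b1 + b2 * P)`:
#' colored DOC (`DOC - b0`) times the inverse apparent absorptivity. This is
#' the Beer-Lambert reading of the model — chromophoric DOC absorbs with an
#' effective molar absorptivity proportional to `1 / (b1 + b2 * P)`. The
#' round trip `invert_a254(fit, predict_doc(fit, table), P)` returns the
#' table's A254 exactly. Negative output (DOC below the uncolored-DOC
#' intercept) is returned as-is; it flags physically impossible input.
#'
#' @param fit An `arint_fit`.
#' @param doc DOC values, mg/L.
#' @param p Proxy values of the fitted kind.
#' @return Predicted A254, 1/m.
#' @export
invert_a254 <- function(fit, doc, p) {
  stopifnot(inherits(fit, "arint_fit"))
  (doc - fit$b0) / (fit$b1 + fit$b2 * p)
}

#' Per-sample diagnostics of a fitted interaction model
#'
#' For each sample: colored DOC `cdoc = DOC - b0`; the apparent molar
#' absorptivity proxy `epsilon = 1 / (b1 + b2 * P)` (flagged `NA` where the
#' bracket is non-positive, i.e. outside the physical regime); and the
#' interaction ratio `b2 * P / b1`, which measures how strongly aromaticity
#' modulates the DOC-absorbance coupling (values near 0: no modulation;
#' approaching -1: aromaticity cancels the absorbance term).
#'
#' @param fit An `arint_fit`.
#' @param table Sample table with `doc` and the fitted proxy's column.
#' @return A tibble with columns `sample_id` (if present), `cdoc`,
#'   `epsilon`, `interaction_ratio`; the ratio range is attached as
#'   attribute `ratio_range`.
#' @export
arint_diagnostics <- function(fit, table) {
  stopifnot(inherits(fit, "arint_fit"))
  need_cols(table, "doc")
  p <- proxy_values(table, fit$proxy)
  bracket <- fit$b1 + fit$b2 * p
  out <- tibble::tibble(
    cdoc = table$doc - fit$b0,
    epsilon = ifelse(bracket > 0, 1 / bracket, NA_real_),
    interaction_ratio = fit$b2 * p / fit$b1
  )
  if ("sample_id" %in% names(table)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = table$sample_id), out)
  }
  attr(out, "ratio_range") <- range(out$interaction_ratio, na.rm = TRUE)
  out
}

#' Information criteria from a Gaussian residual vector
#'
#' Gaussian log likelihood at the maximum-likelihood variance,
#' `logL = -(n/2) (ln 2pi + ln(RSS/n) + 1)`, then
#' `AIC = -2 logL + 2k`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = -2 logL + k ln n`, `CAIC = -2 logL + k (ln n + 1)`.
#' `k` counts estimated model coefficients only, following the convention
#' under which the fixed global UV-slope model has `k = 0`, two-coefficient
#' models have `k = 2` and the interaction model `k = 3`; set
#' `count_sigma = TRUE` to add one for the residual variance uniformly
#' (rank order is unchanged).
#'
#' @param residuals Residual vector of the fitted model.
#' @param k Number of estimated parameters.
#' @param n Number of observations (default `length(residuals)`).
#' @param count_sigma Add 1 to `k` for the residual variance.
#' @return A one-row tibble: `logL`, `k`, `n`, `aic`, `aicc`, `bic`, `caic`.
#' @export
info_criteria <- function(residuals, k, n = length(residuals),
                          count_sigma = FALSE) {
  rss <- sum(residuals^2)
  if (rss <= 0) {
    stop("perfect fit (RSS = 0): likelihood unbounded, report the ",
         "comparison as degenerate", call. = FALSE)
  }
  if (isTRUE(count_sigma)) k <- k + 1
  if (n - k - 1 <= 0) stop("need n > k + 1 for AICc", call. = FALSE)
  logl <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * logl + 2 * k
  tibble::tibble(
    logL = logl, k = k, n = n,
    aic = aic,
    aicc = aic + 2 * k * (k + 1) / (n - k - 1),
    bic = -2 * logl + k * log(n),
    caic = -2 * logl + k * (log(n) + 1)
  )
}

#' Compare DOC prediction models on one sample table
#'
#' Fits every model the table supports — base, the interaction model for
#' each requested proxy, Pan-Arctic, the fixed global UV-slope preset and
#' its locally fitted variant — on the identical complete-case subset, so
#' all information criteria share `n`. Reports per model the goodness of
#' fit, the percent change in RMSE relative to the base model, and the four
#' information criteria; the preferred model is the one lowest on a majority
#' of criteria, with ties listed explicitly.
#'
#' @param table Sample table.
#' @param proxies Proxy kinds to fit the interaction model with.
#' @param count_sigma Passed to [info_criteria()].
#' @return A `doc_model_comparison`: list with `summary` (tibble: `model`,
#'   `k`, `r_squared`, `rmse`, `pct_rmse_change`, `aic`, `aicc`, `bic`,
#'   `caic`), `preferred`, `ties`, `n`, and the underlying `fits`.
#' @export
compare_doc_models <- function(table, proxies = "arix", count_sigma = FALSE) {
  stopifnot(is.data.frame(table))
  has <- function(cols) all(cols %in% names(table))
  proxy_col <- c(arix = "arix", inv_s275 = "s275_295", suva = "suva")

  specs <- list()
  if (has(c("doc", "a254"))) specs$base <- list(model = "base")
  for (pr in proxies) {
    if (has(c("doc", "a254", proxy_col[[pr]]))) {
      specs[[paste0("arint_", pr)]] <- list(model = "arint", proxy = pr)
    }
  }
  if (has(c("doc", "a350", "s275_295"))) {
    specs$pan_arctic <- list(model = "pan_arctic")
  }
  if (has(c("doc", "a275", "s275_295", "s380_443"))) {
    specs$doc_uv <- list(model = "doc_uv")
    specs$doc_ls <- list(model = "doc_ls")
  }
  if (length(specs) < 2) {
    stop("table supports fewer than 2 models; nothing to compare",
         call. = FALSE)
  }

  used_cols <- unique(c("doc", unlist(lapply(names(specs), function(nm) {
    switch(specs[[nm]]$model,
           base = "a254",
           arint = c("a254", proxy_col[[specs[[nm]]$proxy]]),
           pan_arctic = c("a350", "s275_295"),
           c("a275", "s275_295", "s380_443"))
  }))))
  cc <- stats::complete.cases(table[used_cols])
  sub <- table[cc, , drop = FALSE]
  n <- nrow(sub)

  fits <- lapply(specs, function(sp) {
    if (sp$model == "doc_uv") {
      doc_uv_model()
    } else if (sp$model == "arint") {
      fit_doc_model(sub, "arint", proxy = sp$proxy)
    } else {
      fit_doc_model(sub, sp$model)
    }
  })

  rows <- purrr::imap(fits, function(fit, nm) {
    pred <- predict_doc(fit, sub)
    k <- fit$k
    met <- fit_metrics(sub$doc, pred, n_params = k)
    ic <- info_criteria(sub$doc - pred, k = k, n = n,
                        count_sigma = count_sigma)
    tibble::tibble(model = nm, k = ic$k, r_squared = met$r_squared,
                   rmse = met$rmse, aic = ic$aic, aicc = ic$aicc,
                   bic = ic$bic, caic = ic$caic)
  })
  summary <- dplyr::bind_rows(rows)
  base_rmse <- summary$rmse[summary$model == "base"]
  summary$pct_rmse_change <- if (length(base_rmse) == 1) {
    100 * (summary$rmse - base_rmse) / base_rmse
  } else {
    NA_real_
  }
  summary <- summary[, c("model", "k", "r_squared", "rmse",
                         "pct_rmse_change", "aic", "aicc", "bic", "caic")]

  crits <- c("aic", "aicc", "bic", "caic")
  winners <- vapply(crits, function(cr) {
    summary$model[which.min(summary[[cr]])]
  }, character(1))
  tally <- sort(table(winners), decreasing = TRUE)
  top <- names(tally)[tally == max(tally)]
  structure(
    list(summary = summary,
         preferred = if (length(top) == 1) top else NA_character_,
         ties = if (length(top) > 1) top else character(),
         criterion_winners = winners, n = n, fits = fits),
    class = "doc_model_comparison")
}

#' @export
print.doc_model_comparison <- function(x, ...) {
  cat("<doc_model_comparison> n =", x$n, "\n")
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  if (!is.na(x$preferred)) {
    cat("preferred:", x$preferred, "(lowest on",
        sum(x$criterion_winners == x$preferred), "of 4 criteria)\n")
  } else {
    cat("tie between:", paste(x$ties, collapse = ", "), "\n")
  }
  invisible(x)
}
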