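#' Registry of published aromaticity proxy equations
#'
#' The affine calibrations, with coefficients exactly as printed in the
#' source calibrations, that link the fluorescence aromaticity indices to
#' independent measures of DOM aromaticity:
#'
#' | id | equation | output |
#' |----|----------|--------|
#' | `pa_pp_from_parix` | `%(PA+PP) = 30.28 * PARIX` | percent polycyclic aromatic + polyphenolic FT-ICR-MS formulas |
#' | `hs_bb_from_arix` | `HS/BB = 6.1 * ARIX` | LC-OCD humic-substance / building-block ratio |
#' | `suva_from_arix` | `SUVA = 6.1 * ARIX - 0.7` | SUVA, m^2/gC (global whole-water model II calibration) |
#' | `suva_from_arix_isolates` | `SUVA = 4.5 * ARIX` | SUVA, m^2/gC (DOM extracts, through origin) |
#' | `aromaticity_from_suva` | `% aromaticity = 6.52 * SUVA + 3.63` | percent aromatic carbon (13C-NMR calibration) |
#' | `aromaticity_from_arix` | `% aromaticity = 29.3 * ARIX + 3.63` | as above, composed through the isolate ARIX calibration |
#'
#' The zero intercepts of the first two equations encode the limit of no
#' aromatic structures: when the long-emission fluorophores vanish, so do
#' the aromatic fractions. The ARIX form of the percent-aromaticity relation
#' inherits the caveat that it extends a 13C-NMR calibration made on XAD-8
#' isolates, assuming extract fluorescence behaves like bulk DOM; the
#' `caveat` column carries this.
#'
#' @return A tibble with columns `model_id`, `input`, `output`, `slope`,
#'   `intercept`, `description`, `caveat`.
#' @export
published_models <- function() {
  tibble::tribble(
    ~model_id, ~input, ~output, ~slope, ~intercept, ~description, ~caveat,
    "pa_pp_from_parix", "PARIX", "percent_pa_pp", 30.28, 0,
    "Percent polycyclic aromatic + polyphenolic formulas (FT-ICR-MS) from PARIX; zero intercept: no aromatic structures, no long-emission fluorescence.",
    NA_character_,
    "hs_bb_from_arix", "ARIX", "hs_bb_ratio", 6.1, 0,
    "LC-OCD humic substances / building blocks ratio from ARIX.",
    NA_character_,
    "suva_from_arix", "ARIX", "suva", 6.1, -0.7,
    "Global whole-water SUVA from ARIX (model II calibration across eight data sets).",
    "ARIX below 0.115 implies negative SUVA: out of the calibrated domain (observed ARIX range 0.15-1.1).",
    "suva_from_arix_isolates", "ARIX", "suva", 4.5, 0,
    "SUVA from ARIX in DOM extracts, through-origin fit.",
    NA_character_,
    "aromaticity_from_suva", "SUVA", "percent_aromaticity", 6.52, 3.63,
    "Percent aromatic carbon from SUVA (13C-NMR calibration on XAD-8 isolates).",
    NA_character_,
    "aromaticity_from_arix", "ARIX", "percent_aromaticity", 29.3, 3.63,
    "Percent aromatic carbon directly from ARIX, composing the isolate SUVA calibration into the 13C-NMR relation.",
    "Assumes isolate fluorescence trends carry over to bulk DOM."
  )
}

#' Evaluate a published aromaticity proxy equation
#'
#' Applies `slope * x + intercept` for the chosen registry entry (see
#' [published_models()]). A negative predicted SUVA from the global
#' whole-water calibration (ARIX below 0.115) is returned as-is with a
#' warning rather than clamped: negative output signals input outside the
#' calibrated ARIX domain, which the caller should see.
#'
#' @param model_id Registry id.
#' @param x Non-negative index value(s) of the model's input kind.
#' @return Numeric vector of predictions, in the model's output units.
#' @export
apply_published_model <- function(model_id, x) {
  reg <- published_models()
  row <- reg[reg$model_id == model_id, ]
  if (nrow(row) == 0) {
    stop("unknown model_id '", model_id, "'; see published_models()",
         call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop("index values must be non-negative", call. = FALSE)
  }
  out <- row$slope * x + row$intercept
  if (row$output == "suva" && any(out < 0, na.rm = TRUE)) {
    warning("negative predicted SUVA: input below the calibrated ",
            row$input, " domain", call. = FALSE)
  }
  out
}

#' Invert a published proxy equation
#'
#' Solves `y = slope * x + intercept` for the index value `x`.
#'
#' @param model_id Registry id (see [published_models()]).
#' @param y Output value(s) in the model's output units.
#' @return Index value(s).
#' @export
invert_published_model <- function(model_id, y) {
  reg <- published_models()
  row <- reg[reg$model_id == model_id, ]
  if (nrow(row) == 0) {
    stop("unknown model_id '", model_id, "'", call. = FALSE)
  }
  (y - row$intercept) / row$slope
}

#' Calibrate SUVA against a fluorescence index in a sample table
#'
#' Local calibration `SUVA = slope * index + intercept` by model I
#' (optionally robust) or model II geometric regression, delegating to
#' [ols_fit()] / [gm_fit()]. Rows missing either variable are dropped and
#' listed in the result's `dropped` field.
#'
#' @param table Sample table with a `suva` column and the named index column.
#' @param index Name of the index column (default `"arix"`).
#' @param method `"modelI"` or `"modelII"` (geometric).
#' @param robust Model I only: bisquare IRLS automatic outlier downweighting.
#' @param intercept Model I only: fit an intercept or force through origin.
#' @return A `dom_fit` with extra fields `index`, `response`, `dropped`.
#' @export
fit_suva_model <- function(table, index = "arix",
                           method = c("modelI", "modelII"),
                           robust = FALSE, intercept = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), "suva" %in% names(table),
            index %in% names(table))
  ok <- is.finite(table[[index]]) & is.finite(table$suva)
  if (sum(ok) < 3) {
    stop("need at least 3 records with both suva and ", index, call. = FALSE)
  }
  x <- table[[index]][ok]
  y <- table$suva[ok]
  fit <- if (method == "modelII") {
    if (robust) warning("robust option applies to model I only; ignored",
                        call. = FALSE)
    gm_fit(x, y)
  } else {
    ols_fit(x, y, intercept = intercept, robust = robust)
  }
  fit$index <- index
  fit$response <- "suva"
  fit$dropped <- if ("sample_id" %in% names(table)) {
    table$sample_id[!ok]
  } else {
    which(!ok)
  }
  fit
}
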