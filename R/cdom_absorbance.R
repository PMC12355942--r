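#' Interpolated decadic absorbance at a wavelength
#'
#' Linear interpolation within the measured grid; exact on grid points; no
#' extrapolation.
#'
#' @param spec An [new_abs_spectrum()] object.
#' @param lambda Wavelength(s), nm.
#' @return Decadic absorbance (dimensionless cell reading).
#' @export
absorbance_at <- function(spec, lambda) {
  stopifnot(inherits(spec, "abs_spectrum"))
  rng <- range(spec$wavelength)
  if (any(lambda < rng[1] | lambda > rng[2])) {
    stop("wavelength outside measured range (", rng[1], "-", rng[2],
         " nm); no extrapolation", call. = FALSE)
  }
  stats::approx(spec$wavelength, spec$absorbance, xout = lambda,
                method = "linear")$y
}

#' Decadic absorption coefficient per meter
#'
#' The per-meter decadic coefficient `A(lambda) / path_length_m`, the
#' convention in which A254 enters SUVA (a 1 cm cell reading multiplied
#' by 100).
#'
#' @inheritParams absorbance_at
#' @return Decadic absorption coefficient, 1/m.
#' @export
absorbance_per_meter <- function(spec, lambda) {
  absorbance_at(spec, lambda) / spec$path_length
}

#' Napierian absorption coefficient
#'
#' `a(lambda) = ln(10) * A(lambda) / path_length_m`, the natural-log
#' convention used by CDOM literature models (e.g. a275, a350 in 1/m).
#' `ln(10)` is used at full precision.
#'
#' @inheritParams absorbance_at
#' @return Napierian absorption coefficient, 1/m.
#' @export
napierian_coefficient <- function(spec, lambda) {
  log(10) * absorbance_at(spec, lambda) / spec$path_length
}

#' CDOM spectral slope over a wavelength band
#'
#' Fits the exponential decay `a(lambda) = a(lambda_ref) * exp(S *
#' (lambda_ref - lambda))` of the CDOM absorption coefficient over a band,
#' returning the slope `S` in 1/nm (positive for normal CDOM decay; multiply
#' by 1000 for the 1/um convention). Two methods are provided because the two
#' literature lineages that consume S275-295 differ in how they estimate it:
#'
#' * `loglinear`: ordinary least squares of `ln a(lambda)` on `lambda`;
#'   `S = -slope`. Requires strictly positive absorbance inside the band.
#' * `nonlinear`: unweighted nonlinear least squares of the exponential
#'   itself, with the reference wavelength fixed at the band's upper edge
#'   and the log-linear estimate as the starting point. If the optimizer
#'   fails, the error carries the log-linear fallback fit.
#'
#' Both methods agree exactly on noise-free exponential spectra and are
#' invariant to amplitude scaling of the spectrum.
#'
#' @param spec An [new_abs_spectrum()] object.
#' @param band Length-2 numeric, band edges in nm (e.g. `c(275, 295)`).
#' @param method `"loglinear"` or `"nonlinear"`.
#' @return A `slope_fit` object with fields `S` (1/nm), `band`, `method`,
#'   `lambda_ref`, `a_ref` (Napierian 1/m at `lambda_ref`), `r_squared`,
#'   `rmse`, `n`.
#' @export
spectral_slope <- function(spec, band = c(275, 295),
                           method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "abs_spectrum"), length(band) == 2, band[1] < band[2])
  sel <- spec$wavelength >= band[1] & spec$wavelength <= band[2]
  lam <- spec$wavelength[sel]
  a <- log(10) * spec$absorbance[sel] / spec$path_length
  if (length(lam) < 5) {
    stop("need >= 5 grid points inside the band ", band[1], "-", band[2],
         " nm", call. = FALSE)
  }
  if (any(a <= 0)) {
    stop("non-positive absorbance inside the band; slope undefined",
         call. = FALSE)
  }
  lambda_ref <- band[2]

  loglin <- function() {
    f <- stats::lm(log(a) ~ lam)
    s <- -unname(stats::coef(f)[2])
    a_ref <- exp(unname(stats::coef(f)[1]) - s * lambda_ref)
    list(S = s, a_ref = a_ref)
  }
  ll <- loglin()

  if (method == "loglinear") {
    S <- ll$S; a_ref <- ll$a_ref
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(a ~ a_ref * exp(S * (lambda_ref - lam)),
                        start = list(a_ref = ll$a_ref, S = ll$S),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        cond <- simpleError(paste0("nonlinear slope fit failed to converge: ",
                                   conditionMessage(e)))
        cond$loglinear_fallback <- ll
        stop(cond)
      })
    cf <- stats::coef(fit)
    S <- unname(cf[["S"]]); a_ref <- unname(cf[["a_ref"]])
  }
  pred <- a_ref * exp(S * (lambda_ref - lam))
  resid <- a - pred
  tss <- sum((a - mean(a))^2)
  structure(
    list(S = S, band = band, method = method, lambda_ref = lambda_ref,
         a_ref = a_ref,
         r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
         rmse = sqrt(mean(resid^2)), n = length(lam)),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> S%g-%g = %.6f 1/nm (%.2f 1/um), method %s, n = %d\n",
              x$band[1], x$band[2], x$S, x$S * 1000, x$method, x$n))
  invisible(x)
}

#' SUVA254: specific UV absorbance
#'
#' Decadic absorbance at 254 nm per meter divided by the DOC concentration:
#' `SUVA = A254 / DOC`, in m^2/gC (equivalent to L/(mg C)/m). Natural waters
#' typically span SUVA of roughly 1-6 m^2/gC.
#'
#' @param a254 Decadic absorbance at 254 nm, 1/m. Non-negative.
#' @param doc DOC concentration, mg/L (= g/m^3). Strictly positive.
#' @return SUVA, m^2/gC. Vectorized.
#' @export
compute_suva <- function(a254, doc) {
  if (any(!is.na(doc) & doc <= 0)) stop("DOC must be positive", call. = FALSE)
  if (any(!is.na(a254) & a254 < 0)) stop("A254 must be non-negative", call. = FALSE)
  a254 / doc
}

#' Summarize absorbance-derived quantities for one spectrum
#'
#' Convenience wrapper returning, as one tibble row, the standard CDOM
#' quantities consumed by the DOC prediction models: A254 (decadic, 1/m),
#' Napierian a275 and a350 (1/m), and the spectral slopes S275-295 (both
#' methods) and S380-443 (1/nm). Slopes whose band is not covered by the
#' spectrum are `NA`.
#'
#' @param spec An [new_abs_spectrum()] object.
#' @return A one-row tibble.
#' @export
cdom_summary <- function(spec) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  tibble::tibble(
    sample_id = spec$sample_id,
    a254 = safe(absorbance_per_meter(spec, 254)),
    a275 = safe(napierian_coefficient(spec, 275)),
    a350 = safe(napierian_coefficient(spec, 350)),
    s275_295 = safe(spectral_slope(spec, c(275, 295), "loglinear")$S),
    s275_295_nonlinear = safe(spectral_slope(spec, c(275, 295), "nonlinear")$S),
    s380_443 = safe(spectral_slope(spec, c(380, 443), "loglinear")$S)
  )
}
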