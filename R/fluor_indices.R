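#' Interpolated fluorescence intensity at arbitrary wavelengths
#'
#' Bilinear lookup into an EEM: linear interpolation in excitation between
#' the two adjacent excitation slices, then linear interpolation in emission
#' along the resulting profile. Requests exactly on the grid return the
#' stored value. Extrapolation beyond either grid is refused: index
#' wavelengths are chosen to sit in clean spectral regions, and fabricating
#' off-grid data would defeat that.
#'
#' @param eem An [new_eem()] object.
#' @param ex Excitation wavelength (nm), scalar.
#' @param em Emission wavelength(s) (nm).
#' @return Numeric vector of intensities, one per `em`.
#' @export
eem_intensity <- function(eem, ex, em) {
  stopifnot(inherits(eem, "eem"), length(ex) == 1)
  profile <- emission_profile(eem, ex)
  if (any(em < eem$em[1] | em > eem$em[length(eem$em)])) {
    stop("emission wavelength outside EEM grid (", eem$em[1], "-",
         eem$em[length(eem$em)], " nm); no extrapolation", call. = FALSE)
  }
  stats::approx(eem$em, profile, xout = em, method = "linear")$y
}

# Emission profile at one excitation wavelength (linear between slices).
emission_profile <- function(eem, ex) {
  g <- eem$ex
  if (ex < g[1] || ex > g[length(g)]) {
    stop("excitation wavelength ", ex, " outside EEM grid (", g[1], "-",
         g[length(g)], " nm); no extrapolation", call. = FALSE)
  }
  hi <- findInterval(ex, g, rightmost.closed = TRUE)
  if (g[hi] == ex) return(eem$intensities[, hi])
  w <- (ex - g[hi]) / (g[hi + 1] - g[hi])
  (1 - w) * eem$intensities[, hi] + w * eem$intensities[, hi + 1]
}

#' ARIX: fluorescence aromaticity index
#'
#' Ratio of emission intensities at 520 and 390 nm under excitation at
#' 320 nm. The two wavelengths sit on the shoulders of the long-emission
#' (humic-like, peak above 500 nm) and short-emission (peak near 400 nm)
#' fluorophore groups whose balance tracks DOM aromaticity, while avoiding
#' the water Raman line. The index is dimensionless and invariant to any
#' positive rescaling of the EEM.
#'
#' At very low fluorescence signal the ratio degenerates to noise; a
#' detection floor on the 390 nm denominator can be set to flag such values
#' as undefined (`NA`). The floor defaults to 0 (disabled).
#'
#' @param eem An [new_eem()] object covering excitation 320 nm and emission
#'   390-520 nm.
#' @param floor Detection floor for the denominator intensity, in the EEM's
#'   intensity units.
#' @return ARIX (dimensionless), or `NA` if the denominator is at or below
#'   `floor` or non-positive.
#' @export
arix <- function(eem, floor = 0) {
  num <- eem_intensity(eem, 320, 520)
  den <- eem_intensity(eem, 320, 390)
  if (!is.finite(den) || den <= floor || den <= 0) return(NA_real_)
  num / den
}

#' Classic fluorescence indices plus ARIX
#'
#' Computes, from one EEM, the dimensionless indices commonly used to
#' characterize DOM fluorescence, each returned `NA` (never silently zero)
#' if its wavelengths fall outside the grids:
#'
#' * `arix` — emission 520/390 nm at excitation 320 nm ([arix()]).
#' * `fi` — fluorescence index: emission 470/520 nm at excitation 370 nm.
#' * `hix` — humification index: sum of emission 435-480 nm divided by the
#'   sum over 300-345 plus 435-480 nm, at excitation 254 nm; bounded in
#'   \[0, 1\].
#' * `hix1999` — the older humification index with the 300-345 nm band alone
#'   in the denominator, so `hix = hix1999 / (1 + hix1999)`.
#' * `bix` — biological index: emission 430/380 nm at excitation 310 nm.
#' * `freshness` — beta/alpha ratio: emission at 380 nm over the maximum
#'   emission in 420-435 nm, at excitation 310 nm.
#'
#' Band sums and the freshness maximum are evaluated on a 1 nm linearly
#' interpolated emission grid with inclusive endpoints; the constant grid
#' factor cancels in every ratio.
#'
#' @param eem An [new_eem()] object.
#' @param arix_floor Detection floor passed to [arix()].
#' @return A one-row tibble with columns `sample_id`, `arix`, `fi`, `hix`,
#'   `hix1999`, `bix`, `freshness`.
#' @export
fluor_indices <- function(eem, arix_floor = 0) {
  stopifnot(inherits(eem, "eem"))
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  band <- function(ex, lo, hi) {
    sum(eem_intensity(eem, ex, seq(lo, hi, by = 1)))
  }
  h_num <- safe(band(254, 435, 480))
  h_den <- safe(band(254, 300, 345))
  tibble::tibble(
    sample_id = eem$sample_id,
    arix = safe(arix(eem, floor = arix_floor)),
    fi = safe(eem_intensity(eem, 370, 470) / eem_intensity(eem, 370, 520)),
    hix = ratio_or_na(h_num, h_den + h_num),
    hix1999 = ratio_or_na(h_num, h_den),
    bix = safe(eem_intensity(eem, 310, 430) / eem_intensity(eem, 310, 380)),
    freshness = safe(eem_intensity(eem, 310, 380) /
                       max(eem_intensity(eem, 310, seq(420, 435, by = 1))))
  )
}

ratio_or_na <- function(num, den) {
  if (!is.finite(num) || !is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' PARIX: PARAFAC-based aromaticity index
#'
#' Ratio of the maximum fluorescence (Fmax) scores of two PARAFAC
#' components: a long-emission humic-like component (peak emission above
#' 500 nm) over a short-emission component (peak emission near 400 nm).
#' A zero long-component score gives PARIX = 0, the zero-aromaticity limit;
#' a zero or missing short-component score is an error.
#'
#' @param scores Named numeric vector (or single-row data frame) of
#'   non-negative Fmax scores by component id.
#' @param long,short Component ids designating the long- and short-emission
#'   components.
#' @return PARIX (dimensionless).
#' @export
parix <- function(scores, long, short) {
  if (is.data.frame(scores)) {
    stopifnot(nrow(scores) == 1)
    scores <- unlist(scores[intersect(names(scores), c(long, short))])
  }
  if (!all(c(long, short) %in% names(scores))) {
    stop("designated components not present in scores: need ", long,
         " and ", short, call. = FALSE)
  }
  s_long <- as.numeric(scores[[long]])
  s_short <- as.numeric(scores[[short]])
  if (is.na(s_long) || is.na(s_short) || s_long < 0 || s_short < 0) {
    stop("Fmax scores must be non-negative and present", call. = FALSE)
  }
  if (s_short == 0) {
    stop("short-emission component score is zero; PARIX undefined",
         call. = FALSE)
  }
  s_long / s_short
}

#' Mask and interpolate scatter regions of an EEM
#'
#' Optional pre-processing for EEMs whose upstream correction did not remove
#' scatter: excises a band of `width` nm around first- and second-order
#' Rayleigh scatter (em = ex and em = 2 ex) and the water Raman line
#' (Raman shift `raman_shift` 1/cm; ex 320 nm maps to em near 359 nm), then
#' fills the gaps by linear interpolation along each emission scan. Off by
#' default in every index function: inputs are normally fully corrected.
#'
#' @param eem An [new_eem()] object.
#' @param width Half-width of the excision band, nm.
#' @param raman_shift Water Raman shift, 1/cm.
#' @return A new `eem` with masked cells replaced by interpolated values.
#' @export
mask_scatter <- function(eem, width = 10, raman_shift = 3500) {
  stopifnot(inherits(eem, "eem"))
  m <- eem$intensities
  for (j in seq_along(eem$ex)) {
    ex <- eem$ex[j]
    centers <- c(ex, 2 * ex, 1e7 / (1e7 / ex - raman_shift))
    bad <- rep(FALSE, length(eem$em))
    for (c0 in centers) bad <- bad | abs(eem$em - c0) <= width
    if (any(bad) && sum(!bad) >= 2) {
      m[bad, j] <- stats::approx(eem$em[!bad], m[!bad, j],
                                 xout = eem$em[bad], rule = 2)$y
    }
  }
  out <- eem
  out$intensities <- m
  out
}
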