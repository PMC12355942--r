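# Synthetic optical data with closed-form ground truth. Separable
# Gaussian-profile fluorophores and exponential CDOM absorbance are test
# fixtures, not physical models: true index values and slopes have closed
# forms, which is what makes every estimator in the package verifiable
# without real data.

#' Define a separable Gaussian fluorophore component
#'
#' Intensity at `(ex, em)` is
#' `amplitude * exp(-(ex - ex_mean)^2 / (2 ex_sd^2)) *
#'  exp(-(em - em_mean)^2 / (2 em_sd^2))`.
#' Real EEM shapes are not separable; these profiles exist so that true
#' index values are available in closed form to tests.
#'
#' @param amplitude Non-negative peak intensity (arbitrary units).
#' @param ex_mean,ex_sd Excitation profile mean and sd, nm (`ex_sd > 0`).
#' @param em_mean,em_sd Emission profile mean and sd, nm (`em_sd > 0`).
#' @return A one-row tibble.
#' @export
fluor_component <- function(amplitude, ex_mean, ex_sd, em_mean, em_sd) {
  stopifnot(amplitude >= 0, ex_sd > 0, em_sd > 0)
  tibble::tibble(amplitude = amplitude, ex_mean = ex_mean, ex_sd = ex_sd,
                 em_mean = em_mean, em_sd = em_sd)
}

#' Default two-component fluorophore palette
#'
#' A long-emission humic-like component (emission peak 510 nm, above 500)
#' and a short-emission component (peak 400 nm), both excited around
#' 310-320 nm. Sweeping the ratio of their amplitudes between roughly 0.14
#' and 1.24 sweeps ARIX over about 0.15-1.1, the range observed in natural
#' whole-water samples; the default amplitudes give a mid-range ARIX.
#'
#' @param long_amplitude,short_amplitude Component amplitudes.
#' @return A two-row component tibble (rows named by role via the `role`
#'   column).
#' @export
default_components <- function(long_amplitude = 0.6, short_amplitude = 1) {
  dplyr::bind_cols(
    tibble::tibble(role = c("long", "short")),
    dplyr::bind_rows(
      fluor_component(long_amplitude, ex_mean = 320, ex_sd = 60,
                      em_mean = 510, em_sd = 60),
      fluor_component(short_amplitude, ex_mean = 310, ex_sd = 50,
                      em_mean = 400, em_sd = 40)
    )
  )
}

component_intensity <- function(components, ex, em) {
  # closed form; ex and em may be vectors of equal length (or one scalar)
  total <- 0
  for (i in seq_len(nrow(components))) {
    c_ <- components[i, ]
    total <- total +
      c_$amplitude *
      exp(-(ex - c_$ex_mean)^2 / (2 * c_$ex_sd^2)) *
      exp(-(em - c_$em_mean)^2 / (2 * c_$em_sd^2))
  }
  total
}

#' Closed-form true ARIX of a component mixture
#'
#' Evaluates the analytic intensity of the mixture at (ex 320, em 520) and
#' (ex 320, em 390) and returns their ratio — the value [arix()] must
#' recover from a noise-free synthetic EEM.
#'
#' @param components A component tibble ([fluor_component()] rows).
#' @return True ARIX.
#' @export
true_arix <- function(components) {
  component_intensity(components, 320, 520) /
    component_intensity(components, 320, 390)
}

#' Generate a synthetic EEM with known truth
#'
#' Sums the separable Gaussian component profiles over the grids and adds
#' i.i.d. Gaussian noise. Grids must cover excitation through 254-370 nm
#' and emission 300-520 nm at 5 nm spacing or finer for all indices to be
#' computable; a warning lists indices the grids cannot support.
#'
#' @param components Component tibble; default [default_components()].
#' @param ex_grid,em_grid Wavelength grids, nm.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param seed Random seed (required when `noise_sd > 0`).
#' @param sample_id Sample identifier.
#' @return List with `eem` and `truth` (components, closed-form `arix`,
#'   `noise_sd`, `seed`).
#' @export
synth_eem <- function(components = default_components(),
                      ex_grid = seq(250, 500, by = 5),
                      em_grid = seq(300, 600, by = 2),
                      noise_sd = 0, seed = NULL,
                      sample_id = "synthetic") {
  stopifnot(is.data.frame(components), nrow(components) >= 1)
  if (max(diff(ex_grid)) > 5 || max(diff(em_grid)) > 5) {
    warning("grid spacing above 5 nm; interpolated indices will be coarse",
            call. = FALSE)
  }
  uncomputable <- character()
  if (min(ex_grid) > 254 || max(ex_grid) < 254) {
    uncomputable <- c(uncomputable, "hix", "hix1999")
  }
  if (max(ex_grid) < 370) uncomputable <- c(uncomputable, "fi")
  if (min(em_grid) > 300 || max(em_grid) < 520) {
    uncomputable <- c(uncomputable, "hix", "fi", "arix")
  }
  if (length(uncomputable) > 0) {
    warning("grids too short for: ", paste(unique(uncomputable),
                                           collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, length(em_grid), length(ex_grid))
  for (i in seq_len(nrow(components))) {
    c_ <- components[i, ]
    m <- m + c_$amplitude *
      outer(exp(-(em_grid - c_$em_mean)^2 / (2 * c_$em_sd^2)),
            exp(-(ex_grid - c_$ex_mean)^2 / (2 * c_$ex_sd^2)))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + stats::rnorm(length(m), 0, noise_sd)
  }
  list(
    eem = new_eem(m, em_grid, ex_grid, sample_id = sample_id),
    truth = list(components = components, arix = true_arix(components),
                 noise_sd = noise_sd, seed = seed)
  )
}

#' Generate a synthetic exponential CDOM absorbance spectrum
#'
#' Decadic cell absorbance
#' `A(lambda) = a_ref * exp(S * (lambda_ref - lambda)) * path_length / ln 10`
#' so that the Napierian coefficient at `lambda_ref` is exactly `a_ref` and
#' [spectral_slope()] recovers `S` exactly at zero noise. Noise is relative
#' multiplicative Gaussian.
#'
#' @param a_ref Napierian absorption coefficient at `lambda_ref`, 1/m (> 0).
#' @param s Spectral slope, 1/nm (> 0).
#' @param grid Wavelength grid, nm.
#' @param path_length Cell path length, meters.
#' @param lambda_ref Reference wavelength, nm.
#' @param noise_sd Relative noise sd (e.g. 0.01 for 1%).
#' @param seed Random seed.
#' @param sample_id Sample identifier.
#' @return An [new_abs_spectrum()] object.
#' @export
synth_absorbance <- function(a_ref, s, grid = seq(250, 500, by = 1),
                             path_length = 0.01, lambda_ref = 350,
                             noise_sd = 0, seed = NULL,
                             sample_id = "synthetic") {
  stopifnot(a_ref > 0, s > 0)
  a_nap <- a_ref * exp(s * (lambda_ref - grid))
  cell <- a_nap * path_length / log(10)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cell <- cell * (1 + stats::rnorm(length(cell), 0, noise_sd))
  }
  new_abs_spectrum(grid, cell, path_length, sample_id)
}

#' Generate a synthetic DOC sample table from the interaction model
#'
#' Generates samples in the forward direction of the interaction model: a
#' per-sample aromaticity proxy `P` (uniform over `proxy_range`, matching
#' where most natural whole-water ARIX values fall) and colored DOC `cdoc`
#' (log-normal), then `DOC = b0 + cdoc`,
#' `A254 = cdoc / (b1 + b2 * P)` and `SUVA = A254 / DOC`, after which the
#' [noise_model()] (if any) perturbs DOC, the proxy and A254 and SUVA is
#' recomputed. Under the default regime `b1 + b2 * P` stays within
#' \[0.3, 0.7\], which keeps SUVA inside the 1-6 m^2/gC range typical of
#' natural waters; a truth spec with `b1 + b2 * P <= 0` anywhere in the
#' proxy support is rejected before generation.
#'
#' @param n Number of samples.
#' @param b0 Uncolored DOC, mg/L.
#' @param b1 Absorbance coefficient, g/m^2 (positive).
#' @param b2 Interaction coefficient (negative in the natural regime).
#' @param proxy `"arix"` or `"inv_s275"` — which column the proxy is written
#'   to (`inv_s275` stores `s275_295 = 1/(1000 P)` in 1/nm).
#' @param proxy_range Uniform support of the proxy.
#' @param cdoc_meanlog,cdoc_sdlog Log-normal parameters of colored DOC.
#' @param noise Optional [noise_model()] applied to doc, proxy, a254.
#' @param seed Random seed.
#' @return List with `table` (tibble: `sample_id`, `doc`, `a254`, `suva`,
#'   proxy column) and `truth` (b0, b1, b2, proxy kind, per-sample true
#'   values, noise, seed).
#' @export
synth_dataset <- function(n, b0 = 0.8, b1 = 0.8, b2 = -0.5,
                          proxy = c("arix", "inv_s275"),
                          proxy_range = c(0.2, 1.0),
                          cdoc_meanlog = log(5), cdoc_sdlog = 0.5,
                          noise = NULL, seed = NULL) {
  proxy <- match.arg(proxy)
  brackets <- b1 + b2 * proxy_range
  if (any(brackets <= 0)) {
    stop("truth spec implies non-positive A254: b1 + b2 * P <= 0 inside ",
         "the proxy support [", proxy_range[1], ", ", proxy_range[2], "]",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n, proxy_range[1], proxy_range[2])
  cdoc <- stats::rlnorm(n, cdoc_meanlog, cdoc_sdlog)
  doc <- b0 + cdoc
  a254 <- cdoc / (b1 + b2 * p)

  tab <- tibble::tibble(sample_id = sprintf("synth%04d", seq_len(n)),
                        doc = doc, a254 = a254)
  p_obs <- p
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    tab$doc <- abs(perturb(doc, noise$doc))  # reflect at 0; DOC must stay > 0
    p_obs <- perturb(p, noise$arix)
    tab$a254 <- perturb(a254, noise$a254)
  }
  tab$suva <- tab$a254 / tab$doc
  if (proxy == "arix") {
    tab$arix <- p_obs
  } else {
    tab$s275_295 <- 1 / (1000 * p_obs)
  }
  list(
    table = tab,
    truth = list(b0 = b0, b1 = b1, b2 = b2, proxy = proxy, p = p,
                 cdoc = cdoc, doc = doc, a254 = a254,
                 noise = noise, seed = seed)
  )
}

#' Generate a synthetic SUVA-vs-ARIX calibration table
#'
#' Samples ARIX uniformly over its natural whole-water range and builds
#' SUVA on the reference line `SUVA = slope * ARIX + intercept` plus
#' absolute Gaussian noise on SUVA and ARIX; DOC is log-normal and
#' `A254 = SUVA * DOC`. This is the regime for exercising the SUVA
#' calibration fits ([fit_suva_model()]) and the measurement-error
#' simulation. Defaults reproduce the global whole-water calibration line
#' (slope 6.07, intercept -0.67) with scatter at the magnitude reported
#' across DOC analysers (about 0.3 m^2/gC).
#'
#' @param n Number of samples.
#' @param slope,intercept True calibration line.
#' @param arix_range Uniform ARIX support.
#' @param suva_noise_sd Absolute Gaussian sd added to SUVA.
#' @param arix_noise_sd Absolute Gaussian sd added to observed ARIX.
#' @param doc_meanlog,doc_sdlog Log-normal DOC parameters.
#' @param seed Random seed.
#' @return List with `table` and `truth`.
#' @export
synth_suva_table <- function(n, slope = 6.07, intercept = -0.67,
                             arix_range = c(0.15, 1.1),
                             suva_noise_sd = 0.3, arix_noise_sd = 0.03,
                             doc_meanlog = log(5), doc_sdlog = 0.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arix_true <- stats::runif(n, arix_range[1], arix_range[2])
  suva_true <- slope * arix_true + intercept
  if (any(suva_true < 0)) {
    stop("true line implies negative SUVA inside the ARIX support",
         call. = FALSE)
  }
  suva <- suva_true + stats::rnorm(n, 0, suva_noise_sd)
  arix <- arix_true + stats::rnorm(n, 0, arix_noise_sd)
  doc <- stats::rlnorm(n, doc_meanlog, doc_sdlog)
  list(
    table = tibble::tibble(sample_id = sprintf("cal%04d", seq_len(n)),
                           doc = doc, arix = arix, suva = suva,
                           a254 = suva * doc),
    truth = list(slope = slope, intercept = intercept,
                 arix_true = arix_true, suva_true = suva_true, seed = seed)
  )
}
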