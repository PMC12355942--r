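test_that("bilinear EEM lookup is exact on grid points and linear between", {
  em <- c(380, 390, 400); ex <- c(300, 320, 340)
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  e <- new_eem(m, em, ex)
  expect_equal(eem_intensity(e, 320, 390), m[2, 2])
  # midway in emission between stored values 4 and 5
  expect_equal(eem_intensity(e, 320, 385), (m[1, 2] + m[2, 2]) / 2)
  # midway in excitation
  expect_equal(eem_intensity(e, 310, 390), (m[2, 1] + m[2, 2]) / 2)
  expect_error(eem_intensity(e, 290, 390), "no extrapolation")
  expect_error(eem_intensity(e, 320, 300), "no extrapolation")
})

test_that("ARIX matches the closed-form value of a two-Gaussian mixture", {
  comps <- example_components()
  # independent closed-form oracle evaluated at the index wavelengths
  gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
  num <- 2 * gauss(520, 510, 60) + 1 * gauss(520, 400, 40)
  den <- 2 * gauss(390, 510, 60) + 1 * gauss(390, 400, 40)
  expect_equal(num / den, 1.5998, tolerance = 1e-4)

  se <- synth_eem(comps, ex_grid = seq(250, 500, 5),
                  em_grid = seq(300, 600, 2))
  expect_equal(arix(se$eem), num / den, tolerance = 1e-12)
  expect_equal(true_arix(comps), num / den, tolerance = 1e-12)
})

test_that("uniform EEMs give the degenerate index values exactly", {
  idx <- fluor_indices(uniform_eem())
  expect_equal(idx$arix, 1)
  expect_equal(idx$fi, 1)
  expect_equal(idx$bix, 1)
  expect_equal(idx$freshness, 1)
  expect_equal(idx$hix, 0.5)
  expect_equal(idx$hix1999, 1)
})

test_that("linear emission spectrum reproduces hand-computed index values", {
  idx <- fluor_indices(linear_emission_eem())
  # band sums are arithmetic series: 46 terms centered on the band midpoint
  expect_equal(idx$hix1999, (46 * 457.5) / (46 * 322.5), tolerance = 1e-12)
  expect_equal(idx$hix, 21.045 / 35.880, tolerance = 1e-12)
  expect_equal(idx$fi, 470 / 520, tolerance = 1e-12)
  expect_equal(idx$bix, 430 / 380, tolerance = 1e-12)
  expect_equal(idx$freshness, 380 / 435, tolerance = 1e-12)
})

test_that("every index is invariant to positive rescaling of the EEM", {
  set.seed(11)
  for (rep in 1:5) {
    em <- seq(300, 600, 2); ex <- seq(250, 500, 5)
    base <- matrix(stats::runif(length(em) * length(ex), 0.5, 2),
                   length(em), length(ex))
    e1 <- new_eem(base, em, ex)
    c_ <- stats::runif(1, 0.01, 100)
    e2 <- new_eem(base * c_, em, ex)
    expect_equal(fluor_indices(e1)[-1], fluor_indices(e2)[-1],
                 tolerance = 1e-10)
  }
})

test_that("HIX equals HIX1999/(1 + HIX1999) on random EEMs", {
  set.seed(12)
  for (rep in 1:10) {
    em <- seq(300, 600, 2); ex <- seq(250, 500, 5)
    m <- matrix(stats::runif(length(em) * length(ex), 0.1, 3),
                length(em), length(ex))
    idx <- fluor_indices(new_eem(m, em, ex))
    expect_equal(idx$hix, idx$hix1999 / (1 + idx$hix1999), tolerance = 1e-12)
  }
})

test_that("adding long-emission fluorescence strictly increases ARIX", {
  comps <- example_components()
  base <- true_arix(comps)
  for (amp in c(0.1, 0.5, 2)) {
    more <- dplyr::bind_rows(
      comps, fluor_component(amp, 320, 60, em_mean = 530, em_sd = 50))
    expect_gt(true_arix(more), base)
  }
})

test_that("1-nm band-sum HIX agrees with a trapezoid-integral oracle", {
  set.seed(13)
  trapz <- function(e, lo, hi) {
    x <- sort(unique(c(lo, e$em[e$em > lo & e$em < hi], hi)))
    y <- eem_intensity(e, 254, x)
    sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  }
  for (spacing in c(1, 2)) {
    em <- seq(300, 600, spacing); ex <- seq(250, 500, 5)
    # smooth random EEM: sum of random Gaussian bumps
    comps <- dplyr::bind_rows(lapply(1:4, function(i) {
      fluor_component(stats::runif(1, 0.5, 2), stats::runif(1, 280, 400),
                      stats::runif(1, 30, 80), stats::runif(1, 350, 550),
                      stats::runif(1, 30, 80))
    }))
    e <- synth_eem(comps, ex_grid = ex, em_grid = em)$eem
    num <- trapz(e, 435, 480)
    den <- trapz(e, 300, 345)
    idx <- fluor_indices(e)
    expect_equal(idx$hix1999, num / den, tolerance = 0.01)
    expect_equal(idx$hix, num / (num + den), tolerance = 0.01)
  }
})

test_that("indices whose wavelengths fall off-grid are NA, others computed", {
  # excitation grid starting above 254 nm: HIX is uncomputable, ARIX fine
  em <- seq(300, 600, 2); ex <- seq(300, 500, 5)
  e <- new_eem(matrix(1, length(em), length(ex)), em, ex)
  idx <- fluor_indices(e)
  expect_true(is.na(idx$hix))
  expect_true(is.na(idx$hix1999))
  expect_equal(idx$arix, 1)
  expect_equal(idx$bix, 1)
})

test_that("the ARIX detection floor flags low-signal denominators", {
  e <- uniform_eem(value = 1e-4)
  expect_equal(arix(e), 1)
  expect_true(is.na(arix(e, floor = 1e-3)))
})

test_that("PARIX is the long/short Fmax ratio with the documented edge cases", {
  expect_equal(parix(c(C4 = 0.5, C3 = 0.5), long = "C4", short = "C3"), 1)
  expect_equal(parix(c(C4 = 0, C3 = 1), long = "C4", short = "C3"), 0)
  expect_error(parix(c(C4 = 1, C3 = 0), long = "C4", short = "C3"), "zero")
  expect_error(parix(c(C4 = 1), long = "C4", short = "C3"), "not present")
  s <- c(C4 = 0.4, C3 = 0.8)
  expect_equal(parix(s * 7, "C4", "C3"), parix(s, "C4", "C3"))
})

test_that("scatter masking interpolates across the excised ridges", {
  em <- seq(300, 600, 2); ex <- seq(250, 500, 5)
  e <- synth_eem(example_components(), ex_grid = ex, em_grid = em)$eem
  spiked <- e
  # plant a Raman-like spike at ex 320, em within the excision band
  j <- which(e$ex == 320)
  i <- which.min(abs(e$em - 359))
  spiked$intensities[i, j] <- spiked$intensities[i, j] + 100
  clean <- mask_scatter(spiked)
  expect_lt(abs(clean$intensities[i, j] - e$intensities[i, j]), 0.05)
  # untouched regions are preserved
  k <- which.min(abs(e$em - 500))
  expect_equal(clean$intensities[k, j], spiked$intensities[k, j])
})
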