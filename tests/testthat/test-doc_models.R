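test_that("interaction-model coefficients are recovered exactly without noise", {
  tab <- exact_arint_table(b0 = 1, b1 = 0.5, b2 = -0.2)
  f <- fit_doc_model(tab, "arint", proxy = "arix")
  expect_equal(f$b0, 1, tolerance = 1e-9)
  expect_equal(f$b1, 0.5, tolerance = 1e-9)
  expect_equal(f$b2, -0.2, tolerance = 1e-9)
  expect_equal(f$rmse, 0, tolerance = 1e-9)
  expect_equal(f$k, 3L)
})

test_that("a constant proxy makes the interaction design rank deficient", {
  tab <- exact_arint_table()
  tab$arix <- 0.5
  tab$doc <- 1 + 0.4 * tab$a254
  expect_error(fit_doc_model(tab, "arint"), "rank-deficient")
})

test_that("interaction model with the 1/S proxy uses the 1/um convention", {
  n <- 40
  p <- seq(0.3, 0.9, length.out = n)        # proxy = 1/S with S in 1/um
  a254 <- seq(3, 25, length.out = n)
  tab <- tibble::tibble(doc = 2 + 0.6 * a254 - 0.3 * a254 * p,
                        a254 = a254,
                        s275_295 = 1 / (1000 * p))  # stored in 1/nm
  f <- fit_doc_model(tab, "arint", proxy = "inv_s275")
  expect_equal(f$b0, 2, tolerance = 1e-9)
  expect_equal(f$b1, 0.6, tolerance = 1e-9)
  expect_equal(f$b2, -0.3, tolerance = 1e-9)
  expect_equal(f$b2_unit, "Mg/m")
})

test_that("base model equals the interaction model when b2 is truly zero", {
  ds <- synth_dataset(60, b2 = 0, proxy_range = c(0.2, 1), seed = 41)
  base <- fit_doc_model(ds$table, "base")
  expect_equal(base$b0, ds$truth$b0, tolerance = 1e-9)
  expect_equal(base$b1, ds$truth$b1, tolerance = 1e-9)
  arint <- fit_doc_model(ds$table, "arint")
  expect_equal(arint$b2, 0, tolerance = 1e-8)
  expect_equal(arint$b1, base$b1, tolerance = 1e-6)
})

test_that("Pan-Arctic fit recovers its generating (C, M) pair", {
  n <- 30
  s_um <- seq(15, 25, length.out = n)       # typical S275-295 in 1/um
  a350 <- seq(0.5, 6, length.out = n)
  C <- 0.6; M <- 0.05
  tab <- tibble::tibble(doc = a350 * 10^(C + M * s_um), a350 = a350,
                        s275_295 = s_um / 1000)
  f <- fit_doc_model(tab, "pan_arctic")
  expect_equal(f$C, C, tolerance = 1e-6)
  expect_equal(f$M, M, tolerance = 1e-6)
  # hand-computed point prediction
  pred <- predict_doc(f, tibble::tibble(a350 = 2, s275_295 = 0.020))
  expect_equal(pred, 2 * 10^(0.6 + 0.05 * 20), tolerance = 1e-6)
})

test_that("UV-slope local fit recovers the global constants exactly", {
  n <- 30
  a275 <- seq(2, 40, length.out = n)
  s275 <- seq(0.015, 0.03, length.out = n)
  s380 <- seq(0.014, 0.02, length.out = n)
  x <- a275 * (s275 + 0.078 * s380 - 0.0084)
  doc_um <- 1507 * x + 32.2
  tab <- tibble::tibble(doc = doc_um * 12.011 / 1000, a275 = a275,
                        s275_295 = s275, s380_443 = s380)
  f <- fit_doc_model(tab, "doc_ls")
  expect_equal(f$phi, 1507, tolerance = 1e-6)
  expect_equal(f$doc_cor, 32.2, tolerance = 1e-6)
  # pinned to the global constants it reproduces the fixed preset exactly
  expect_equal(predict_doc(f, tab), predict_doc(doc_uv_model(), tab),
               tolerance = 1e-9)
})

test_that("fixed UV-slope prediction matches hand arithmetic", {
  tab <- tibble::tibble(a275 = 10, s275_295 = 0.0200, s380_443 = 0.0180)
  pred_um <- 1507 * 10 * (0.0200 + 0.078 * 0.0180 - 0.0084) + 32.2
  expect_equal(pred_um, 228.17, tolerance = 1e-3)
  expect_equal(predict_doc(doc_uv_model(), tab), pred_um * 12.011 / 1000)
  expect_equal(predict_doc(doc_uv_model(), tab), 2.741, tolerance = 1e-3)
})

test_that("interaction predictions and the A254 inversion round-trip", {
  fit <- structure(list(model = "arint", proxy = "arix",
                        b0 = 1, b1 = 0.5, b2 = -0.2, k = 3L),
                   class = c("arint_fit", "doc_model_fit"))
  tab <- tibble::tibble(a254 = 10, arix = 1)
  expect_equal(predict_doc(fit, tab), 1 + 5 - 2)
  # pure uncolored DOC absorbs nothing
  expect_equal(invert_a254(fit, doc = 1, p = 0.5), 0)
  # algebraic round trip on a grid of inputs
  a254 <- seq(1, 30, length.out = 20)
  p <- seq(0.2, 1, length.out = 20)
  doc <- predict_doc(fit, tibble::tibble(a254 = a254, arix = p))
  expect_equal(invert_a254(fit, doc, p), a254, tolerance = 1e-10)
  # proxy-kind mismatch is refused
  expect_error(predict_doc(fit, tibble::tibble(a254 = 1, suva = 3)),
               "missing required columns: arix")
})

test_that("diagnostics expose colored DOC, absorptivity and the interaction ratio", {
  fit <- structure(list(model = "arint", proxy = "arix",
                        b0 = 1, b1 = 0.5, b2 = -0.2, k = 3L),
                   class = c("arint_fit", "doc_model_fit"))
  d <- arint_diagnostics(fit, tibble::tibble(doc = 5, arix = 1))
  expect_equal(d$cdoc, 4)
  expect_equal(d$interaction_ratio, -0.4)
  expect_equal(d$epsilon, 1 / 0.3)
  # no-interaction limit: ratio 0, epsilon constant
  fit0 <- fit; fit0$b2 <- 0
  d0 <- arint_diagnostics(fit0, tibble::tibble(doc = c(3, 8),
                                               arix = c(0.2, 0.9)))
  expect_equal(d0$interaction_ratio, c(0, 0))
  expect_equal(d0$epsilon, rep(2, 2))
  # epsilon is flagged undefined outside the physical regime
  fitn <- fit; fitn$b2 <- -1
  dn <- arint_diagnostics(fitn, tibble::tibble(doc = 3, arix = 0.9))
  expect_true(is.na(dn$epsilon))
})

test_that("the generator regime reproduces its interaction-ratio range", {
  ds <- synth_dataset(300, b0 = 0.8, b1 = 0.8, b2 = -0.5,
                      proxy_range = c(0.16, 1.0), seed = 42)
  f <- fit_doc_model(ds$table, "arint")
  d <- arint_diagnostics(f, ds$table)
  rng <- attr(d, "ratio_range")
  # truth range is b2/b1 * [0.16, 1.0] = [-0.625, -0.1]; the sampled proxy
  # only approaches the support endpoints
  expect_equal(rng[1], -0.625, tolerance = 0.01)
  expect_equal(rng[2], -0.1, tolerance = 0.01)
  # natural regime: positive absorbance slope, negative interaction
  expect_gt(f$b1, 0)
  expect_lt(f$b2, 0)
})

test_that("information criteria match the closed-form hand evaluation", {
  resid <- rep(1, 10)  # RSS = 10
  ic <- info_criteria(resid, k = 2)
  expect_equal(ic$logL, -(10 / 2) * (log(2 * pi) + log(1) + 1),
               tolerance = 1e-10)
  expect_equal(ic$logL, -14.18939, tolerance = 1e-5)
  expect_equal(ic$aic, 32.3788, tolerance = 1e-4)
  expect_equal(ic$aicc, 34.0931, tolerance = 1e-4)
  expect_equal(ic$bic, 32.9840, tolerance = 1e-4)
  expect_equal(ic$caic, 34.9840, tolerance = 1e-4)
})

test_that("information criteria penalize parameters and converge for large n", {
  resid <- stats::rnorm(50)
  ic0 <- info_criteria(resid, k = 0)
  ic2 <- info_criteria(resid, k = 2)
  for (crit in c("aic", "aicc", "bic", "caic")) {
    expect_lt(ic0[[crit]], ic2[[crit]])
  }
  expect_gte(ic2$aicc, ic2$aic)
  # AICc converges to AIC as n grows at fixed k
  big <- info_criteria(stats::rnorm(1e6), k = 3)
  expect_equal(big$aicc, big$aic, tolerance = 1e-8)
  expect_error(info_criteria(rep(0, 10), k = 2), "perfect fit")
  # the optional residual-variance count shifts all penalties by one
  ic3 <- info_criteria(resid, k = 2, count_sigma = TRUE)
  expect_equal(ic3$k, 3)
})

test_that("model comparison prefers the interaction model when it is true", {
  ds <- synth_dataset(150, noise = noise_model(
    doc = list(mode = "relative", sd = 0.03),
    arix = list(mode = "absolute", sd = 0),
    a254 = list(mode = "relative", sd = 0)), seed = 43)
  cmp <- compare_doc_models(ds$table, proxies = "arix")
  expect_equal(cmp$preferred, "arint_arix")
  expect_true(all(cmp$criterion_winners == "arint_arix"))
  # the interaction model beats base RMSE substantially here
  s <- cmp$summary
  expect_lt(s$pct_rmse_change[s$model == "arint_arix"], -20)
})

test_that("model comparison prefers the base model when there is no interaction", {
  set.seed(44)
  n <- 100
  a254 <- stats::runif(n, 2, 30)
  tab <- tibble::tibble(
    doc = 1 + 0.5 * a254 + stats::rnorm(n, 0, 0.5),
    a254 = a254,
    arix = stats::runif(n, 0.2, 1))  # pure noise proxy
  cmp <- compare_doc_models(tab, proxies = "arix")
  s <- cmp$summary
  # the BIC/CAIC penalty beats the spurious third coefficient
  expect_equal(s$model[which.min(s$bic)], "base")
  expect_equal(s$model[which.min(s$caic)], "base")
})

test_that("comparison shares one complete-case sample across models", {
  ds <- synth_dataset(80, seed = 45)
  tab <- ds$table
  tab$a254[3] <- NA
  cmp <- compare_doc_models(tab, proxies = "arix")
  expect_equal(cmp$n, 79)
  expect_true(all(cmp$summary$model %in% c("base", "arint_arix")))
  expect_error(compare_doc_models(tibble::tibble(doc = 1:5)), "fewer than 2")
})

test_that("coefficient recovery is calibrated under relative DOC noise", {
  # 20 replicates here keep the unit suite fast; the full 100-seed version
  # runs in the acceptance suite
  hits <- 0L
  for (i in 1:20) {
    ds <- synth_dataset(200, noise = noise_model(
      doc = list(mode = "relative", sd = 0.05),
      arix = list(mode = "absolute", sd = 0),
      a254 = list(mode = "relative", sd = 0)), seed = 4600 + i)
    f <- fit_doc_model(ds$table, "arint")
    ok <- abs(f$b0 - ds$truth$b0) <= 3 * f$b0_se &&
      abs(f$b1 - ds$truth$b1) <= 3 * f$b1_se &&
      abs(f$b2 - ds$truth$b2) <= 3 * f$b2_se
    hits <- hits + ok
  }
  expect_gte(hits, 19)
})
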