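test_that("wide EEM CSV parses, round-trips exactly, and matches long layout", {
  ex <- c(300, 320, 340); em <- c(380, 390, 400)
  vals <- matrix(1:9, 3, 3)
  wide <- file.path(tempdir(), "eem_wide.csv")
  writeLines(c(
    paste(c("em\\ex", ex), collapse = ","),
    vapply(1:3, function(i) paste(c(em[i], vals[i, ]), collapse = ","),
           character(1))), wide)
  e <- read_eem(wide, layout = "wide")
  expect_equal(e$ex, ex)
  expect_equal(e$em, em)
  expect_equal(unname(e$intensities), vals * 1.0)

  long <- file.path(tempdir(), "eem_long.csv")
  d <- expand.grid(em = em, ex = ex)
  d$intensity <- as.vector(vals)
  utils::write.csv(d[c("ex", "em", "intensity")], long, row.names = FALSE)
  e2 <- read_eem(long, layout = "long")
  expect_equal(unname(e2$intensities), unname(e$intensities))
  expect_equal(e2$ex, e$ex)

  # write/read round trip is exact
  rt <- file.path(tempdir(), "eem_rt.csv")
  write_eem(e, rt)
  e3 <- read_eem(rt, layout = "wide")
  expect_identical(e3$intensities, e$intensities)
  expect_identical(e3$em, e$em)

  # transpose flag swaps the orientation
  et <- read_eem(wide, layout = "wide", transpose = TRUE)
  expect_equal(et$ex, em)
  expect_equal(unname(et$intensities), unname(t(e$intensities)))
})

test_that("malformed EEM files are rejected with clear errors", {
  long <- file.path(tempdir(), "eem_bad.csv")
  d <- expand.grid(em = c(380, 390, 400), ex = c(300, 320, 340))
  d$intensity <- 1:9
  utils::write.csv(d[-4, c("ex", "em", "intensity")], long, row.names = FALSE)
  expect_error(read_eem(long, layout = "long"), "non-rectilinear")

  utils::write.csv(rbind(d, d[1, ])[c("ex", "em", "intensity")], long,
                   row.names = FALSE)
  expect_error(read_eem(long, layout = "long"), "duplicate")

  wide <- file.path(tempdir(), "eem_nonnum.csv")
  writeLines(c("em\\ex,300,320", "380,1,x", "390,2,3"), wide)
  expect_error(read_eem(wide), "non-numeric")

  expect_error(read_eem(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("absorbance files parse with path length from argument or header", {
  f <- file.path(tempdir(), "abs.csv")
  writeLines(c("350,0.01", "254,0.06"), f)
  sp <- read_absorbance(f, path_length = 0.01)
  expect_s3_class(sp, "abs_spectrum")
  expect_equal(sp$wavelength, c(254, 350))  # sorted
  expect_equal(sp$absorbance, c(0.06, 0.01))
  expect_equal(sp$path_length, 0.01)

  writeLines(c("# path_length_cm=5", "254,0.06", "350,0.01"), f)
  expect_equal(read_absorbance(f)$path_length, 0.05)
  # explicit argument beats the header
  expect_equal(read_absorbance(f, path_length = 0.1)$path_length, 0.1)

  expect_error(read_absorbance(f, path_length = 0), "positive")
  empty <- file.path(tempdir(), "empty.csv")
  writeLines(character(), empty)
  expect_error(read_absorbance(empty, path_length = 0.01), "empty")
})

test_that("sample tables validate ids, units and SUVA consistency", {
  f <- file.path(tempdir(), "tab.csv")
  utils::write.csv(data.frame(sample_id = c("a", "b"), doc = c(2, 4),
                              a254 = c(6, 6)), f, row.names = FALSE)
  tab <- read_sample_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(compute_suva(tab$a254, tab$doc), c(3, 1.5))

  utils::write.csv(data.frame(sample_id = c("a", "b"), doc = c(0, 4)), f,
                   row.names = FALSE)
  expect_error(read_sample_table(f), "positive")

  utils::write.csv(data.frame(sample_id = c("a", "a"), doc = c(2, 4)), f,
                   row.names = FALSE)
  expect_error(read_sample_table(f), "duplicate")

  # stored SUVA disagreeing with A254/DOC is flagged, not repaired
  utils::write.csv(data.frame(sample_id = c("a", "b"), doc = c(2, 2),
                              a254 = c(6, 6), suva = c(3, 4)), f,
                   row.names = FALSE)
  tab <- read_sample_table(f)
  expect_equal(tab$suva_inconsistent, c(FALSE, TRUE))
  expect_equal(tab$suva, c(3, 4))
})

test_that("qc_filter applies the standard exclusions and logs every removal", {
  tab <- tibble::tibble(
    sample_id = c("ok", "hi_suva", "hi_doc", "estuary"),
    dataset_label = c("river", "river", "river", "estuarine"),
    suva = c(3.0, 7.5, 3.0, 2.0),
    doc = c(10, 10, 125, 10))
  out <- qc_filter(tab, exclude_groups = "estuarine")
  expect_equal(out$sample_id, "ok")
  log <- exclusion_log(out)
  expect_equal(nrow(tab), nrow(out) + nrow(log))
  expect_setequal(log$rule, c("max_suva", "max_doc", "group_exclusion"))
  expect_equal(log$rule[log$sample_id == "hi_suva"], "max_suva")
  # boundary values are kept: the rules are strict inequalities
  keep <- qc_filter(tibble::tibble(sample_id = "edge", suva = 7, doc = 120))
  expect_equal(nrow(keep), 1)
  # original table untouched
  expect_equal(nrow(tab), 4)
})

test_that("qc_filter is idempotent and composes its log across calls", {
  tab <- tibble::tibble(sample_id = letters[1:5],
                        suva = c(2, 8, 3, 9, 4), doc = c(5, 5, 130, 5, 5))
  once <- qc_filter(tab)
  twice <- qc_filter(once)
  expect_equal(twice$sample_id, once$sample_id)
  expect_equal(nrow(exclusion_log(twice)), nrow(exclusion_log(once)))
  expect_equal(nrow(tab), nrow(once) + nrow(exclusion_log(once)))
})
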