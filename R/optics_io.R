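#' Construct a fluorescence excitation-emission matrix (EEM)
#'
#' An `eem` stores spectrally corrected fluorescence intensities on a
#' rectilinear wavelength grid, with emission wavelengths along rows and
#' excitation wavelengths along columns (Aqualog-style orientation).
#' Intensities are in arbitrary (instrument) units; small negative values from
#' blank subtraction are allowed. Scatter handling and inner-filter correction
#' are assumed to have been applied upstream.
#'
#' @param intensities Numeric matrix, `length(em)` rows by `length(ex)` columns.
#' @param em,ex Strictly increasing emission / excitation wavelengths (nm).
#' @param sample_id Sample identifier.
#' @param corrected Logical flag asserting instrument correction and scatter
#'   handling were already applied.
#' @return An object of class `eem`.
#' @export
new_eem <- function(intensities, em, ex, sample_id = NA_character_,
                    corrected = TRUE) {
  intensities <- as.matrix(intensities)
  em <- as.numeric(em)
  ex <- as.numeric(ex)
  if (nrow(intensities) != length(em) || ncol(intensities) != length(ex)) {
    stop("intensity matrix must be length(em) x length(ex)", call. = FALSE)
  }
  check_grid(em, "emission")
  check_grid(ex, "excitation")
  if (!all(is.finite(intensities))) {
    stop("EEM intensities must all be finite", call. = FALSE)
  }
  dimnames(intensities) <- list(format_nm(em), format_nm(ex))
  structure(
    list(sample_id = as.character(sample_id), em = em, ex = ex,
         intensities = intensities, corrected = isTRUE(corrected)),
    class = "eem"
  )
}

check_grid <- function(x, what) {
  if (length(x) < 2 || anyNA(x) || any(x <= 0)) {
    stop(what, " grid must be positive and of length >= 2", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop(what, " grid must be strictly increasing", call. = FALSE)
  }
  invisible(x)
}

format_nm <- function(x) formatC(x, format = "fg", digits = 10)

#' @export
print.eem <- function(x, ...) {
  cat("<eem> ", x$sample_id, "\n",
      "  emission:   ", length(x$em), " wavelengths, ",
      min(x$em), "-", max(x$em), " nm\n",
      "  excitation: ", length(x$ex), " wavelengths, ",
      min(x$ex), "-", max(x$ex), " nm\n", sep = "")
  invisible(x)
}

#' @method as_tibble eem
#' @export
as_tibble.eem <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    em = rep(x$em, times = length(x$ex)),
    ex = rep(x$ex, each = length(x$em)),
    intensity = as.vector(x$intensities)
  )
}

#' Read an EEM from a CSV file
#'
#' Two layouts are supported. `wide`: first row holds excitation wavelengths,
#' first column emission wavelengths, cell (1,1) blank or `em\ex`. `long`:
#' three columns `ex`, `em`, `intensity` covering every grid combination
#' exactly once. Grids are sorted on read; duplicate wavelength pairs and
#' missing combinations (a non-rectilinear grid) are errors.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param transpose For wide files written with excitation rows and emission
#'   columns, set `TRUE` to transpose on read.
#' @param sample_id Defaults to the file name without extension.
#' @return An [new_eem()] object.
#' @export
read_eem <- function(path, layout = c("wide", "long"), transpose = FALSE,
                     sample_id = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))

  if (layout == "wide") {
    raw <- utils::read.csv(path, header = FALSE, check.names = FALSE,
                           colClasses = "character")
    if (nrow(raw) < 2 || ncol(raw) < 2) stop("wide EEM file too small", call. = FALSE)
    ex <- parse_num(unlist(raw[1, -1]), "excitation header")
    em <- parse_num(raw[-1, 1], "emission column")
    m <- apply(as.matrix(raw[-1, -1, drop = FALSE]), c(1, 2),
               function(v) parse_num(v, "intensity cell"))
    if (isTRUE(transpose)) {
      m <- t(m); tmp <- ex; ex <- em; em <- tmp
    }
    o_em <- order(em); o_ex <- order(ex)
    return(new_eem(m[o_em, o_ex, drop = FALSE], em[o_em], ex[o_ex], sample_id))
  }

  d <- utils::read.csv(path, header = TRUE)
  need <- c("ex", "em", "intensity")
  if (!all(need %in% names(d))) {
    stop("long EEM file must have columns ex, em, intensity", call. = FALSE)
  }
  d$ex <- parse_num(d$ex, "ex"); d$em <- parse_num(d$em, "em")
  d$intensity <- parse_num(d$intensity, "intensity")
  if (anyDuplicated(d[c("ex", "em")])) {
    stop("duplicate (ex, em) pairs in long EEM file", call. = FALSE)
  }
  ex <- sort(unique(d$ex)); em <- sort(unique(d$em))
  if (nrow(d) != length(ex) * length(em)) {
    stop("non-rectilinear grid: long EEM file is missing (ex, em) combinations",
         call. = FALSE)
  }
  m <- matrix(NA_real_, length(em), length(ex))
  m[cbind(match(d$em, em), match(d$ex, ex))] <- d$intensity
  new_eem(m, em, ex, sample_id)
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) stop("non-numeric value in ", what, call. = FALSE)
  out
}

#' Write an EEM as a wide CSV
#'
#' Counterpart of [read_eem()]'s wide layout; a read/write round trip
#' reproduces the parsed values exactly.
#'
#' @param eem An `eem` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(eem, path) {
  stopifnot(inherits(eem, "eem"))
  header <- paste(c("em\\ex", format_num(eem$ex)), collapse = ",")
  rows <- vapply(seq_along(eem$em), function(i) {
    paste(c(format_num(eem$em[i]), format_num(eem$intensities[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

format_num <- function(x) {
  # full precision so round trips are bit-identical
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE), character(1))
}

#' Construct a CDOM absorbance spectrum
#'
#' Stores decadic absorbance (the dimensionless cell reading) versus
#' wavelength, together with the optical path length in meters. Conversions to
#' per-meter decadic or Napierian absorption coefficients are done by
#' [absorbance_per_meter()] and [napierian_coefficient()].
#'
#' @param wavelength Strictly increasing wavelengths (nm).
#' @param absorbance Decadic absorbance per cell (dimensionless).
#' @param path_length Path length in meters (e.g. 0.01 for a 1 cm cell).
#' @param sample_id Sample identifier.
#' @return An object of class `abs_spectrum`.
#' @export
new_abs_spectrum <- function(wavelength, absorbance, path_length,
                             sample_id = NA_character_) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("wavelength and absorbance must have equal length", call. = FALSE)
  }
  check_grid(wavelength, "wavelength")
  if (!all(is.finite(absorbance))) stop("absorbance must be finite", call. = FALSE)
  if (!is.numeric(path_length) || length(path_length) != 1 ||
      !is.finite(path_length) || path_length <= 0) {
    stop("path_length must be a single positive number (meters)", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), wavelength = wavelength,
         absorbance = absorbance, path_length = path_length),
    class = "abs_spectrum"
  )
}

#' @export
print.abs_spectrum <- function(x, ...) {
  cat("<abs_spectrum> ", x$sample_id, ": ", length(x$wavelength),
      " wavelengths, ", min(x$wavelength), "-", max(x$wavelength),
      " nm, path ", x$path_length * 100, " cm\n", sep = "")
  invisible(x)
}

#' @method as_tibble abs_spectrum
#' @export
as_tibble.abs_spectrum <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, wavelength = x$wavelength,
                 absorbance = x$absorbance, path_length = x$path_length)
}

#' Read an absorbance spectrum from a two-column CSV
#'
#' The file holds `wavelength, absorbance` rows (decadic cell readings).
#' Comment lines starting with `#` before the data may declare the path
#' length as `path_length_cm=5` or `path_length_m=0.05`; an explicit
#' `path_length` argument wins over the header.
#'
#' @param path CSV file path.
#' @param path_length Path length in meters; optional if the file header
#'   declares it.
#' @param sample_id Defaults to the file name without extension.
#' @return An [new_abs_spectrum()] object sorted by wavelength.
#' @export
read_absorbance <- function(path, path_length = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty absorbance file: ", path, call. = FALSE)

  is_hdr <- grepl("^\\s*#", lines) |
    grepl("^\\s*path_length_(cm|m)\\s*=", lines)
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (is.null(path_length)) {
    m <- regmatches(header,
                    regexec("path_length_(cm|m)\\s*=\\s*([0-9.eE+-]+)", header))
    m <- Filter(function(g) length(g) == 3, m)
    if (length(m) > 0) {
      unit <- m[[1]][2]
      val <- as.numeric(m[[1]][3])
      path_length <- if (unit == "cm") val / 100 else val
    }
  }
  if (is.null(path_length)) {
    stop("path length neither supplied nor declared in file header",
         call. = FALSE)
  }
  # drop an optional column-name line
  if (length(body) > 0 && grepl("[A-Za-z]", strsplit(body[1], ",")[[1]][1])) {
    body <- body[-1]
  }
  if (length(body) == 0) stop("no data rows in absorbance file", call. = FALSE)
  d <- utils::read.csv(text = paste(body, collapse = "\n"), header = FALSE)
  wl <- parse_num(d[[1]], "wavelength")
  ab <- parse_num(d[[2]], "absorbance")
  o <- order(wl)
  new_abs_spectrum(wl[o], ab[o], path_length, sample_id)
}

#' Read a per-sample table of DOC and optical measurements
#'
#' Expects a CSV with a `sample_id` column and any of the documented
#' measurement columns: `doc` (mg/L), `a254` (decadic absorbance per meter),
#' `suva` (m^2/gC), index columns (`arix`, `fi`, `hix`, ...), slopes
#' `s275_295`, `s380_443` (1/nm), Napierian coefficients `a275`, `a350`
#' (1/m), and arbitrary metadata columns (kept as-is; no unit conversion is
#' ever applied). When `doc`, `a254` and `suva` are all present, rows where
#' `suva` disagrees with `a254/doc` beyond 1e-9 relative are flagged in a
#' `suva_inconsistent` column.
#'
#' @param path CSV file path.
#' @return A tibble of samples with an empty exclusion log attached
#'   (see [exclusion_log()]).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(d)) {
    stop("sample table must have a sample_id column", call. = FALSE)
  }
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if ("doc" %in% names(d) && any(!is.na(d$doc) & d$doc <= 0)) {
    stop("DOC must be positive where present", call. = FALSE)
  }
  if ("a254" %in% names(d) && any(!is.na(d$a254) & d$a254 < 0)) {
    stop("A254 must be non-negative where present", call. = FALSE)
  }
  if (all(c("doc", "a254", "suva") %in% names(d))) {
    ok <- !is.na(d$doc) & !is.na(d$a254) & !is.na(d$suva)
    rel <- abs(d$suva[ok] - d$a254[ok] / d$doc[ok]) /
      pmax(abs(d$suva[ok]), .Machine$double.eps)
    flag <- rep(FALSE, nrow(d))
    flag[ok] <- rel > 1e-9
    d$suva_inconsistent <- flag
  }
  set_exclusion_log(tibble::as_tibble(d), empty_exclusion_log())
}

empty_exclusion_log <- function() {
  tibble::tibble(sample_id = character(), rule = character(),
                 detail = character())
}

set_exclusion_log <- function(table, log) {
  attr(table, "exclusion_log") <- log
  table
}

#' Exclusion log of a quality-filtered sample table
#'
#' Every record dropped by [qc_filter()] is appended here with the rule that
#' dropped it, so `nrow(table) == nrow(qc_filter(table)) + new log rows`.
#'
#' @param table A sample table.
#' @return A tibble with columns `sample_id`, `rule`, `detail`.
#' @export
exclusion_log <- function(table) {
  log <- attr(table, "exclusion_log")
  if (is.null(log)) empty_exclusion_log() else log
}

#' Apply quality-control exclusion rules to a sample table
#'
#' Implements the standard screening applied before regression analyses of
#' SUVA versus fluorescence indices: samples with unrealistically high SUVA
#' (default above 7 m^2/gC) or extremely high DOC (default above 120 mg/L)
#' are removed, and whole groups (e.g. estuarine samples, where low-signal
#' fluorescence makes the indices unreliable) can be excluded declaratively
#' by a label column. Removals are recorded in the exclusion log; the
#' operation is idempotent and never modifies its input.
#'
#' @param table A sample table (tibble with `sample_id`).
#' @param max_suva Maximum allowed SUVA, m^2/gC. `Inf` disables.
#' @param max_doc Maximum allowed DOC, mg/L. `Inf` disables.
#' @param exclude_groups Character vector of group labels to drop.
#' @param group_col Column holding the group labels.
#' @return The filtered tibble, with the updated [exclusion_log()] attached.
#' @export
qc_filter <- function(table, max_suva = 7, max_doc = 120,
                      exclude_groups = character(), group_col = "dataset_label") {
  stopifnot(is.data.frame(table), "sample_id" %in% names(table))
  log <- exclusion_log(table)
  drop <- rep(FALSE, nrow(table))
  note <- function(idx, rule, detail) {
    if (!any(idx)) return(invisible())
    log <<- dplyr::bind_rows(log, tibble::tibble(
      sample_id = table$sample_id[idx], rule = rule, detail = detail))
    drop <<- drop | idx
  }
  if ("suva" %in% names(table)) {
    note(!drop & !is.na(table$suva) & table$suva > max_suva,
         "max_suva", paste0("SUVA > ", max_suva, " m2/gC"))
  }
  if ("doc" %in% names(table)) {
    note(!drop & !is.na(table$doc) & table$doc > max_doc,
         "max_doc", paste0("DOC > ", max_doc, " mg/L"))
  }
  if (length(exclude_groups) > 0 && group_col %in% names(table)) {
    note(!drop & !is.na(table[[group_col]]) &
           table[[group_col]] %in% exclude_groups,
         "group_exclusion",
         paste0(group_col, " in {", paste(exclude_groups, collapse = ", "), "}"))
  }
  set_exclusion_log(tibble::as_tibble(table[!drop, , drop = FALSE]), log)
}
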