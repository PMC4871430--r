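#' Cohort survivorship (lx) container
#'
#' A cohort life-table survivorship column: strictly increasing integer ages
#' with the number (relative to `radix`) of the cohort still alive at each
#' exact age.  `lx` must be non-increasing and start at `radix` (after
#' truncation-and-renormalization, `lx` equals `radix` at the truncation
#' age).
#'
#' @param ages Strictly increasing ages in years.
#' @param lx Survivor count/proportion at each age, scaled to `radix`.
#' @param radix Scale of the `lx` column (e.g. 100000).
#' @param cohort_label Free-text description of the cohort.
#' @param truncation_age Age at which the curve was renormalized, or `NULL`.
#' @return An object of class `cohort_survival`.
#' @export
cohort_survival <- function(ages, lx, radix = lx[1],
                            cohort_label = "cohort", truncation_age = NULL) {
  ages <- as.numeric(ages); lx <- as.numeric(lx)
  if (length(ages) != length(lx) || length(ages) < 2L)
    stop("'ages' and 'lx' must be equal-length vectors (>= 2 ages)",
         call. = FALSE)
  if (any(diff(ages) <= 0))
    stop("'ages' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(lx)) || any(lx < 0))
    stop("'lx' must be finite and non-negative", call. = FALSE)
  if (any(diff(lx) > 1e-9 * max(lx)))
    stop("'lx' must be non-increasing in age", call. = FALSE)
  if (abs(lx[1] - radix) > 1e-6 * radix)
    stop("lx at the first age must equal the radix", call. = FALSE)
  structure(list(ages = ages, lx = lx, radix = radix,
                 cohort_label = cohort_label,
                 truncation_age = truncation_age),
            class = "cohort_survival")
}

#' @rdname cohort_survival
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.cohort_survival <- function(x, ...) {
  cat(sprintf("Cohort survivorship: %s\n", x$cohort_label))
  cat(sprintf("  ages %g-%g (%d points), radix %g%s\n",
              min(x$ages), max(x$ages), length(x$ages), x$radix,
              if (is.null(x$truncation_age)) ""
              else sprintf(", renormalized at age %g", x$truncation_age)))
  invisible(x)
}

#' Read a Human Mortality Database cohort lx table
#'
#' Parses the HMD cohort survivorship text dialect: any number of header
#' lines, then a column-header line containing `Year` and `Age`, then
#' whitespace-delimited rows `Year Age Female Male Total`.  The age `110+`
#' is parsed as 110 (start of the open-ended interval); a `.` entry (missing
#' value) in the requested column is rejected with its line number.  When
#' several birth cohorts are requested they are pooled age-by-age: an
#' unweighted mean of lx by default, or a weighted mean when per-cohort
#' `weights` (e.g. birth counts) are supplied.
#'
#' @param path Path to the HMD-format text file.
#' @param sex Which column to read: `"Female"`, `"Male"` or `"Total"`.
#' @param years Birth-cohort year(s) to read; `NULL` means all years present.
#' @param weights Optional numeric vector, one weight per requested year (in
#'   the same order), used for the age-wise pooled mean.
#' @param radix Radix the file's lx column is scaled to (HMD uses 100000).
#' @return A [cohort_survival()].
#' @export
read_hmd_cohort_lx <- function(path, sex = c("Female", "Male", "Total"),
                               years = NULL, weights = NULL, radix = 1e5) {
  sex <- match.arg(sex)
  lines <- readLines(path)
  hdr <- grep("\\bYear\\b.*\\bAge\\b", lines)[1]
  if (is.na(hdr))
    stop("not an HMD lx file: no 'Year ... Age ...' column header found",
         call. = FALSE)
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  sex_col <- match(sex, cols)
  if (is.na(sex_col))
    stop(sprintf("column '%s' not present in file header", sex),
         call. = FALSE)
  body_idx <- which(seq_along(lines) > hdr & trimws(lines) != "")
  if (length(body_idx) == 0L) stop("HMD file has no data rows", call. = FALSE)

  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != length(cols))
      stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                   i, length(cols), length(f)), call. = FALSE)
    if (f[sex_col] == ".")
      stop(sprintf("missing value ('.') in column %s at line %d", sex, i),
           call. = FALSE)
    age <- if (grepl("\\+$", f[cols == "Age"])) {
      as.numeric(sub("\\+$", "", f[cols == "Age"]))
    } else as.numeric(f[cols == "Age"])
    lx <- suppressWarnings(as.numeric(f[sex_col]))
    if (is.na(age) || is.na(lx))
      stop(sprintf("non-numeric entry at line %d", i), call. = FALSE)
    c(year = as.numeric(f[cols == "Year"]), age = age, lx = lx)
  })
  tab <- as.data.frame(do.call(rbind, rows))

  all_years <- sort(unique(tab$year))
  if (is.null(years)) years <- all_years
  missing_years <- setdiff(years, all_years)
  if (length(missing_years))
    stop("requested cohort year(s) absent from file: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  tab <- tab[tab$year %in% years, ]
  if (is.null(weights)) {
    weights <- rep(1, length(years))
  } else if (length(weights) != length(years) || any(weights < 0)) {
    stop("'weights' must be non-negative, one per requested year",
         call. = FALSE)
  }
  w <- setNames(weights / sum(weights), as.character(sort(years)))

  ages <- sort(unique(tab$age))
  lx <- vapply(ages, function(a) {
    sub <- tab[tab$age == a, ]
    if (nrow(sub) != length(years))
      stop(sprintf("age %g missing for some requested cohort years", a),
           call. = FALSE)
    sum(sub$lx * w[as.character(sub$year)])
  }, numeric(1))

  label <- sprintf("HMD cohort %s, %s",
                   if (length(years) == 1) years else
                     paste0(min(years), "-", max(years)), sex)
  cohort_survival(ages, lx, radix = radix, cohort_label = label)
}

#' Read and write the simple delimited cohort format
#'
#' A comma-delimited file with header `age, survivors` (comment lines
#' starting with `#` allowed).  The radix is taken as the survivor count at
#' the first age.
#'
#' @param path File path.
#' @param cohort_label Label for the returned object.
#' @return `read_cohort_csv()` a [cohort_survival()]; the writer returns the
#'   path invisibly.
#' @export
read_cohort_csv <- function(path, cohort_label = basename(path)) {
  tab <- utils::read.csv(path, comment.char = "#")
  if (nrow(tab) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  if (!all(c("age", "survivors") %in% names(tab)))
    stop("cohort CSV needs columns 'age' and 'survivors'", call. = FALSE)
  if (!is.numeric(tab$age) || !is.numeric(tab$survivors))
    stop("non-numeric cells in cohort CSV", call. = FALSE)
  cohort_survival(tab$age, tab$survivors, cohort_label = cohort_label)
}

#' @rdname read_cohort_csv
#' @param cohort A [cohort_survival()] to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_survival"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cohort: %s (radix %g)", cohort$cohort_label,
                     cohort$radix), con)
  utils::write.csv(data.frame(age = cohort$ages, survivors = cohort$lx),
                   con, row.names = FALSE)
  invisible(path)
}

#' Truncate a cohort at an entry age and renormalize
#'
#' Drops ages below `x0` and rescales so that survivorship equals the radix
#' at `x0` -- the preprocessing applied at age 10 before model fitting, where
#' the fitted model conditions on survival to the truncation age.  `x0` must
#' be one of the tabulated ages (no interpolation).  Idempotent.
#'
#' @param cohort A [cohort_survival()].
#' @param x0 Truncation age, one of `cohort$ages`.
#' @return A renormalized [cohort_survival()] with `truncation_age = x0`.
#' @export
truncate_renormalize <- function(cohort, x0) {
  stopifnot(inherits(cohort, "cohort_survival"))
  i <- match(x0, cohort$ages)
  if (is.na(i))
    stop(sprintf("truncation age %g is not a tabulated age (no interpolation)",
                 x0), call. = FALSE)
  if (cohort$lx[i] <= 0)
    stop("survivorship is zero at the truncation age", call. = FALSE)
  keep <- cohort$ages >= x0
  cohort_survival(cohort$ages[keep],
                  cohort$lx[keep] * cohort$radix / cohort$lx[i],
                  radix = cohort$radix,
                  cohort_label = cohort$cohort_label,
                  truncation_age = x0)
}

#' Convert a survivorship curve to interval death counts
#'
#' Distributes an actual cohort size over the age intervals of an lx curve:
#' `deaths[j] = round(actual_n * (lx[j] - lx[j+1]) / radix)` for closed
#' intervals, with the open-ended final interval receiving the survivors at
#' the last tabulated age.  The rounding residual (at most a few counts) is
#' assigned to the largest interval so that the counts sum to `actual_n`
#' exactly.  Supplying the true cohort size matters because standard errors
#' of the fitted parameters scale with it, not with the radix.
#'
#' @param cohort A [cohort_survival()], already truncated/renormalized if
#'   fitting conditions on an entry age.
#' @param actual_n True number of individuals the curve describes; defaults
#'   to the radix.
#' @return An [interval_deaths()] with `breaks = cohort$ages`.
#' @export
cohort_to_intervals <- function(cohort, actual_n = cohort$radix) {
  stopifnot(inherits(cohort, "cohort_survival"))
  if (length(actual_n) != 1L || !is.finite(actual_n) || actual_n <= 0)
    stop("'actual_n' must be a single positive count", call. = FALSE)
  p <- cohort$lx / cohort$radix
  p <- p / p[1]
  deaths <- round(actual_n * c(-diff(p), p[length(p)]))
  resid <- actual_n - sum(deaths)
  if (resid != 0) {
    k <- which.max(deaths)
    deaths[k] <- deaths[k] + resid
  }
  interval_deaths(cohort$ages, deaths, n_entry = actual_n)
}
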