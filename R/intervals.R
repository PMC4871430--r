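#' Death counts per age interval
#'
#' The sufficient statistic of the interval-censored multinomial likelihood:
#' an increasing grid of interval start ages (`breaks`), the death count in
#' each interval -- `deaths[j]` covers the half-open interval
#' `[breaks[j], breaks[j+1])`, with the final element covering the open-ended
#' interval `[breaks[K], Inf)` -- and the number alive at the first break
#' (`n_entry`).  Individuals censored at the simulation horizon contribute to
#' `n_entry` but to no closed interval; the likelihood treats them, together
#' with open-ended-interval deaths, as survivors past the last break.
#'
#' @param breaks Strictly increasing numeric vector of interval start ages
#'   (years); the first break is the entry/truncation age.
#' @param deaths Non-negative counts, one per interval (same length as
#'   `breaks`; the last is the open-ended interval). Non-integer values are
#'   allowed so that expected (fractional) counts can be fitted.
#' @param n_entry Number (or mass) alive at `breaks[1]`; must be at least
#'   `sum(deaths)`.
#' @return An object of class `interval_deaths`.
#' @export
interval_deaths <- function(breaks, deaths, n_entry) {
  breaks <- as.numeric(breaks)
  deaths <- as.numeric(deaths)
  if (length(breaks) < 2L)
    stop("need at least two breaks", call. = FALSE)
  if (any(diff(breaks) <= 0))
    stop("'breaks' must be strictly increasing", call. = FALSE)
  if (length(deaths) != length(breaks))
    stop("'deaths' must have one element per interval, i.e. length(breaks) ",
         "(last interval open-ended)", call. = FALSE)
  if (any(deaths < 0) || any(!is.finite(deaths)))
    stop("'deaths' must be finite and non-negative", call. = FALSE)
  if (length(n_entry) != 1L || !is.finite(n_entry) || n_entry < 0)
    stop("'n_entry' must be a single non-negative number", call. = FALSE)
  if (sum(deaths) > n_entry * (1 + 1e-8))
    stop("sum(deaths) exceeds n_entry", call. = FALSE)
  structure(list(breaks = breaks, deaths = deaths, n_entry = n_entry),
            class = "interval_deaths")
}

#' @rdname interval_deaths
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.interval_deaths <- function(x, ...) {
  cat(sprintf("Interval death counts: %d intervals on [%g, Inf), n_entry = %g\n",
              length(x$breaks), x$breaks[1], x$n_entry))
  cat(sprintf("  deaths in closed intervals: %g; open-ended: %g; surviving past last break: %g\n",
              sum(head(x$deaths, -1)), tail(x$deaths, 1),
              x$n_entry - sum(head(x$deaths, -1))))
  invisible(x)
}

#' Bin individual records into interval death counts
#'
#' Assigns each uncensored death to the half-open interval
#' `[breaks[j], breaks[j+1])` containing its age (deaths at or past the last
#' break go to the open-ended interval).  Censored records enter `n_entry`
#' only.  A death age below the first break is an error: such records should
#' have been removed by truncation.
#'
#' @param records Data frame of individual records (needs columns
#'   `age_at_death` and `censored`), as from [simulate_cohort()].
#' @param breaks Strictly increasing interval start ages.
#' @return An [interval_deaths()] object.
#' @export
records_to_intervals <- function(records, breaks) {
  if (!is.data.frame(records) ||
      !all(c("age_at_death", "censored") %in% names(records)))
    stop("'records' must have columns 'age_at_death' and 'censored'",
         call. = FALSE)
  breaks <- as.numeric(breaks)
  if (any(diff(breaks) <= 0))
    stop("'breaks' must be strictly increasing", call. = FALSE)
  ages <- records$age_at_death[!records$censored]
  if (any(ages < breaks[1]))
    stop(sprintf("%d death(s) below the first break (%g): truncation violated",
                 sum(ages < breaks[1]), breaks[1]), call. = FALSE)
  K <- length(breaks)
  idx <- findInterval(ages, breaks)      # K for the open-ended interval
  deaths <- tabulate(idx, nbins = K)
  interval_deaths(breaks, deaths, n_entry = nrow(records))
}

#' Read and write individual records and interval counts
#'
#' Plain-text interfaces: records as a comma-delimited table with columns
#' `id, pair_id, group, age_at_death, cause, censored`, interval counts as a
#' two-column `age, deaths` table (the last row is the open-ended interval;
#' `n_entry` is stored in a comment). Both carry `#`-prefixed comment lines
#' recording the seed when one is known.
#'
#' @param records,x Object to write.
#' @param path File path.
#' @return `read_records()` a data frame; `read_interval_deaths()` an
#'   [interval_deaths()]; writers return the path invisibly.
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(records, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  writeLines(paste0("# written by vitalfit ",
                    as.character(utils::packageVersion("vitalfit"))), con)
  utils::write.csv(records[, c("id", "pair_id", "group", "age_at_death",
                               "cause", "censored")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "pair_id", "group", "age_at_death", "cause", "censored")
  if (!all(need %in% names(rec)))
    stop("records file lacks required columns: ",
         paste(setdiff(need, names(rec)), collapse = ", "), call. = FALSE)
  rec$censored <- as.logical(rec$censored)
  rec
}

#' @rdname write_records
#' @param seed Optional seed to record in the file header.
#' @export
write_interval_deaths <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "interval_deaths"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  writeLines(sprintf("# n_entry: %.10g", x$n_entry), con)
  writeLines("# last row is the open-ended interval [age, Inf)", con)
  utils::write.csv(data.frame(age = x$breaks, deaths = x$deaths),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_interval_deaths <- function(path) {
  lines <- readLines(path)
  n_line <- grep("^# n_entry:", lines, value = TRUE)
  if (length(n_line) != 1L)
    stop("interval-deaths file lacks the '# n_entry:' header", call. = FALSE)
  n_entry <- as.numeric(sub("^# n_entry:", "", n_line))
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  interval_deaths(tab$age, tab$deaths, n_entry)
}
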