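#' Pairwise difference of cohort survivorship curves
#'
#' Difference in cumulative survival proportion by age between two cohorts
#' (e.g. monozygotic twins minus the general population), on the
#' intersection of their age grids (no interpolation).  Antisymmetric:
#' `survival_difference(a, b)` equals minus `survival_difference(b, a)`.
#'
#' @param a,b [cohort_survival()] objects.
#' @return Data frame with columns `age` and `diff`
#'   (`lx_a/radix_a - lx_b/radix_b`).
#' @export
survival_difference <- function(a, b) {
  stopifnot(inherits(a, "cohort_survival"), inherits(b, "cohort_survival"))
  ages <- intersect(a$ages, b$ages)
  if (length(ages) == 0L)
    stop("cohorts share no tabulated ages", call. = FALSE)
  ages <- sort(ages)
  pa <- a$lx[match(ages, a$ages)] / a$radix
  pb <- b$lx[match(ages, b$ages)] / b$radix
  data.frame(age = ages, diff = pa - pb)
}

#' Intrinsic/extrinsic decomposition of a fitted survival curve
#'
#' Evaluates the fitted intrinsic and extrinsic survival components (and
#' their product, the total curve) on an age grid, using the bias-corrected
#' parameters when available.
#'
#' @param fit A `vital_fit` (must have converged).
#' @param ages Age grid on the model clock (years since the curve's origin).
#' @param use_corrected Use `params_corrected` if present (default), else
#'   the raw estimates.
#' @return Data frame with columns `age`, `intrinsic`, `extrinsic`, `total`.
#' @export
decompose_survival <- function(fit, ages = 0:110, use_corrected = TRUE) {
  stopifnot(inherits(fit, "vital_fit"))
  if (!fit$converged)
    stop("cannot decompose an unconverged fit", call. = FALSE)
  p <- if (use_corrected && !is.null(fit$params_corrected))
    fit$params_corrected else fit$params_raw
  li <- surv_intrinsic(p, ages)
  le <- surv_extrinsic(p, ages)
  data.frame(age = ages, intrinsic = li, extrinsic = le, total = li * le)
}

#' Parameter comparison table across fitted groups
#'
#' Collects the (bias-corrected) parameter estimates of several group fits
#' into one machine-readable table with uncertainty intervals of plus/minus
#' two standard errors, the standard errors taken from the estimated
#' variance matrix of each fit.  Unconverged fits are excluded with a
#' warning.  The intervals scale with each group's entry cohort size, so
#' small-cohort groups show wide intervals; they are descriptive, not formal
#' tests.
#'
#' @param fits Named list of `vital_fit` objects (names are the group
#'   labels).
#' @return Data frame with columns `group`, `parameter`, `estimate`, `se`,
#'   `lower` (`estimate - 2 se`) and `upper` (`estimate + 2 se`).
#' @export
compare_parameters <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L || is.null(names(fits)))
    stop("'fits' must be a named list of at least two fits", call. = FALSE)
  keep <- vapply(fits, function(f) inherits(f, "vital_fit") && f$converged,
                 logical(1))
  if (any(!keep))
    warning("excluding unconverged fit(s): ",
            paste(names(fits)[!keep], collapse = ", "), call. = FALSE)
  fits <- fits[keep]
  if (length(fits) == 0L) stop("no converged fits to compare", call. = FALSE)
  rows <- lapply(names(fits), function(g) {
    f <- fits[[g]]
    p <- if (!is.null(f$params_corrected)) f$params_corrected else
      f$params_raw
    se <- if (!is.null(f$se)) f$se[names(unclass(p))] else rep(NA_real_, 4)
    data.frame(group = g, parameter = names(unclass(p)),
               estimate = as.numeric(unclass(p)), se = as.numeric(se),
               lower = as.numeric(unclass(p)) - 2 * as.numeric(se),
               upper = as.numeric(unclass(p)) + 2 * as.numeric(se),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subsample bootstrap validation of twin-cohort fits
#'
#' Refits the model to random 75% subsets of a twin cohort, resampling
#' whole twin pairs without replacement (the pair is the sampling unit), and
#' returns the distribution of the bias-corrected parameter estimates across
#' replicates -- a check that the full-sample estimates are not driven by a
#' small subset of pairs.  Each replicate is re-binned on the same age grid
#' and refitted; unconverged replicates are excluded, never imputed, and
#' counted.  The full-sample multiplicative correction factors are applied
#' to each replicate's raw estimates (re-running the simulation-based
#' calibration inside every replicate is not a desk-scale computation, and
#' the factors are locally constant across 75% subsamples of the same data).
#'
#' @param records Individual records of one twin group (must carry
#'   `pair_id`), as from [simulate_cohort()] or [simulate_twin_study()].
#' @param breaks Age grid for binning (first break = entry age).
#' @param fraction Fraction of pairs drawn per replicate, in (0, 1]
#'   (default 0.75).
#' @param B Number of replicates (default 1000; use ~50 for a fast check).
#' @param seed Integer seed.
#' @param correction_factors Named multiplicative factors
#'   (`r`, `s`, `lam`, `beta`) from the full-sample [bias_correct()] fit;
#'   `NULL` leaves replicate estimates uncorrected.
#' @param init Optional starting point for the replicate fits (the
#'   full-sample raw estimate is a good choice).
#' @return Object of class `vital_boot`: list with `estimates` (data frame,
#'   one row per successful replicate, columns `r`, `s`, `lam`, `beta`),
#'   `summary` (per-parameter median, IQR and outlier count on the boxplot
#'   1.5 IQR rule), `n_failed`, `fraction`, `B` and `seed`.
#' @export
bootstrap_validation <- function(records, breaks, fraction = 0.75, B = 1000,
                                 seed = NULL, correction_factors = NULL,
                                 init = NULL) {
  if (!is.data.frame(records) || !"pair_id" %in% names(records) ||
      anyNA(records$pair_id))
    stop("'records' must be paired twin records with a complete 'pair_id'",
         call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pairs <- unique(records$pair_id)
  n_take <- max(1L, floor(fraction * length(pairs)))
  est <- matrix(NA_real_, B, 4,
                dimnames = list(NULL, c("r", "s", "lam", "beta")))
  for (b in seq_len(B)) {
    take <- if (n_take == length(pairs)) pairs
            else sample(pairs, n_take, replace = FALSE)
    sub <- records[records$pair_id %in% take, , drop = FALSE]
    f <- tryCatch(
      fit_vitality(records_to_intervals(sub, breaks), init = init,
                   multi_start = is.null(init), compute_vcov = FALSE),
      error = function(e) NULL)
    if (!is.null(f) && f$converged) est[b, ] <- unclass(f$params_raw)
  }
  ok <- stats::complete.cases(est)
  est <- as.data.frame(est[ok, , drop = FALSE])
  if (!is.null(correction_factors)) {
    for (k in names(est)) est[[k]] <- est[[k]] * correction_factors[[k]]
  }
  summ <- do.call(rbind, lapply(names(est), function(k) {
    v <- est[[k]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(parameter = k, median = q[2], q25 = q[1], q75 = q[3],
               n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr),
               row.names = NULL)
  }))
  structure(list(estimates = est, summary = summ, n_failed = sum(!ok),
                 fraction = fraction, B = B, seed = seed,
                 corrected = !is.null(correction_factors)),
            class = "vital_boot")
}

#' @rdname bootstrap_validation
#' @param x Object to print.
#' @param ... Ignored.
#' @export
print.vital_boot <- function(x, ...) {
  cat(sprintf("Subsample bootstrap: %d/%d replicates converged (fraction %g%s)\n",
              nrow(x$estimates), x$B, x$fraction,
              if (x$corrected) ", bias-corrected" else ", raw"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Survivorship curve of simulated records
#'
#' Empirical cumulative survival of a set of individual records on an age
#' grid, as a [cohort_survival()] -- the bridge from the simulator to the
#' life-table operations.  Censored individuals count as alive at every
#' tabulated age up to the censoring horizon.
#'
#' @param records Individual records.
#' @param ages Integer age grid.
#' @param radix Radix of the returned curve.
#' @param cohort_label Label for the returned curve.
#' @return A [cohort_survival()].
#' @export
records_to_cohort <- function(records, ages = 0:110, radix = 1e5,
                              cohort_label = "simulated") {
  # censored records carry age_at_death = horizon, so they count as alive at
  # every tabulated age below it
  alive <- vapply(ages, function(a) sum(records$age_at_death > a),
                  numeric(1))
  if (alive[1] == 0) stop("no individuals alive at the first age",
                          call. = FALSE)
  cohort_survival(ages, radix * alive / alive[1], radix = radix,
                  cohort_label = cohort_label)
}
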