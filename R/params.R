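#' Two-process vitality model parameters
#'
#' Bundles the four parameters of the two-process vitality mortality model.
#' Vitality is an abstract, dimensionless survival capacity, normalized to 1
#' at the clock origin, that declines stochastically with age.  Intrinsic
#' (chronic, senescent) mortality is governed by the drift `r` and diffusion
#' `s` of the vitality process; extrinsic (acute, environmental) mortality by
#' the challenge frequency `lam` and mean challenge magnitude `beta`.
#'
#' @param r Mean rate of vitality loss, per year. Must be positive.
#' @param s Variability in the rate of vitality loss, units year^(-1/2).
#'   Must be positive.
#' @param lam Frequency of extrinsic environmental challenges, per year.
#'   Must be non-negative (`lam = 0` switches the extrinsic process off).
#' @param beta Mean magnitude of extrinsic challenges, as a fraction of
#'   initial vitality; challenge magnitudes are exponentially distributed
#'   with this mean. Must be positive.
#'
#' @return An object of class `vital_params`: a named numeric vector with
#'   elements `r`, `s`, `lam`, `beta`.
#'
#' @examples
#' vital_params(r = 0.0135, s = 0.0126, lam = 0.0449, beta = 0.3999)
#' @export
vital_params <- function(r, s, lam, beta) {
  p <- c(r = as.numeric(r)[1], s = as.numeric(s)[1],
         lam = as.numeric(lam)[1], beta = as.numeric(beta)[1])
  validate_vital_params(p)
  structure(p, class = "vital_params")
}

#' @rdname vital_params
#' @param x Object to test or print.
#' @export
is_vital_params <- function(x) inherits(x, "vital_params")

validate_vital_params <- function(p) {
  if (length(p) != 4L || !all(c("r", "s", "lam", "beta") %in% names(p)))
    stop("vitality parameters must be the named set {r, s, lam, beta}",
         call. = FALSE)
  if (any(!is.finite(p)))
    stop("vitality parameters must all be finite", call. = FALSE)
  if (p[["r"]] <= 0) stop("'r' must be > 0", call. = FALSE)
  if (p[["s"]] <= 0) stop("'s' must be > 0", call. = FALSE)
  if (p[["lam"]] < 0) stop("'lam' must be >= 0", call. = FALSE)
  if (p[["beta"]] <= 0) stop("'beta' must be > 0", call. = FALSE)
  invisible(p)
}

as_vital_params <- function(x) {
  if (is_vital_params(x)) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    if (is.null(names(x))) names(x) <- c("r", "s", "lam", "beta")
    return(vital_params(x[["r"]], x[["s"]], x[["lam"]], x[["beta"]]))
  }
  if (is.list(x)) return(vital_params(x$r, x$s, x$lam, x$beta))
  stop("cannot interpret object as vitality parameters", call. = FALSE)
}

#' @rdname vital_params
#' @param ... Ignored.
#' @export
print.vital_params <- function(x, ...) {
  cat("Two-process vitality parameters:\n")
  cat(sprintf("  r    = %-10.6g (mean rate of vitality loss, 1/yr)\n", x[["r"]]))
  cat(sprintf("  s    = %-10.6g (variability of vitality loss, yr^-1/2)\n", x[["s"]]))
  cat(sprintf("  lam  = %-10.6g (challenge frequency, 1/yr)\n", x[["lam"]]))
  cat(sprintf("  beta = %-10.6g (mean challenge magnitude)\n", x[["beta"]]))
  invisible(x)
}
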