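#' Closed-form survival functions of the two-process vitality model
#'
#' The model partitions mortality into an intrinsic process -- first passage
#' of a Wiener vitality process (initial value 1, drift `-r`, diffusion `s`)
#' to the absorbing boundary at 0 -- and an extrinsic process -- a Poisson
#' stream (rate `lam`) of environmental challenges with Exponential(mean
#' `beta`) magnitudes that kill when a challenge exceeds the deterministic
#' population vitality `1 - r x`.  Total survival is the product of the two
#' component survival curves.
#'
#' Intrinsic survival is the inverse-Gaussian first-passage form
#' \deqn{l^i(x) = \Phi\!\left(\frac{1 - r x}{s\sqrt{x}}\right) -
#'   e^{2r/s^2}\,\Phi\!\left(-\frac{1 + r x}{s\sqrt{x}}\right),}
#' with the second term evaluated as `exp(2r/s^2 + pnorm(..., log.p = TRUE))`
#' because `2r/s^2` routinely exceeds the direct range of `exp` (it is about
#' 170 for typical human-cohort fits).
#'
#' Extrinsic survival integrates the challenge hazard
#' \eqn{\mu_e(x) = \lambda e^{-(1 - r x)/\beta}} in closed form:
#' \deqn{l^e(x) = \exp\!\left(-\frac{\lambda\beta}{r} e^{-1/\beta}
#'   \left(e^{r x / \beta} - 1\right)\right).}
#' The linear-vitality approximation underlying \eqn{\mu_e} goes negative
#' past \eqn{x = 1/r}; the closed form is evaluated as written there (it
#' remains finite), which is the model actually fit to data -- the resulting
#' parameter bias is handled by [bias_correct()].
#'
#' @param params A [vital_params()] object (or coercible).
#' @param x Age in years since the clock origin (vectorized, `x >= 0`). The
#'   origin is wherever vitality is normalized to 1 -- birth, or the
#'   truncation age when fitting data renormalized there.
#'
#' @return Numeric vector of survival probabilities in `[0, 1]`, same length
#'   as `x`.  All three functions return exactly 1 at `x = 0` (analytic
#'   limit).
#'
#' @seealso [hazard_intrinsic()], [hazard_extrinsic()], [surv_conditional()]
#' @examples
#' p <- vital_params(0.0135, 0.0126, 0.0449, 0.3999)
#' x <- 0:110
#' all.equal(surv_total(p, x), surv_intrinsic(p, x) * surv_extrinsic(p, x))
#' @export
surv_intrinsic <- function(params, x) {
  params <- as_vital_params(params)
  check_age(x)
  r <- params[["r"]]; s <- params[["s"]]
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- 1
  if (any(!zero)) {
    xx <- x[!zero]
    sq <- s * sqrt(xx)
    t1 <- pnorm((1 - r * xx) / sq)
    # exp(2r/s^2) * Phi(-(1+rx)/(s sqrt x)), combined in log space
    t2 <- exp(2 * r / s^2 + pnorm(-(1 + r * xx) / sq, log.p = TRUE))
    out[!zero] <- pmin(1, pmax(0, t1 - t2))
  }
  out
}

#' @rdname surv_intrinsic
#' @export
surv_extrinsic <- function(params, x) {
  params <- as_vital_params(params)
  check_age(x)
  r <- params[["r"]]; lam <- params[["lam"]]; beta <- params[["beta"]]
  if (lam == 0) return(rep(1, length(x)))
  exp(-(lam * beta / r) * exp(-1 / beta) * expm1(r * x / beta))
}

#' @rdname surv_intrinsic
#' @export
surv_total <- function(params, x) {
  surv_intrinsic(params, x) * surv_extrinsic(params, x)
}

#' Conditional (truncated) survival
#'
#' Survival to age `x` conditional on being alive at the truncation age `x0`,
#' i.e. `surv_total(params, x) / surv_total(params, x0)`.  Supports fitting
#' cohorts renormalized at a truncation age (age 10 in the twin analyses)
#' while keeping the vitality clock anchored at `x = 0`.
#'
#' @inheritParams surv_intrinsic
#' @param x0 Truncation age (years, `0 <= x0 <= min(x)`).
#' @return Survival probabilities; exactly 1 at `x = x0`.
#' @export
surv_conditional <- function(params, x0, x) {
  if (length(x0) != 1L || !is.finite(x0) || x0 < 0)
    stop("'x0' must be a single non-negative age", call. = FALSE)
  if (any(x < x0))
    stop("ages 'x' must not be below the truncation age 'x0'", call. = FALSE)
  s0 <- surv_total(params, x0)
  if (s0 <= 0)
    stop("total survival at the truncation age is zero; cannot condition",
         call. = FALSE)
  surv_total(params, x) / s0
}

#' Hazard rates of the two mortality processes
#'
#' `hazard_intrinsic()` is the inverse-Gaussian first-passage density divided
#' by intrinsic survival; `hazard_extrinsic()` is the Strehler-Mildvan
#' challenge hazard \eqn{\mu_e(x) = \lambda e^{-(1 - r x)/\beta}}, which is
#' log-linear in age with slope \eqn{r/\beta}.
#'
#' @inheritParams surv_intrinsic
#' @param x Age in years, `x > 0` for the intrinsic hazard (`x >= 0` for the
#'   extrinsic one).
#' @return Non-negative rates per year.
#' @export
hazard_intrinsic <- function(params, x) {
  params <- as_vital_params(params)
  if (any(x <= 0)) stop("intrinsic hazard requires x > 0", call. = FALSE)
  fpt_density(params, x) / surv_intrinsic(params, x)
}

#' @rdname hazard_intrinsic
#' @export
hazard_extrinsic <- function(params, x) {
  params <- as_vital_params(params)
  check_age(x)
  lam <- params[["lam"]]; beta <- params[["beta"]]; r <- params[["r"]]
  lam * exp(-(1 - r * x) / beta)
}

# Inverse-Gaussian (Wald) first-passage-time density of the vitality process:
# f(t) = (s sqrt(2 pi t^3))^{-1} exp(-(1 - r t)^2 / (2 s^2 t))
fpt_density <- function(params, x) {
  r <- params[["r"]]; s <- params[["s"]]
  1 / (s * sqrt(2 * pi * x^3)) * exp(-(1 - r * x)^2 / (2 * s^2 * x))
}

check_age <- function(x) {
  if (length(x) == 0) stop("no ages supplied", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("ages must be finite and non-negative", call. = FALSE)
  invisible(x)
}
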