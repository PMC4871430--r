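#' Interval-censored multinomial log-likelihood
#'
#' The likelihood of interval death counts under the closed-form two-process
#' survival curve.  With `S(x)` the model survival conditioned on being alive
#' at the first break (`S(b) = surv_total(b) / surv_total(b1)`), the cell
#' probabilities are `p_j = S(b_j) - S(b_{j+1})` for the closed intervals and
#' `p_last = S(b_K)` for everything past the last break; the log-likelihood
#' is
#' \deqn{\ell = \sum_j d_j \log p_j + n_{surv} \log p_{last},}
#' where `n_surv = n_entry - sum(closed-interval deaths)` counts open-ended
#' deaths and horizon-censored individuals alike (both are known only to
#' have outlived the last break).  Cell probabilities are floored at a tiny
#' positive constant before the log so that a zero cell cannot derail an
#' optimizer's line search; invalid parameters raise an error rather than
#' returning `-Inf` so optimizers must respect the parameter domain
#' explicitly.
#'
#' @param params A [vital_params()] (or coercible named vector).
#' @param data An [interval_deaths()] object.
#' @param floor Lower bound applied to cell probabilities before taking
#'   logs.
#' @return The log-likelihood (finite scalar).
#' @export
loglik_intervals <- function(params, data, floor = 1e-300) {
  params <- as_vital_params(params)
  stopifnot(inherits(data, "interval_deaths"))
  b <- data$breaks
  K <- length(b)
  S <- surv_total(params, b)
  S <- S / S[1]
  p <- pmax(c(-diff(S), S[K]), floor)
  d <- data$deaths[-K]
  n_surv <- data$n_entry - sum(d)
  sum(d * log(p[-K])) + n_surv * log(p[K])
}
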