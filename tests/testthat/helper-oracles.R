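# Shared fixtures and independent oracles for the test suite.

# Reference parameter set used throughout (illustrative human-cohort values).
fig_params <- function() vital_params(r = 0.0135, s = 0.0126,
                                      lam = 0.0449, beta = 0.3999)

# Independent oracle: inverse-Gaussian first-passage density of a Wiener
# process started at 1 with drift -r and diffusion s, written from the
# density formula directly (no calls into the package's survival code).
oracle_fpt_density <- function(r, s) {
  function(t) exp(-(1 - r * t)^2 / (2 * s^2 * t)) / (s * sqrt(2 * pi * t^3))
}

# Oracle intrinsic survival by adaptive quadrature of the density tail.
oracle_intrinsic_survival <- function(r, s, x) {
  f <- oracle_fpt_density(r, s)
  total <- integrate(f, 0, Inf, rel.tol = 1e-10)$value   # defect-free check
  stats::integrate(f, x, Inf, rel.tol = 1e-10)$value / total
}

# Oracle extrinsic survival: exponentiate the negative of the numerically
# integrated challenge hazard lam * exp(-(1 - r t)/beta).
oracle_extrinsic_survival <- function(r, lam, beta, x) {
  h <- function(t) lam * exp(-(1 - r * t) / beta)
  exp(-integrate(h, 0, x, rel.tol = 1e-12)$value)
}

# Random valid parameter draws on realistic scales, reproducible.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vital_params(r = runif(1, 0.005, 0.05), s = runif(1, 0.005, 0.05),
                 lam = runif(1, 0, 0.2), beta = runif(1, 0.05, 1))
  })
}

# Expected (fractional) interval deaths under the closed-form model --
# noise-free data for self-consistency checks.
expectation_data <- function(params, breaks = 0:110, n_entry = 1e6) {
  S <- surv_total(params, breaks)
  K <- length(breaks)
  p <- c(-diff(S), S[K])
  interval_deaths(breaks, n_entry * p, n_entry)
}

# Text of a small synthetic HMD-style cohort lx file.
hmd_fixture_lines <- function() {
  c("Synthetic cohort survivorship (sample of the HMD lx dialect)",
    "",
    "  Year          Age         Female        Male       Total",
    unlist(lapply(1870:1872, function(yr) {
      ages <- c(0:4, "110+")
      lx_f <- c(100000, 90000 - (yr - 1870) * 1000, 85000, 80000, 76000, 10)
      lx_m <- c(100000, 88000 - (yr - 1870) * 2000, 82000, 77000, 72000, 5)
      lx_t <- round((lx_f + lx_m) / 2)
      sprintf("  %d%12s%13d%12d%12d", yr, ages, lx_f, lx_m, lx_t)
    })))
}
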