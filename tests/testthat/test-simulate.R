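test_that("simulation is reproducible and validates its configuration", {
  p <- fig_params()
  a <- simulate_cohort(p, n = 200, seed = 42)
  b <- simulate_cohort(p, n = 200, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(simulate_cohort(p, n = 1, seed = 1)), 1L)
  expect_error(simulate_cohort(p, n = 0), "positive integer")
  expect_error(simulate_cohort(p, n = 10, dt = 0.5), "dt")
  expect_error(simulate_cohort(p, n = 3, paired = TRUE), "even")
})

test_that("every individual gets exactly one cause", {
  rec <- simulate_cohort(fig_params(), n = 5000, seed = 7)
  expect_equal(sum(table(factor(rec$cause,
                                c("intrinsic", "extrinsic", "censored")))),
               5000)
  expect_identical(rec$censored, rec$cause == "censored")
  expect_true(all(rec$age_at_death > 0 & rec$age_at_death <= 120))
})

test_that("deterministic vitality decline dies intrinsically at 1/r", {
  rec <- simulate_cohort(vital_params(0.02, 1e-9, 0, 0.5), n = 50, seed = 3)
  expect_true(all(rec$cause == "intrinsic"))
  expect_true(all(abs(rec$age_at_death - 50) <= 0.05 + 1e-12))
})

test_that("overwhelming challenges kill extrinsically almost immediately", {
  rec <- simulate_cohort(vital_params(0.01, 0.01, 100, 100), n = 200,
                         seed = 4)
  expect_true(all(rec$cause == "extrinsic"))
  expect_true(all(rec$age_at_death < 1))
})

test_that("intrinsic-only mean lifespan matches the first-passage mean", {
  p <- vital_params(0.0135, 0.0126, 0, 0.3999)
  rec <- simulate_cohort(p, n = 50000, dt = 0.05, seed = 11)
  expect_true(all(rec$cause[!rec$censored] == "intrinsic"))
  # first-passage time of (1, -r, s) is inverse-Gaussian with mean 1/r and
  # variance s^2 / r^3
  mu <- 1 / p[["r"]]
  se <- sqrt(p[["s"]]^2 / p[["r"]]^3 / sum(!rec$censored))
  expect_lt(abs(mean(rec$age_at_death[!rec$censored]) - mu), 3 * se + 0.05)
})

test_that("halving the step leaves the empirical survival curve unchanged", {
  p <- fig_params()
  x <- 0:110
  emp <- function(dt, seed) {
    rec <- simulate_cohort(p, n = 40000, dt = dt, seed = seed)
    vapply(x, function(a) mean(rec$age_at_death > a), numeric(1))
  }
  d <- max(abs(emp(0.1, 21) - emp(0.05, 22)))
  expect_lt(d, 0.015)   # two-sample Monte-Carlo noise at this n
})

test_that("binning assigns deaths to half-open intervals and conserves counts", {
  rec <- data.frame(age_at_death = c(12.1, 12.9, 47.0), censored = FALSE)
  d <- records_to_intervals(rec, breaks = seq(10, 60, by = 10))
  expect_equal(d$deaths, c(2, 0, 0, 1, 0, 0))
  expect_equal(d$n_entry, 3)

  empty <- data.frame(age_at_death = numeric(), censored = logical())
  expect_equal(records_to_intervals(empty, c(0, 1, 2))$deaths, c(0, 0, 0))

  sim <- simulate_cohort(fig_params(), n = 10000, seed = 5)
  dd <- records_to_intervals(sim, 0:110)
  expect_equal(sum(dd$deaths), sum(!sim$censored))
  expect_equal(dd$n_entry, 10000)

  expect_error(records_to_intervals(rec, breaks = c(20, 30)),
               "truncation violated")
})

test_that("interval container validates its invariants", {
  expect_error(interval_deaths(c(1, 1), c(0, 0), 5), "increasing")
  expect_error(interval_deaths(c(0, 1), c(1, 2, 3), 10), "one element per")
  expect_error(interval_deaths(c(0, 1), c(-1, 0), 10), "non-negative")
  expect_error(interval_deaths(c(0, 1), c(9, 9), 10), "exceeds")
  d <- interval_deaths(c(0, 1, 2), c(1, 2, 3), 10)
  expect_output(print(d), "n_entry = 10")
})

test_that("record and interval files round-trip with seed headers", {
  rec <- simulate_cohort(fig_params(), n = 50, seed = 99,
                         group_label = "MZ-M", paired = TRUE)
  f <- tempfile(fileext = ".csv")
  write_records(rec, f)
  expect_true(any(grepl("seed: 99", readLines(f))))
  back <- read_records(f)
  expect_equal(back$age_at_death, rec$age_at_death)
  expect_equal(back$pair_id, rec$pair_id)
  expect_equal(back$censored, rec$censored)

  d <- records_to_intervals(rec, 0:110)
  g <- tempfile(fileext = ".csv")
  write_interval_deaths(d, g, seed = 99)
  d2 <- read_interval_deaths(g)
  expect_equal(d2$breaks, d$breaks)
  expect_equal(d2$deaths, d$deaths)
  expect_equal(d2$n_entry, d$n_entry)
})
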