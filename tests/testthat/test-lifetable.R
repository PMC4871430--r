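test_that("the HMD cohort lx dialect parses, selects sex and pools cohorts", {
  f <- tempfile(fileext = ".txt")
  writeLines(hmd_fixture_lines(), f)

  one <- read_hmd_cohort_lx(f, sex = "Female", years = 1870)
  expect_s3_class(one, "cohort_survival")
  expect_equal(one$ages, c(0:4, 110))
  expect_equal(one$lx[1], 100000)
  expect_equal(one$radix, 1e5)

  m <- read_hmd_cohort_lx(f, sex = "Male", years = 1871)
  expect_equal(m$lx[2], 86000)

  # unweighted pooling across cohort years, hand-computed
  pooled <- read_hmd_cohort_lx(f, sex = "Female", years = 1870:1872)
  expect_equal(pooled$lx[2], mean(c(90000, 89000, 88000)))
  # births-weighted pooling
  wtd <- read_hmd_cohort_lx(f, sex = "Female", years = 1870:1871,
                            weights = c(3, 1))
  expect_equal(wtd$lx[2], (3 * 90000 + 1 * 89000) / 4)

  expect_error(read_hmd_cohort_lx(f, sex = "Female", years = 1900), "absent")
})

test_that("malformed HMD rows and missing values are rejected with line numbers", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(hmd_fixture_lines(), "  1873   0   100000"), f)
  expect_error(read_hmd_cohort_lx(f, sex = "Total"), "line 22")

  g <- tempfile(fileext = ".txt")
  lines <- hmd_fixture_lines()
  lines[5] <- "  1870           1         .       88000       94000"
  writeLines(lines, g)
  expect_error(read_hmd_cohort_lx(g, sex = "Female"), "line 5")

  h <- tempfile(fileext = ".txt")
  writeLines(c("no header", "1870 0 1 2 3"), h)
  expect_error(read_hmd_cohort_lx(h), "column header")
})

test_that("survivorship container rejects non-monotone curves", {
  expect_error(cohort_survival(0:3, c(100, 80, 90, 40)), "non-increasing")
  expect_error(cohort_survival(c(0, 0, 1), c(100, 90, 80)), "increasing")
  expect_error(cohort_survival(0:2, c(90, 80, 70), radix = 100), "radix")
})

test_that("cohort CSV round-trips and rejects bad files", {
  co <- cohort_survival(c(10, 20, 30, 40), c(100, 75, 50, 10),
                        cohort_label = "toy")
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back$ages, co$ages)
  expect_equal(back$lx, co$lx)

  empty <- tempfile(fileext = ".csv")
  writeLines("age,survivors", empty)
  expect_error(read_cohort_csv(empty), "empty")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("age,count", "0,100"), bad)
  expect_error(read_cohort_csv(bad), "columns")
})

test_that("truncation renormalizes to the radix and is idempotent", {
  co <- cohort_survival(c(0, 10, 20, 30), c(100, 80, 60, 40), radix = 100)
  tr <- truncate_renormalize(co, 10)
  expect_equal(tr$ages, c(10, 20, 30))
  expect_equal(tr$lx, c(100, 75, 50))
  expect_equal(tr$truncation_age, 10)
  tr2 <- truncate_renormalize(tr, 10)
  expect_equal(tr2$lx, tr$lx)
  expect_error(truncate_renormalize(co, 15), "not a tabulated age")

  flat <- cohort_survival(0:3, rep(500, 4))
  expect_equal(truncate_renormalize(flat, 1)$lx, rep(500, 3))
})

test_that("a renormalized simulated cohort matches conditional survival", {
  p <- fig_params()
  rec <- simulate_cohort(p, n = 40000, seed = 31)
  co <- truncate_renormalize(records_to_cohort(rec, ages = 0:100), 10)
  model <- surv_conditional(p, 10, co$ages)
  # Monte-Carlo + closed-form approximation tolerance
  expect_lt(max(abs(co$lx / co$radix - model)), 0.03)
})

test_that("lx-to-counts conversion conserves the true cohort size", {
  co <- cohort_survival(c(10, 20, 30), c(100, 75, 50), radix = 100)
  d <- cohort_to_intervals(co, actual_n = 100)
  expect_equal(d$deaths, c(25, 25, 50))
  expect_equal(sum(d$deaths), 100)

  flat <- cohort_survival(0:4, rep(1000, 5))
  df <- cohort_to_intervals(flat, actual_n = 77)
  expect_equal(df$deaths, c(0, 0, 0, 0, 77))

  f <- tempfile(fileext = ".txt")
  writeLines(hmd_fixture_lines(), f)
  hm <- read_hmd_cohort_lx(f, sex = "Total", years = 1870)
  dh <- cohort_to_intervals(hm, actual_n = 10007)   # forces a rounding residual
  expect_equal(sum(dh$deaths), 10007)
  expect_error(cohort_to_intervals(co, actual_n = -5), "positive")
})
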