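test_that("all survival curves start at exactly 1", {
  for (p in random_params(5)) {
    expect_identical(surv_intrinsic(p, 0), 1)
    expect_identical(surv_extrinsic(p, 0), 1)
    expect_identical(surv_total(p, 0), 1)
  }
})

test_that("intrinsic survival matches quadrature of the first-passage density", {
  p <- fig_params()
  for (x in c(30, 55, 70, 80, 95)) {
    expect_equal(surv_intrinsic(p, x),
                 oracle_intrinsic_survival(p[["r"]], p[["s"]], x),
                 tolerance = 1e-6)
  }
  # at these parameters the intrinsic process has killed essentially nobody
  # by age 30
  expect_equal(round(surv_intrinsic(p, 30), 3), 1)
})

test_that("vanishing variability collapses intrinsic survival to a step at 1/r", {
  p <- vital_params(r = 0.02, s = 1e-7, lam = 0, beta = 0.5)
  expect_equal(surv_intrinsic(p, 40), 1, tolerance = 1e-12)
  expect_equal(surv_intrinsic(p, 60), 0, tolerance = 1e-12)
})

test_that("extrinsic closed form equals the exponentiated hazard integral", {
  p <- fig_params()
  o60 <- oracle_extrinsic_survival(p[["r"]], p[["lam"]], p[["beta"]], 60)
  expect_equal(surv_extrinsic(p, 60), o60, tolerance = 1e-8)
  expect_equal(round(o60, 2), 0.49)
  for (q in random_params(20, seed = 3)) {
    x <- runif(1, 1, 100)
    expect_equal(surv_extrinsic(q, x),
                 oracle_extrinsic_survival(q[["r"]], q[["lam"]],
                                           q[["beta"]], x),
                 tolerance = 1e-8)
  }
})

test_that("no challenges means no extrinsic mortality", {
  p <- vital_params(0.0135, 0.0126, 0, 0.3999)
  x <- seq(0, 110, by = 0.5)
  expect_identical(surv_extrinsic(p, x), rep(1, length(x)))
  expect_identical(surv_total(p, x), surv_intrinsic(p, x))
})

test_that("survival curves are bounded, monotone and multiply exactly", {
  draws <- random_params(1000, seed = 11)
  x <- seq(0, 110, length.out = 200)
  for (p in draws) {
    li <- surv_intrinsic(p, x)
    le <- surv_extrinsic(p, x)
    lt <- surv_total(p, x)
    for (v in list(li, le, lt)) {
      expect_true(all(v >= 0 & v <= 1))
      expect_true(all(diff(v) <= 1e-12))
    }
    expect_lt(max(abs(lt - li * le)), 1e-12)
  }
})

test_that("survival responds monotonically to r and lam", {
  x <- 50
  s <- 0.0126; lam <- 0.05; beta <- 0.4
  rs <- seq(0.008, 0.019, length.out = 12)       # keep x < 1/r throughout
  li <- vapply(rs, function(r) surv_intrinsic(vital_params(r, s, lam, beta), x),
               numeric(1))
  expect_true(all(diff(li) <= 0))
  lams <- seq(0, 0.2, length.out = 12)
  le <- vapply(lams, function(l)
    surv_extrinsic(vital_params(0.0135, s, l, beta), x), numeric(1))
  expect_true(all(diff(le) <= 0))
})

test_that("conditional survival normalizes at the truncation age", {
  p <- fig_params()
  expect_equal(surv_conditional(p, 10, 10), 1)
  x <- seq(0, 100, by = 5)
  expect_equal(surv_conditional(p, 0, x), surv_total(p, x))
  expect_equal(surv_conditional(p, 10, 70),
               surv_total(p, 70) / surv_total(p, 10))
  expect_error(surv_conditional(p, 10, 5), "truncation age")
  # oracle route: both component integrals, then the conditional ratio
  o <- oracle_intrinsic_survival(p[["r"]], p[["s"]], 70) *
    oracle_extrinsic_survival(p[["r"]], p[["lam"]], p[["beta"]], 70) /
    (oracle_intrinsic_survival(p[["r"]], p[["s"]], 10) *
       oracle_extrinsic_survival(p[["r"]], p[["lam"]], p[["beta"]], 10))
  expect_equal(surv_conditional(p, 10, 70), o, tolerance = 1e-6)
})

test_that("age domain is validated", {
  p <- fig_params()
  expect_error(surv_intrinsic(p, -1), "non-negative")
  expect_error(surv_total(p, c(3, NA)), "finite")
})
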