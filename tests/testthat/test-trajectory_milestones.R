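test_that("noise-free logistic parameters are recovered", {
  gen <- gen_growth_series(growth_spec("logistic", A = 120, k = 0.02,
                                       t0 = 800, sigma = 0, n = 40,
                                       seed = 61))
  fit <- fit_growth(gen$series$age_days, gen$series$value)
  expect_equal(fit$family, "logistic")
  expect_equal(unname(fit$parameters),
               c(120, 0.02, 800), tolerance = 1e-6)
})

test_that("gompertz data select the gompertz family by AIC", {
  gen <- gen_growth_series(growth_spec("gompertz", A = 80, k = 0.015,
                                       t0 = 600, sigma = 0.2, n = 60,
                                       seed = 62))
  fit <- fit_growth(gen$series$age_days, gen$series$value)
  expect_equal(fit$family, "gompertz")
  expect_equal(unname(fit$parameters["A"]), 80, tolerance = 0.05)
})

test_that("milestones match their closed forms", {
  gen <- gen_growth_series(growth_spec("logistic", A = 100, k = 0.01,
                                       t0 = 1000, sigma = 0, n = 40,
                                       seed = 63))
  fit <- fit_growth(gen$series$age_days, gen$series$value)
  # independent oracle: numeric inversion of the true curve
  oracle <- function(frac) uniroot(function(t) gen$truth$curve(t) - frac * 100,
                                   c(1, 5000), tol = 1e-10)$root
  expect_equal(milestone_age(fit, 50), 1000, tolerance = 1e-6)
  expect_equal(milestone_age(fit, 50), oracle(0.5), tolerance = 1e-6)
  expect_equal(milestone_age(fit, 90), 1000 + log(9) / 0.01,
               tolerance = 1e-6)
  expect_equal(milestone_age(fit, 90), oracle(0.9), tolerance = 1e-6)
  # pct = 100 is finite under the (1 - tol) * asymptote rule
  m100 <- milestone_age(fit, 100)
  expect_true(is.finite(m100))
  expect_equal(m100, oracle(0.99), tolerance = 1e-6)
})

test_that("milestone ages are non-decreasing in the percentage", {
  gen <- gen_growth_series(growth_spec("gompertz", A = 50, k = 0.02,
                                       t0 = 400, sigma = 0.3, n = 50,
                                       seed = 64))
  fit <- fit_growth(gen$series$age_days, gen$series$value)
  ms <- milestone_set(fit, pcts = c(25, 50, 75, 90, 100))
  expect_true(all(diff(ms$age) >= 0))
  tps <- milestones_to_timepoints(ms, "gorilla")
  expect_equal(nrow(as_timepoints(tps, default_config)$errors), 0)
})

test_that("degenerate and decreasing series hit their contract paths", {
  expect_warning(fit <- fit_growth(1:10, rep(5, 10)), "constant")
  expect_equal(fit$asymptote, 5)
  expect_warning(fit2 <- fit_growth(1:10, 10:1 + 0.1), "monotone")
  expect_equal(fit2$family, "monotone_spline")
})

test_that("the monotone fallback still yields milestone ages", {
  # step-ish increasing data that no sigmoid fits well
  age <- seq(10, 100, by = 5)
  value <- pmin(pmax(age - 40, 0), 30) +
    rep(c(0, 0.001), length.out = length(age))
  fit <- suppressWarnings(fit_growth(age, value,
                                     families = character(0)))
  expect_equal(fit$family, "monotone_spline")
  m50 <- milestone_age(fit, 50)
  expect_gt(m50, 40)
  expect_lt(m50, 70)
  # the fallback's asymptote is its largest fitted value, so even
  # pct = 100 under the (1 - tol) rule stays attainable
  expect_true(is.finite(milestone_age(fit, 100)))
})

test_that("peak ages are located and boundary peaks flagged", {
  age <- seq(0, 40, length.out = 60)
  peaked <- 100 - (age - 20)^2
  res <- peak_age(age, peaked)
  expect_equal(res$peak_age, 20, tolerance = 0.05)
  expect_false(res$boundary)
  rising <- peak_age(age, age * 2)
  expect_true(rising$boundary)
  # smooth bump, noise-free: mode recovered within 1%
  bump <- exp(-(age - 26)^2 / 18)
  expect_equal(peak_age(age, bump)$peak_age, 26, tolerance = 0.01 * 26)
})

test_that("attainment age is exact for step series and ignores duplicates", {
  age <- c(1, 2, 3, 4, 5)
  count <- c(0, 0, 8, 8, 8)
  expect_identical(attainment_age(age, count, 8), 3)
  dup <- attainment_age(rep(age, 2)[order(rep(age, 2))],
                        rep(count, 2)[order(rep(age, 2))], 8)
  expect_equal(attainment_age(age, count, 8), dup)
  expect_error(attainment_age(age, count, 12), "refusing to extrapolate")
})

test_that("synthetic carpal-style series recover their attainment ages", {
  for (yrs in c(4.7, 11)) {
    gen <- gen_attainment_series(adult_count = 8,
                                 attain_age_days = yrs * 365.25,
                                 n = 60, seed = 65)
    est <- attainment_age(gen$series$age_days, gen$series$count, 8)
    expect_lt(abs(est / 365.25 - yrs), 0.5)
  }
})
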