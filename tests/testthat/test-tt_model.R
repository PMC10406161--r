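test_that("noise-free linear tables are fitted exactly", {
  spec <- event_table_spec(n_events = 30, sigma = 0, missing = 0,
                           gamma = 0, seed = 31)
  res <- run_synthetic_fit(spec)
  expect_gt(res$fit$r_squared, 1 - 1e-10)
  # predictions coincide with the observed time points
  expect_lt(max(abs(residuals(res$fit$lm))), 1e-8)
  # marginal species slopes equal the generator's beta
  sl <- species_slopes(res$fit)
  expect_equal(sl$slope, unname(res$gen$truth$beta[sl$species]),
               tolerance = 1e-6)
})

# a fit whose shared quadratic is exactly -0.4: inject the curvature on a
# fixed score axis (the scale of the unmodified table), since a scale
# recomputed from curved data absorbs any shared curvature into itself —
# the cross-species mean is affine in its own min-max scale by construction
curved_fit <- function(seed = 32, gamma = -0.4) {
  gen <- gen_event_table(event_table_spec(n_events = 40, sigma = 0,
                                          missing = 0, gamma = 0,
                                          seed = seed))
  sc <- compute_event_scale(gen$table)
  gen$table$log_age <- gen$table$log_age + gamma * sc$score^2
  list(fit = fit_translating_time(gen$table, sc), gen = gen, scale = sc)
}

test_that("the shared quadratic term is recovered on a fixed scale axis", {
  cf <- curved_fit()
  expect_equal(unname(coef(cf$fit$lm)["I(score^2)"]), -0.4,
               tolerance = 1e-6)
  expect_equal(species_slopes(cf$fit)$slope,
               unname(cf$gen$truth$beta[cf$fit$species]), tolerance = 1e-6)
})

test_that("a scale recomputed from curved data absorbs shared curvature", {
  res <- run_synthetic_fit(event_table_spec(n_events = 40, sigma = 0,
                                            missing = 0, gamma = -0.4,
                                            seed = 32))
  expect_lt(abs(coef(res$fit$lm)["I(score^2)"]), 0.05)
  expect_gt(res$fit$r_squared, 0.999)
})

test_that("inversion is the exact inverse of prediction", {
  res <- run_synthetic_fit(event_table_spec(n_events = 40, sigma = 0.05,
                                            missing = 0.3, seed = 33))
  for (sp in c("human", "rhesus_macaque", "marmoset")) {
    cv <- species_curve(res$fit, sp)
    E <- runif(50)
    la <- cv$intercept + cv$slope * E + cv$quad * E^2
    inv <- invert_to_scale(res$fit, sp, la)
    expect_lt(max(abs(inv$score - E)), 1e-8)
  }
})

test_that("a zero quadratic coefficient degrades to linear inversion", {
  res <- run_synthetic_fit(event_table_spec(n_events = 25, sigma = 0,
                                            missing = 0, gamma = 0,
                                            seed = 34))
  cv <- species_curve(res$fit, "human")
  expect_lt(abs(cv$quad), 1e-8)
  inv <- invert_to_scale(res$fit, "human", cv$intercept + cv$slope * 0.37)
  expect_equal(inv$score, 0.37, tolerance = 1e-8)
})

test_that("scores outside [0, 1] are flagged as extrapolation", {
  res <- run_synthetic_fit(event_table_spec(n_events = 25, sigma = 0,
                                            missing = 0, seed = 35))
  cv <- species_curve(res$fit, "human")
  inv <- invert_to_scale(res$fit, "human",
                         cv$intercept + cv$slope * 1.2 + cv$quad * 1.44)
  expect_true(inv$extrapolated)
  # an age above the quadratic curve's apex has no real solution and the
  # error names the attainable bound
  cf <- curved_fit()
  expect_error(invert_to_scale(cf$fit, "human", 80), "bound")
})

test_that("translation is identity within species and invertible across", {
  res <- run_synthetic_fit(event_table_spec(n_events = 40, sigma = 0.05,
                                            missing = 0.3, seed = 36))
  ages <- c(300, 1000, 5000, 15000)
  expect_equal(translate_age(res$fit, "human", ages, "human")$to_age_days,
               ages)
  there <- translate_age(res$fit, "human", ages, "gorilla")
  back <- translate_age(res$fit, "gorilla", there$to_age_days, "human")
  expect_equal(back$to_age_days, ages, tolerance = 1e-6)
  # strictly increasing in input age
  grid <- translate_age(res$fit, "human", seq(200, 20000, length.out = 50),
                        "chimpanzee")
  expect_true(all(diff(grid$to_age_days) > 0))
})

test_that("a known two-species log-log warp is recovered by translation", {
  spec <- event_table_spec(n_events = 40,
                           species_params = two_species_params(alpha = 1.2),
                           gamma = 0, sigma = 0.02, missing = 0.2,
                           seed = 37)
  res <- run_synthetic_fit(spec)
  from <- exp(seq(4.2, 8.5, length.out = 30))
  tr <- translate_age(res$fit, "sp_a", from, "sp_b")
  slope <- coef(lm(log(tr$to_age_days) ~ log(from)))[2]
  expect_equal(unname(slope), 1.2, tolerance = 0.05 * 1.2)
})

test_that("heterochrony test rejects an injected timing shift", {
  spec <- event_table_spec(n_events = 60, sigma = 0.05, missing = 0,
    heterochrony = list(species = "chimpanzee",
                        event_type = "locomotor_forelimb",
                        slope_factor = 0.8),
    seed = 38)
  res <- run_synthetic_fit(spec)
  reduced <- fit_translating_time(res$table, res$scale,
                                  include_event_type = FALSE)
  ht <- heterochrony_test(res$fit, reduced)
  expect_lt(ht$p_value, 1e-4)
  expect_named(ht$type_shift)
})

test_that("heterochrony power exceeds 0.8 under the spec'd shift", {
  rejected <- vapply(1:25, function(s) {
    res <- run_synthetic_fit(event_table_spec(n_events = 60, sigma = 0.05,
      missing = 0,
      heterochrony = list(species = "chimpanzee",
                          event_type = "locomotor_forelimb",
                          slope_factor = 0.8),
      seed = 3000 + s))
    reduced <- fit_translating_time(res$table, res$scale,
                                    include_event_type = FALSE)
    heterochrony_test(res$fit, reduced)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.8)
})

test_that("identical designs make the F test a contract error", {
  res <- run_synthetic_fit(event_table_spec(n_events = 20, seed = 39))
  expect_error(heterochrony_test(res$fit, res$fit), "must not")
  reduced <- fit_translating_time(res$table, res$scale,
                                  include_event_type = FALSE)
  expect_error(heterochrony_test(reduced, reduced), "must")
})

test_that("paired alignment regression recovers slope, intercept and a tissue effect", {
  withr::local_seed(40)
  x <- runif(158, 3, 10)                       # predictor-species log ages
  tissue <- rep(c(0, 1), c(147, 11))           # in vivo vs in vitro
  y <- 1.08 * x - 0.13 - 0.11 * tissue + rnorm(158, 0, 0.05)
  fit <- two_species_alignment(x, y, covariate = factor(tissue))
  expect_equal(fit$slope, 1.08, tolerance = 0.02)
  expect_lt(abs(fit$intercept - (-0.13)), 0.06)
  expect_lt(abs(fit$estimate - (-0.11)), 0.06)
  expect_gt(fit$r_squared, 0.95)
  # quadratic variant used for two-species polynomial checks
  y2 <- 1 + 0.8 * x + 0.02 * x^2 + rnorm(158, 0, 0.01)
  fq <- two_species_alignment(x, y2, quadratic = TRUE)
  expect_gt(fq$r_squared, 0.99)
})

test_that("fits serialize to YAML with coefficients and diagnostics", {
  res <- run_synthetic_fit(event_table_spec(n_events = 15, seed = 41))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tt_fit(res$fit, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$diagnostics$r_squared, res$fit$r_squared,
               tolerance = 1e-6)
  expect_equal(y$reference_species, "human")
})
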