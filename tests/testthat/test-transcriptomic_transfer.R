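pair_clean <- gen_expression_pair(expression_pair_spec(
  n_genes = 120, n_informative = 80, n_samples = 24, sigma = 0, seed = 51))

test_that("training reports are deterministic under the seed", {
  r1 <- train_age_predictors(pair_clean$reference, seed = 7)
  r2 <- train_age_predictors(pair_clean$reference, seed = 7)
  expect_identical(r1$reports, r2$reports)
  expect_equal(sum(r1$reports$selected), 1)
  expect_true(all(r1$reports$rmse >= 0, na.rm = TRUE))
})

test_that("noise-free informative expression is predicted almost exactly", {
  preds <- train_age_predictors(pair_clean$reference, seed = 7)
  best <- preds$reports$rmse[preds$reports$selected]
  expect_lt(best, 0.05)
})

test_that("uninformative expression predicts no better than the age spread", {
  null_pair <- gen_expression_pair(expression_pair_spec(
    n_genes = 120, n_informative = 1, n_samples = 24, sigma = 0.5,
    seed = 52))
  # overwrite the lone informative gene with noise so nothing tracks age
  null_expr <- null_pair$reference
  null_expr$values[1, ] <- exp(rnorm(24, 3, 0.5))
  preds <- train_age_predictors(null_expr, seed = 7)
  test_idx <- setdiff(seq_len(24), preds$train_idx)
  spread <- sd(log(null_expr$samples$age_days[test_idx]))
  best <- min(preds$reports$rmse, na.rm = TRUE)
  expect_gt(best, 0.5 * spread)
})

test_that("self-transfer reproduces the training species' own ages", {
  preds <- train_age_predictors(pair_clean$reference, seed = 7)
  pairs <- transfer_ages(preds, pair_clean$reference)
  bias <- mean(log(pairs$translated_age_days) - log(pairs$source_age_days))
  expect_lt(abs(bias), 0.05)
})

test_that("a 1.3x age warp is recovered as the transfer slope", {
  pair <- gen_expression_pair(expression_pair_spec(
    n_genes = 200, n_informative = 120, n_samples = 40,
    warp = function(u) 1.3 * u, age_range = c(100, 5000),
    target_age_range = c(100, 3800),
    sigma = 0.05, seed = 53))
  preds <- train_age_predictors(pair$reference, seed = 7)
  pairs <- transfer_ages(preds, pair$target)
  slope <- unname(coef(lm(translated_age_days ~ source_age_days,
                          data = pairs))[2])
  expect_lt(abs(slope - 1.3), 0.1)
})

test_that("transfer pairs export as transcription time points", {
  preds <- train_age_predictors(pair_clean$reference, seed = 7)
  pairs <- transfer_ages(preds, pair_clean$target)
  expect_equal(nrow(pairs), 24)
  tps <- transfer_to_timepoints(pairs, "human")
  expect_equal(unique(tps$event_type), "transcription")
  expect_equal(nrow(tps), 48)  # one source + one translated row per sample
  expect_equal(nrow(as_timepoints(tps, default_config)$errors), 0)
})

test_that("insufficient gene overlap is refused with counts", {
  preds <- train_age_predictors(pair_clean$reference, seed = 7)
  small <- pair_clean$target
  small$values <- small$values[1:30, , drop = FALSE]
  expect_error(transfer_ages(preds, small), "30 of 120")
})

test_that("correlation alignment self-matches with correlation 1", {
  ref <- pair_clean$reference
  res <- suppressWarnings(
    correlation_align(ref$values[, 10], ref, min_log10_expr = 0.5))
  expect_equal(res$best_age, ref$samples$age_days[10])
  expect_equal(max(res$profile$correlation), 1, tolerance = 1e-12)
  expect_false(res$tie)
})

test_that("correlation alignment places warped samples at their warped age", {
  pair <- gen_expression_pair(expression_pair_spec(
    n_genes = 300, n_informative = 250, n_samples = 30,
    warp = function(u) 1.3 * u, sigma = 0.02, seed = 54))
  i <- 12
  res <- suppressWarnings(
    correlation_align(pair$target$values[, i], pair$reference))
  u <- pair$target$samples$age_days[i]
  nearest <- pair$reference$samples$age_days[
    which.min(abs(log(pair$reference$samples$age_days) - log(1.3 * u)))]
  expect_equal(res$best_age, nearest)
})

test_that("tied maxima return the youngest age with a flag", {
  vals <- matrix(rep(c(5, 10, 20, 40), 3), 4, 3,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  ref <- expression_matrix(vals, ages_days = c(200, 100, 300), "human")
  res <- suppressWarnings(correlation_align(vals[, 1], ref))
  expect_true(res$tie)
  expect_equal(res$best_age, 100)
})

test_that("expression matrices round-trip through TSV + metadata sidecar", {
  ref <- pair_clean$reference
  mat <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(ref, mat, meta)
  back <- read_expression_matrix(mat, meta)
  expect_equal(back$values, ref$values, tolerance = 1e-6)
  expect_equal(back$samples$age_days, ref$samples$age_days)
})

test_that("negative expression values are rejected", {
  expect_error(expression_matrix(matrix(-1, 1, 1, dimnames = list("g", "s")),
                                 100, "human"))
})
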