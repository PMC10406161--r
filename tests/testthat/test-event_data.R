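test_that("well-formed CSV parses to time points with no errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_timepoints_df(), path, row.names = FALSE)
  res <- read_timepoints(path, default_config)
  expect_equal(nrow(res$timepoints), 3)
  expect_equal(nrow(res$errors), 0)
  expect_equal(res$timepoints$event_id, c("ev1", "ev1", "ev2"))
  # years_postnatal converted: 12 y * 365.25 + human gestation
  expect_equal(res$timepoints$age_dpc[3], 12 * 365.25 + 270)
})

test_that("bad rows are flagged individually and good rows kept", {
  df <- tiny_timepoints_df()
  df$age_value[2] <- -1
  df <- rbind(df, within(df[1, ], species <- "lemur"))
  res <- as_timepoints(df, default_config)
  expect_equal(nrow(res$timepoints), 2)
  expect_setequal(res$errors$row, c(2, 4))
  expect_match(res$errors$message[res$errors$row == 2], "age_value")
  expect_match(res$errors$message[res$errors$row == 4], "config entry")
})

test_that("missing mandatory columns are a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_timepoints_df()[, -4], path, row.names = FALSE)
  expect_error(read_timepoints(path, default_config), "age_value")
})

test_that("age-frame conversion follows the additive rules", {
  cfg <- default_config
  expect_equal(to_days_post_conception(100, "days_post_conception",
                                       "human", cfg), 100)
  expect_equal(to_days_post_conception(0, "days_postnatal", "human", cfg),
               270)
  expect_equal(to_days_post_conception(30, "days_postnatal",
                                       "chimpanzee", cfg), 30 + 228)
  # organoid incubation day 25 with default offset 0
  expect_equal(to_days_post_conception(25, "days_post_incubation",
                                       "gorilla", cfg), 25)
  expect_error(to_days_post_conception(5, "lunar_months", "human", cfg),
               "age_frame")
  # strictly increasing in age for a fixed frame/species
  ages <- sort(runif(20, 1, 5000))
  conv <- to_days_post_conception(ages, "days_postnatal", "gorilla", cfg)
  expect_true(all(diff(conv) > 0))
})

test_that("organoid rows must carry the incubation frame", {
  df <- tiny_timepoints_df()
  df$provenance[1] <- "organoid"
  res <- as_timepoints(df, default_config)
  expect_equal(res$errors$row, 1)
  expect_match(res$errors$message, "incubation")
})

test_that("event-table cells average log ages and mask unobserved cells", {
  df <- data.frame(
    species = c("human", "human", "chimpanzee", "human", "chimpanzee"),
    event_id = c("e1", "e1", "e1", "e2", "e3"),
    event_type = "body_growth",
    age_value = c(exp(2), exp(4), exp(3), exp(5), exp(4)),
    age_frame = "days_post_conception", sex = "pooled",
    population = "p", environment = "captive",
    provenance = "individual", stringsAsFactors = FALSE)
  tab <- build_event_table(as_timepoints(df, default_config)$timepoints)
  expect_equal(tab$log_age["e1", "human"], 3)          # mean of 2 and 4
  expect_true(is.na(tab$log_age["e2", "chimpanzee"]))  # human-only event
  expect_false(tab$observed["e2", "chimpanzee"])
  expect_true(tab$observed["e2", "human"])
})

test_that("event-table construction is row-order invariant", {
  df <- tiny_timepoints_df()
  df <- rbind(df, within(df[1, ], {event_id <- "ev3"; age_value <- 500}))
  t1 <- build_event_table(as_timepoints(df, default_config)$timepoints)
  t2 <- build_event_table(as_timepoints(df[sample(nrow(df)), ],
                                        default_config)$timepoints)
  expect_identical(t1$log_age, t2$log_age)
})

test_that("event-table CSV round trip is bit-identical", {
  gen <- gen_event_table(event_table_spec(n_events = 12, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(gen$table, path)
  back <- read_event_table(path)
  expect_identical(back$log_age, gen$table$log_age)
  expect_identical(back$observed, gen$table$observed)
  expect_identical(back$event_type, gen$table$event_type)
})

test_that("a 573-row synthetic fixture yields 573 time points", {
  gen <- gen_event_table(event_table_spec(n_events = 64, missing = 0,
                                          sigma = 0.1, seed = 11))
  tps <- event_table_to_timepoints(gen$table)   # 9 x 64 = 576 rows
  tps <- tps[seq_len(573), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tps, path, row.names = FALSE)
  res <- read_timepoints(path, default_config)
  expect_equal(nrow(res$timepoints), 573)
  expect_equal(nrow(res$errors), 0)
})
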