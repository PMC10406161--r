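#' Default per-species parameters of the synthetic event-table generator
#'
#' Species curves on the latent event scale are anchored at two published
#' landmarks: the age of an early neural event (around the onset of
#' neurogenesis, days post conception) at scale 0, and the oldest age the
#' cross-species alignment covers at scale 1 (e.g. 68 years in humans and
#' the corresponding 57 years in chimpanzees).  Intercepts and slopes are
#' derived from those anchors given the shared quadratic coefficient, so a
#' noise-free generated table reproduces the anchor alignments exactly.
#'
#' @param gamma Shared quadratic coefficient of the latent curve
#'   (log-days per squared scale unit).
#' @param config A [species_config()] used for gestation lengths.
#' @return Data frame with `species`, `alpha` (intercept, log days post
#'   conception at scale 0), `beta` (slope) and the anchors they came from.
#' @export
default_species_params <- function(gamma = -0.4, config = species_config()) {
  anchors <- data.frame(
    species = c("human", "chimpanzee", "bonobo", "gorilla", "orangutan",
                "gibbon", "siamang", "rhesus_macaque", "marmoset"),
    early_dpc = c(40, 38, 38, 38, 38, 35, 35, 30, 28),
    late_years = c(68, 57, 55, 50, 55, 35, 35, 35, 15),
    stringsAsFactors = FALSE)
  gest <- config$gestation_days[anchors$species]
  late_dpc <- anchors$late_years * 365.25 + gest
  anchors$alpha <- log(anchors$early_dpc)
  anchors$beta <- log(late_dpc) - anchors$alpha - gamma
  rownames(anchors) <- NULL
  anchors
}

#' Specification of a synthetic species-by-event table
#'
#' Cells follow `alpha_s + beta_s * E_e + gamma * E_e^2 + N(0, sigma^2)`
#' in natural-log days post conception, with latent event scores `E_e`
#' drawn uniformly on \[0, 1\] and sorted (the earliest and latest events
#' pinned at 0 and 1, since those define the scale), and cells masked
#' completely at
#' random with probability `missing` (every event keeps at least one
#' observed species).
#'
#' @param n_events Number of events.
#' @param species_params Data frame with `species`, `alpha`, `beta`
#'   (defaults: [default_species_params()], nine primate species).
#' @param gamma Shared quadratic coefficient.
#' @param sigma Noise standard deviation (log-days).
#' @param missing Missing-cell fraction in \[0, 1).
#' @param event_type_levels Types cycled over events (a closed-vocabulary
#'   subset; see [event_types()]).
#' @param heterochrony Optional list `(species, event_type, slope_factor)`:
#'   multiplies `beta` for that species' events of that type, injecting a
#'   known timing shift for power studies.  `NULL` (default) generates under
#'   the no-heterochrony null.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `event_table_spec`.
#' @export
event_table_spec <- function(n_events = 64,
                             species_params = default_species_params(gamma),
                             gamma = -0.4, sigma = 0.1, missing = 0.3,
                             event_type_levels = event_types()[1:6],
                             heterochrony = NULL, seed = 1L) {
  stopifnot(n_events >= 3, nrow(species_params) >= 2,
            all(species_params$beta > 0),
            sigma >= 0, missing >= 0, missing < 1,
            all(event_type_levels %in% event_types()))
  structure(list(n_events = as.integer(n_events),
                 species_params = species_params, gamma = gamma,
                 sigma = sigma, missing = missing,
                 event_type_levels = event_type_levels,
                 heterochrony = heterochrony, seed = as.integer(seed)),
            class = "event_table_spec")
}

#' Generate a synthetic event table with known ground truth
#'
#' @param spec An [event_table_spec()].
#' @return List with `table` (an `event_table` with the injected
#'   missingness mask) and `truth` (latent `scores`, `alpha`, `beta`,
#'   `gamma`, and the complete noise-free and noisy matrices).
#' @export
gen_event_table <- function(spec) {
  stopifnot(inherits(spec, "event_table_spec"))
  sp <- spec$species_params
  withr::with_seed(spec$seed, {
    # the earliest and latest events define the scale's endpoints, so the
    # latent axis and the realized min-max scale coincide at sigma = 0
    scores <- sort(c(0, 1, stats::runif(spec$n_events - 2)))
    events <- sprintf("event_%03d", seq_len(spec$n_events))
    et <- rep_len(spec$event_type_levels, spec$n_events)
    names(et) <- events
    beta_mat <- matrix(rep(sp$beta, each = spec$n_events),
                       spec$n_events, nrow(sp),
                       dimnames = list(events, sp$species))
    if (!is.null(spec$heterochrony)) {
      h <- spec$heterochrony
      rows <- et == h$event_type
      beta_mat[rows, h$species] <- beta_mat[rows, h$species] * h$slope_factor
    }
    mean_mat <- matrix(rep(sp$alpha, each = spec$n_events),
                       spec$n_events, nrow(sp)) +
      beta_mat * scores + spec$gamma * scores^2
    noisy <- mean_mat +
      matrix(stats::rnorm(length(mean_mat), 0, spec$sigma),
             spec$n_events, nrow(sp))
    dimnames(noisy) <- dimnames(beta_mat)
    mask <- matrix(stats::runif(length(noisy)) < spec$missing,
                   spec$n_events, nrow(sp))
    # every event keeps >= 1 observed species
    all_masked <- which(rowSums(!mask) == 0)
    for (i in all_masked) mask[i, sample(ncol(mask), 1)] <- FALSE
    observed <- noisy
    observed[mask] <- NA_real_
  })
  truth <- list(scores = stats::setNames(scores, events),
                alpha = stats::setNames(sp$alpha, sp$species),
                beta = stats::setNames(sp$beta, sp$species),
                gamma = spec$gamma, mean_log_age = mean_mat,
                complete_log_age = noisy)
  list(table = new_event_table(observed, event_type = et), truth = truth)
}

#' Convert an event table to a long time-point data frame
#'
#' One time-point row per observed cell, ages expressed in days post
#' conception, for writing synthetic bundles in the CSV dialect
#' [read_timepoints()] parses.
#'
#' @param table An `event_table`.
#' @return Data frame with the mandatory time-point columns.
#' @export
event_table_to_timepoints <- function(table) {
  df <- as.data.frame(table)
  df <- df[df$observed, , drop = FALSE]
  data.frame(species = df$species, event_id = df$event_id,
             event_type = df$event_type,
             age_value = exp(df$log_age),
             age_frame = "days_post_conception",
             sex = "pooled", population = "synthetic",
             environment = "unknown", provenance = "individual",
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic two-species expression pair
#'
#' Informative genes have log-scale expectation `a_i + b_i * log(t)` with
#' `t` the age in days post conception; species-B samples at age `u` are
#' expressed as if at age `warp(u)` on the reference timeline, emulating a
#' species that matures at a different pace.  Values are exp-transformed
#' so matrices are positive and TPM-like.
#'
#' @param n_genes,n_informative Total and age-informative gene counts.
#' @param n_samples Samples per species.
#' @param warp Strictly increasing function mapping target-species age
#'   (days) to reference-species age (days).  Default identity.
#' @param target_age_range Sampled age range of the target species;
#'   defaults to `age_range`.  Choose it so warped ages stay inside
#'   `age_range` when emulating a transfer within the trained span
#'   (predictors are not meant to extrapolate beyond their training ages).
#' @param species Labels for the reference and target matrices.
#' @param age_range Sampled age range (days post conception) of the
#'   reference species.
#' @param sigma Log-scale noise sd.
#' @param seed Integer seed.
#' @return An object of class `expression_pair_spec`.
#' @export
expression_pair_spec <- function(n_genes = 200, n_informative = 100,
                                 n_samples = 40, warp = identity,
                                 age_range = c(100, 8000), sigma = 0.1,
                                 target_age_range = age_range,
                                 species = c("human", "gorilla"),
                                 seed = 1L) {
  stopifnot(n_informative > 0, n_informative <= n_genes,
            is.function(warp), sigma >= 0, age_range[1] > 0,
            age_range[2] > age_range[1], length(species) == 2,
            target_age_range[1] > 0,
            target_age_range[2] > target_age_range[1])
  structure(list(n_genes = n_genes, n_informative = n_informative,
                 n_samples = n_samples, warp = warp, age_range = age_range,
                 target_age_range = target_age_range,
                 sigma = sigma, species = species, seed = as.integer(seed)),
            class = "expression_pair_spec")
}

#' Generate a matched pair of expression matrices with a known time warp
#'
#' @param spec An [expression_pair_spec()].
#' @return List with `reference` and `target` ([expression_matrix()]
#'   objects) and `truth` (`warp`, per-gene `a`, `b`, informative flags).
#' @export
gen_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "expression_pair_spec"))
  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  withr::with_seed(spec$seed, {
    a <- stats::runif(spec$n_genes, 1, 5)
    b <- numeric(spec$n_genes)
    informative <- seq_len(spec$n_informative)
    b[informative] <- sample(c(-1, 1), spec$n_informative, TRUE) *
      stats::runif(spec$n_informative, 0.3, 1)
    ages_ref <- sort(exp(stats::runif(spec$n_samples,
                                      log(spec$age_range[1]),
                                      log(spec$age_range[2]))))
    ages_tgt <- sort(exp(stats::runif(spec$n_samples,
                                      log(spec$target_age_range[1]),
                                      log(spec$target_age_range[2]))))
    signal <- function(t) outer(b, log(t)) + a
    vals_ref <- exp(signal(ages_ref) +
                      matrix(stats::rnorm(spec$n_genes * spec$n_samples,
                                          0, spec$sigma),
                             spec$n_genes))
    vals_tgt <- exp(signal(spec$warp(ages_tgt)) +
                      matrix(stats::rnorm(spec$n_genes * spec$n_samples,
                                          0, spec$sigma),
                             spec$n_genes))
  })
  rownames(vals_ref) <- rownames(vals_tgt) <- genes
  colnames(vals_ref) <- sprintf("ref_%02d", seq_len(spec$n_samples))
  colnames(vals_tgt) <- sprintf("tgt_%02d", seq_len(spec$n_samples))
  list(reference = expression_matrix(vals_ref, ages_ref, spec$species[1]),
       target = expression_matrix(vals_tgt, ages_tgt, spec$species[2]),
       truth = list(warp = spec$warp, a = a, b = b,
                    informative = genes[informative]))
}

#' Specification and generator for synthetic growth trajectories
#'
#' Sigmoidal growth with known parameters: logistic
#' `A / (1 + exp(-k (t - t0)))` or Gompertz `A * exp(-exp(-k (t - t0)))`,
#' plus Gaussian noise.
#'
#' @param family `"logistic"` or `"gompertz"`.
#' @param A Asymptote (> 0), e.g. adult volume.
#' @param k Growth rate (> 0, per day).
#' @param t0 Inflection age (days post conception).
#' @param sigma Noise sd on the value scale.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(family = c("logistic", "gompertz"), A = 100,
                        k = 0.01, t0 = 1000, sigma = 0, n = 50, seed = 1L) {
  family <- match.arg(family)
  stopifnot(A > 0, k > 0, n >= 6, sigma >= 0)
  structure(list(family = family, A = A, k = k, t0 = t0, sigma = sigma,
                 n = n, seed = as.integer(seed)), class = "growth_spec")
}

growth_curve_fun <- function(family, A, k, t0) {
  switch(family,
         logistic = function(t) A / (1 + exp(-k * (t - t0))),
         gompertz = function(t) A * exp(-exp(-k * (t - t0))))
}

#' @rdname growth_spec
#' @param spec A `growth_spec`.
#' @return `gen_growth_series()` returns a list with `series` (data frame
#'   `age_days`, `value`) and `truth` (the spec parameters and curve).
#' @export
gen_growth_series <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  f <- growth_curve_fun(spec$family, spec$A, spec$k, spec$t0)
  lo <- max(1, spec$t0 - 5 / spec$k)
  hi <- spec$t0 + 8 / spec$k
  withr::with_seed(spec$seed, {
    age <- seq(lo, hi, length.out = spec$n)
    value <- f(age) + stats::rnorm(spec$n, 0, spec$sigma)
  })
  list(series = data.frame(age_days = age, value = value),
       truth = list(family = spec$family, A = spec$A, k = spec$k,
                    t0 = spec$t0, curve = f))
}

#' Generate a monotone attainment (count) series
#'
#' Emulates traits like ossified carpal numbers: a count that rises from 0
#' to an adult value, reaching it at a known attainment age.  Ossification
#' ages of the individual structures are evenly spread up to the
#' attainment age; observations are counts at sampled ages.
#'
#' @param adult_count Adult (asymptotic) integer count.
#' @param attain_age_days Age at which the count first equals
#'   `adult_count`.
#' @param n Number of observations.
#' @param max_age_days Last sampled age (defaults to 1.5 x attainment).
#' @param seed Integer seed.
#' @return List with `series` (data frame `age_days`, `count`) and `truth`.
#' @export
gen_attainment_series <- function(adult_count = 8, attain_age_days,
                                  n = 40, max_age_days = 1.5 * attain_age_days,
                                  seed = 1L) {
  stopifnot(adult_count > 0, attain_age_days > 0, max_age_days >= attain_age_days)
  onset <- attain_age_days * seq_len(adult_count) / adult_count
  withr::with_seed(seed, {
    age <- sort(stats::runif(n, 0, max_age_days))
  })
  age <- unique(c(age, attain_age_days, max_age_days))
  count <- vapply(age, function(t) sum(onset <= t), numeric(1))
  list(series = data.frame(age_days = age, count = count),
       truth = list(adult_count = adult_count,
                    attain_age_days = attain_age_days, onsets = onset))
}

#' Specification and generator for synthetic death-age cohorts
#'
#' Death ages follow a Gompertz mortality law with baseline hazard `a`
#' and shape `b` (hazard `a * exp(b * t)`), the standard model for adult
#' primate mortality.
#'
#' @param n Number of individuals.
#' @param a Baseline hazard rate (> 0, per day).
#' @param b Shape (> 0, per day).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1000, a = 2e-5, b = 3e-4, seed = 1L) {
  stopifnot(n >= 1, a > 0, b > 0)
  structure(list(n = as.integer(n), a = a, b = b, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @return `gen_survival_cohort()` returns a list with `death_ages`
#'   (days) and `truth` (parameters and the analytic median).
#' @export
gen_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ages <- withr::with_seed(spec$seed,
    flexsurv::rgompertz(spec$n, shape = spec$b, rate = spec$a))
  list(death_ages = ages,
       truth = list(a = spec$a, b = spec$b,
                    median = flexsurv::qgompertz(0.5, shape = spec$b,
                                                 rate = spec$a)))
}

#' Generate per-population event ages with known dispersion
#'
#' Emulates within-species variation in behavioural and life-history time
#' points observed across populations: each event has a true age and a
#' per-event coefficient of variation.  True CVs are lognormal — most
#' events vary little, a few vary a lot — parameterised by the 5th/95th
#' percentiles of the dispersion observed across human populations
#' (default band 0.01-0.13, capped at 0.3).
#'
#' @param n_events Number of events.
#' @param n_populations Populations observing each event.
#' @param cv_quantiles 5th and 95th percentiles of the per-event true CV
#'   distribution.
#' @param cv_cap Upper cap on true CVs.
#' @param age_range True event-age range (days).
#' @param seed Integer seed.
#' @return List with `ages` (data frame `event_id`, `population`,
#'   `age_days`) and `truth` (per-event true CV).
#' @export
gen_population_ages <- function(n_events = 30, n_populations = 8,
                                cv_quantiles = c(0.01, 0.13),
                                cv_cap = 0.3,
                                age_range = c(200, 20000), seed = 1L) {
  stopifnot(n_populations >= 2, cv_quantiles[1] > 0,
            cv_quantiles[2] > cv_quantiles[1], cv_cap < 1)
  sdlog <- diff(log(cv_quantiles)) / (2 * stats::qnorm(0.95))
  meanlog <- mean(log(cv_quantiles))
  withr::with_seed(seed, {
    mu <- exp(stats::runif(n_events, log(age_range[1]), log(age_range[2])))
    cv <- pmin(stats::rlnorm(n_events, meanlog, sdlog), cv_cap)
    ages <- lapply(seq_len(n_events), function(i) {
      x <- stats::rnorm(n_populations, mu[i], cv[i] * mu[i])
      pmax(x, mu[i] * 0.05)
    })
  })
  events <- sprintf("event_%03d", seq_len(n_events))
  list(ages = data.frame(
         event_id = rep(events, each = n_populations),
         population = rep(sprintf("pop_%02d", seq_len(n_populations)),
                          n_events),
         age_days = unlist(ages), stringsAsFactors = FALSE),
       truth = list(cv = stats::setNames(cv, events),
                    mean_age = stats::setNames(mu, events)))
}

#' Generate matched male/female event ages
#'
#' Emulates sex comparisons of developmental timing: male log ages follow
#' `intercept + slope * female_log_age` plus noise, optionally with
#' injected outlier events (a sex-specific timing shift).
#'
#' @param n_events Number of matched events.
#' @param slope,intercept Log-log relation between male and female ages.
#' @param sigma Residual sd (log-days).
#' @param outlier_events Indices of events shifted by `outlier_shift`.
#' @param outlier_shift Log-days added to male ages of outlier events.
#' @param seed Integer seed.
#' @return Data frame `event_id`, `female_age_days`, `male_age_days` plus
#'   a `truth` attribute.
#' @export
gen_sex_ages <- function(n_events = 60, slope = 1, intercept = 0,
                         sigma = 0.02, outlier_events = integer(0),
                         outlier_shift = 1, seed = 1L) {
  withr::with_seed(seed, {
    f <- sort(stats::runif(n_events, log(200), log(20000)))
    m <- intercept + slope * f + stats::rnorm(n_events, 0, sigma)
  })
  m[outlier_events] <- m[outlier_events] + outlier_shift
  out <- data.frame(event_id = sprintf("event_%03d", seq_len(n_events)),
                    female_age_days = exp(f), male_age_days = exp(m),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             outliers = outlier_events)
  out
}

#' Write a complete synthetic input bundle to disk
#'
#' Writes a time-point CSV (the dialect [read_timepoints()] parses), the
#' species config, and the generator ground truth as YAML, so an
#' end-to-end pipeline run has files to ingest and tests can compare
#' results against the serialized truth.
#'
#' @param dir Output directory (created if needed).
#' @param spec An [event_table_spec()].
#' @return Invisibly, the named list of written paths.
#' @export
write_synthetic_bundle <- function(dir, spec = event_table_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- gen_event_table(spec)
  tps <- event_table_to_timepoints(gen$table)
  paths <- list(timepoints = file.path(dir, "timepoints.csv"),
                truth = file.path(dir, "truth.yaml"))
  utils::write.csv(tps, paths$timepoints, row.names = FALSE)
  yaml::write_yaml(list(scores = as.list(gen$truth$scores),
                        alpha = as.list(gen$truth$alpha),
                        beta = as.list(gen$truth$beta),
                        gamma = gen$truth$gamma,
                        seed = spec$seed),
                   paths$truth)
  invisible(paths)
}
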