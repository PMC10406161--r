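#' Read and validate a pipeline run configuration
#'
#' YAML keys: `seed` (integer), either `simulate` (arguments to
#' [event_table_spec()]) or `inputs$timepoints` (CSV path); optional
#' `inputs$species_config`, `inputs$population_ages`,
#' `inputs$life_tables`; `imputation` (`max_iter`, `tol`);
#' `translation` (`from_species`, `to_species`, `ages_years`);
#' `survival_quantiles`; `output_dir`.  Referenced files must exist at
#' validation time, before any compute.
#'
#' @param path YAML config path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (as read from YAML).
#' @export
validate_run_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$simulate) && is.null(cfg$inputs$timepoints))
    stop("config error: either 'simulate' or 'inputs$timepoints' is required")
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) stop("config error: input file not found: ", p)
  cfg$imputation <- utils::modifyList(list(max_iter = 100, tol = 1e-6),
                                      cfg$imputation %||% list())
  cfg$translation <- utils::modifyList(
    list(from_species = "human",
         to_species = c("chimpanzee", "gorilla", "orangutan"),
         ages_years = c(1, 5, 15, 35, 68)),
    cfg$translation %||% list())
  cfg$survival_quantiles <- cfg$survival_quantiles %||% c(0.9, 0.8, 0.7)
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full translation pipeline
#'
#' Orchestrates ingest (or simulation) -> imputation -> event scale ->
#' translating-time fit -> heterochrony test -> cross-species
#' translation table, plus optional population-variation and survival
#' stages.  All numeric outputs are deterministic under the configured
#' seed; intermediates are written to the output directory as they are
#' produced, so a failing stage leaves earlier results on disk.
#'
#' @param config A `run_config` (or path to one).
#' @param output_dir Overrides the config's `output_dir`.
#' @return Invisibly, the report list (also written as `report.yaml`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out <- output_dir %||% config$output_dir %||% stop("no output_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  scfg <- run_stage("species_config",
    if (!is.null(config$inputs$species_config))
      read_species_config(config$inputs$species_config)
    else species_config())

  table <- run_stage("ingest", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      gen <- gen_event_table(do.call(event_table_spec, args))
      utils::write.csv(event_table_to_timepoints(gen$table),
                       file.path(out, "timepoints.csv"), row.names = FALSE)
      gen$table
    } else {
      parsed <- read_timepoints(config$inputs$timepoints, scfg)
      if (nrow(parsed$errors))
        utils::write.csv(parsed$errors, file.path(out, "row_errors.csv"),
                         row.names = FALSE)
      build_event_table(parsed$timepoints)
    }
  })

  completed <- run_stage("imputation",
    impute_missing(table, max_iter = config$imputation$max_iter,
                   tol = config$imputation$tol))
  write_event_table(completed, file.path(out, "event_table.csv"))

  scale <- run_stage("event_scale", compute_event_scale(completed))
  utils::write.csv(scale, file.path(out, "event_scale.csv"),
                   row.names = FALSE)

  fit <- run_stage("model_fit", fit_translating_time(completed, scale))
  het <- run_stage("heterochrony", {
    reduced <- fit_translating_time(completed, scale,
                                    include_event_type = FALSE)
    heterochrony_test(fit, reduced)
  })

  translations <- run_stage("translation", {
    tr <- config$translation
    from <- intersect(tr$from_species, fit$species)[1]
    tos <- intersect(tr$to_species, fit$species)
    if (is.na(from) || !length(tos))
      stop("translation species not present in the fitted model")
    do.call(rbind, lapply(tos, function(s)
      translate_age(fit, from, tr$ages_years * 365.25, s)))
  })
  utils::write.csv(translations, file.path(out, "translations.csv"),
                   row.names = FALSE)

  report <- list(
    seed = config$seed,
    n_events = nrow(completed$log_age),
    n_species = ncol(completed$log_age),
    imputation = attr(completed, "convergence"),
    fit = list(r_squared = fit$r_squared, f_statistic = fit$f_statistic,
               residual_df = fit$residual_df,
               reference_species = fit$reference_species),
    heterochrony = list(f = het$f, p_value = het$p_value,
                        df = as.list(het$df)))

  if (!is.null(config$inputs$population_ages)) {
    cvp <- run_stage("variation", cv_profile(
      utils::read.csv(config$inputs$population_ages,
                      stringsAsFactors = FALSE)))
    utils::write.csv(cvp, file.path(out, "cv_profile.csv"),
                     row.names = FALSE)
    report$variation <- list(max_cv = attr(cvp, "max_cv"),
                             band = as.list(attr(cvp, "band")))
  }

  if (!is.null(config$inputs$life_tables)) {
    report$survival <- run_stage("survival", {
      curves <- read_life_tables(config$inputs$life_tables)
      res <- lapply(names(curves), function(nm) {
        cv <- curves[[nm]]
        resc <- if (attr(cv, "species") %in% fit$species &&
                    attr(cv, "species") != fit$reference_species)
          rescale_survival(cv, fit, fit$reference_species) else cv
        qs <- vapply(config$survival_quantiles, function(p)
          tryCatch(survival_quantile_age(resc, p), error = function(e) NA_real_),
          numeric(1))
        stats::setNames(as.list(qs / 365.25),
                        paste0("age_years_at_", config$survival_quantiles))
      })
      stats::setNames(res, names(curves))
    })
  }

  yaml::write_yaml(report, file.path(out, "report.yaml"))
  saved <- list(fit = fit, table = completed, scale = scale,
                translations = translations, report = report)
  invisible(saved)
}

#' Serialize a fitted translating-time model to YAML
#'
#' Coefficients, reference levels and diagnostics in a plain-text,
#' human-diffable form.
#'
#' @param fit A `tt_fit`.
#' @param path Output YAML path.
#' @export
write_tt_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tt_fit"))
  cf <- stats::coef(fit$lm)
  yaml::write_yaml(list(
    coefficients = as.list(cf[!is.na(cf)]),
    dropped = names(cf)[is.na(cf)],
    reference_species = fit$reference_species,
    species = fit$species,
    type_weights = if (!is.null(fit$type_weights))
      as.list(as.numeric(fit$type_weights)) else NULL,
    diagnostics = list(r_squared = fit$r_squared,
                       f_statistic = fit$f_statistic,
                       residual_df = fit$residual_df)), path)
  invisible(path)
}
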