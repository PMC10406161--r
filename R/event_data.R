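#' Closed vocabulary of event types
#'
#' Developmental/aging processes a time point can be classified under.
#' These levels drive the heterochrony terms of the translating-time model.
#'
#' @return Character vector of the admissible `event_type` levels.
#' @export
event_types <- function() {
  c("body_growth", "brain_growth", "life_history", "structural_aging",
    "facial_structure", "locomotor_forelimb", "transcription", "behavior",
    "other")
}

#' Admissible age reference frames
#' @return Character vector of `age_frame` levels.
#' @export
age_frames <- function() {
  c("days_post_conception", "days_postnatal", "years_postnatal",
    "days_post_incubation")
}

#' Species configuration: gestation lengths and organoid offset
#'
#' Ages are analysed in days post conception, so postnatal ages need the
#' species' gestation length and organoid incubation days need an offset
#' placing day 0 of incubation on the conception axis.  Defaults ship with
#' the package (standard reference gestation lengths; organoid offset 0,
#' i.e. incubation days are used directly).
#'
#' @param gestation_days Named numeric vector (days), one entry per species
#'   label.  Merged over the shipped defaults; user entries win.
#' @param organoid_offset_days Scalar offset (days) added to organoid
#'   incubation-day ages.
#' @return An object of class `species_config`.
#' @export
species_config <- function(gestation_days = NULL, organoid_offset_days = NULL) {
  def <- yaml::read_yaml(system.file("extdata", "species_config.yaml",
                                     package = "transtime"))
  gest <- unlist(def$gestation_days)
  if (!is.null(gestation_days)) {
    stopifnot(is.numeric(gestation_days), !is.null(names(gestation_days)))
    gest[names(gestation_days)] <- gestation_days
  }
  if (any(gest <= 0)) stop("gestation lengths must be positive")
  off <- if (is.null(organoid_offset_days)) def$organoid_offset_days else organoid_offset_days
  structure(list(gestation_days = gest, organoid_offset_days = off),
            class = "species_config")
}

#' Read a species configuration from YAML
#'
#' @param path YAML file with keys `gestation_days` (map species -> days)
#'   and optionally `organoid_offset_days`.
#' @return A `species_config`.
#' @export
read_species_config <- function(path) {
  y <- yaml::read_yaml(path)
  species_config(gestation_days = unlist(y$gestation_days),
                 organoid_offset_days = y$organoid_offset_days)
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species configuration:", length(x$gestation_days), "species;",
      "organoid offset", x$organoid_offset_days, "days\n")
  invisible(x)
}

tp_required_cols <- function() {
  c("species", "event_id", "event_type", "age_value", "age_frame",
    "sex", "population", "environment", "provenance")
}

#' Convert ages to days post conception
#'
#' Maps an age in any supported reference frame onto the common
#' days-post-conception axis: postnatal frames add the species' gestation
#' length (years are converted at 365.25 days), organoid incubation days
#' add the configured offset.  Vectorised over all arguments.
#'
#' @param age_value Numeric age(s), positive except `days_postnatal`/
#'   `days_post_incubation` where 0 (birth / incubation onset) is allowed.
#' @param age_frame Frame label(s), see [age_frames()].
#' @param species Species label(s) present in `config`.
#' @param config A [species_config()].
#' @return Numeric vector of ages in days post conception (all > 0).
#' @export
to_days_post_conception <- function(age_value, age_frame, species, config) {
  stopifnot(inherits(config, "species_config"))
  bad_frame <- setdiff(unique(age_frame), age_frames())
  if (length(bad_frame))
    stop("unknown age_frame: ", paste(bad_frame, collapse = ", "))
  bad_sp <- setdiff(unique(species), names(config$gestation_days))
  if (length(bad_sp))
    stop("species without a gestation entry: ", paste(bad_sp, collapse = ", "))
  n <- max(length(age_value), length(age_frame), length(species))
  age_value <- rep_len(age_value, n)
  age_frame <- rep_len(age_frame, n)
  species <- rep_len(species, n)
  gest <- config$gestation_days[species]
  out <- ifelse(age_frame == "days_post_conception", age_value,
         ifelse(age_frame == "days_postnatal", age_value + gest,
         ifelse(age_frame == "years_postnatal", age_value * 365.25 + gest,
                age_value + config$organoid_offset_days)))
  if (any(out <= 0, na.rm = TRUE))
    stop("non-positive age after conversion to days post conception")
  unname(out)
}

validate_timepoints <- function(df, config) {
  errors <- character(0)
  err_rows <- integer(0)
  flag <- function(rows, msg) {
    err_rows <<- c(err_rows, rows)
    errors <<- c(errors, rep(msg, length(rows)))
  }
  bad <- which(!is.finite(df$age_value) | df$age_value < 0 |
                 (df$age_value == 0 &
                    !df$age_frame %in% c("days_postnatal", "days_post_incubation")))
  if (length(bad)) flag(bad, "non-positive or missing age_value")
  bad <- which(!df$age_frame %in% age_frames())
  if (length(bad)) flag(bad, "unknown age_frame")
  bad <- which(!df$event_type %in% event_types())
  if (length(bad)) flag(bad, "event_type outside the closed vocabulary")
  bad <- which(!df$species %in% names(config$gestation_days))
  if (length(bad)) flag(bad, "species without a config entry")
  bad <- which(df$provenance == "organoid" & df$age_frame != "days_post_incubation")
  if (length(bad)) flag(bad, "organoid time points must use days_post_incubation")
  list(rows = err_rows, messages = errors)
}

#' Read time points from CSV
#'
#' Parses a CSV whose header names the time-point fields (`species`,
#' `event_id`, `event_type`, `age_value`, `age_frame`, `sex`, `population`,
#' `environment`, `provenance`); extra columns are preserved as metadata.
#' Rows failing validation are dropped and reported, not fatal; a missing
#' mandatory column is a format error.
#'
#' @param path CSV file path.
#' @param config A [species_config()] covering every species in the file.
#' @return A list with `timepoints` (a `timepoint_df` data frame, row order
#'   preserved, with an added `age_dpc` column of days post conception) and
#'   `errors` (data frame with `row` and `message` for rejected rows).
#' @export
read_timepoints <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(tp_required_cols(), names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  as_timepoints(df, config)
}

#' Validate a data frame of time points
#'
#' @param df Data frame with the columns of [read_timepoints()].
#' @param config A [species_config()].
#' @return Same structure as [read_timepoints()].
#' @export
as_timepoints <- function(df, config) {
  stopifnot(inherits(config, "species_config"))
  v <- validate_timepoints(df, config)
  errdf <- data.frame(row = v$rows, message = v$messages,
                      stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(nrow(df)), unique(v$rows))
  out <- df[keep, , drop = FALSE]
  if (nrow(out)) {
    out$age_dpc <- to_days_post_conception(out$age_value, out$age_frame,
                                           out$species, config)
  } else {
    out$age_dpc <- numeric(0)
  }
  class(out) <- c("timepoint_df", "data.frame")
  list(timepoints = out, errors = errdf[order(errdf$row), , drop = FALSE])
}

#' Build a species-by-event table of log ages
#'
#' Aggregates time points into one cell per (event, species): the unweighted
#' mean of natural-log days post conception over all contributing time
#' points (pooled over sex and population by default; pass `sex` to build a
#' sex-specific table).  Cells with no observation are masked for
#' imputation.  Events observed in no species are dropped with a warning.
#'
#' @param tps A `timepoint_df` (from [read_timepoints()]/[as_timepoints()]).
#' @param sex Optional: restrict to one `sex` level before aggregating.
#' @return An `event_table`: list with `log_age` (events x species matrix,
#'   `NA` where unobserved), `observed` (logical mask), `event_type`
#'   (named by event), and `n_obs` (contributing time-point counts).
#' @export
build_event_table <- function(tps, sex = NULL) {
  stopifnot(inherits(tps, "timepoint_df"))
  if (!is.null(sex)) tps <- tps[tps$sex %in% sex, , drop = FALSE]
  if (length(unique(tps$species)) < 2 || length(unique(tps$event_id)) < 3)
    stop("need >= 2 species and >= 3 events to build an event table")
  events <- sort(unique(tps$event_id))
  species <- sort(unique(tps$species))
  log_age <- matrix(NA_real_, length(events), length(species),
                    dimnames = list(events, species))
  n_obs <- matrix(0L, length(events), length(species),
                  dimnames = list(events, species))
  la <- log(tps$age_dpc)
  cell <- tapply(la, list(factor(tps$event_id, events),
                          factor(tps$species, species)), mean)
  cnt <- tapply(la, list(factor(tps$event_id, events),
                         factor(tps$species, species)), length)
  log_age[] <- cell
  n_obs[] <- ifelse(is.na(cnt), 0L, cnt)
  # event_type: modal type among contributing time points
  et <- vapply(events, function(e) {
    tt <- tps$event_type[tps$event_id == e]
    names(sort(table(tt), decreasing = TRUE))[1]
  }, character(1))
  new_event_table(log_age, event_type = et)
}

new_event_table <- function(log_age, event_type,
                            imputed = NULL) {
  stopifnot(is.matrix(log_age), length(event_type) == nrow(log_age))
  observed <- !is.na(log_age)
  empty <- rowSums(observed) == 0
  if (any(empty)) {
    warning(sum(empty), " event(s) observed in no species dropped")
    log_age <- log_age[!empty, , drop = FALSE]
    observed <- observed[!empty, , drop = FALSE]
    event_type <- event_type[!empty]
    if (!is.null(imputed)) imputed <- imputed[!empty, , drop = FALSE]
  }
  structure(list(log_age = log_age, observed = observed,
                 event_type = stats::setNames(unname(event_type),
                                              rownames(log_age)),
                 imputed = imputed),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table:", nrow(x$log_age), "events x", ncol(x$log_age),
      "species;", sum(!x$observed), "unobserved cell(s)",
      if (!is.null(x$imputed)) "(imputed)" else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.event_table <- function(x, ...) {
  long <- expand.grid(event_id = rownames(x$log_age),
                      species = colnames(x$log_age),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$log_age <- as.vector(x$log_age)
  long$observed <- as.vector(x$observed)
  long$event_type <- x$event_type[long$event_id]
  long[!is.na(long$log_age), , drop = FALSE]
}

#' Write / read an event table as CSV (lossless round trip)
#'
#' Long-format CSV with columns `event_id`, `species`, `log_age`,
#' `observed`, `event_type`.  `log_age` is written with full precision so
#' a write/read round trip is bit-identical.
#'
#' @param table An `event_table`.
#' @param path Output CSV path.
#' @export
write_event_table <- function(table, path) {
  # keep unobserved cells as empty rows so the grid order round-trips
  long <- expand.grid(event_id = rownames(table$log_age),
                      species = colnames(table$log_age),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$log_age <- ifelse(is.na(as.vector(table$log_age)), "",
                         sprintf("%.17g", as.vector(table$log_age)))
  long$observed <- as.vector(table$observed)
  long$event_type <- table$event_type[long$event_id]
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_event_table
#' @return `read_event_table()` returns the `event_table`.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  events <- unique(df$event_id)
  species <- unique(df$species)
  log_age <- matrix(NA_real_, length(events), length(species),
                    dimnames = list(events, species))
  log_age[cbind(match(df$event_id, events), match(df$species, species))] <-
    df$log_age
  obs <- matrix(FALSE, length(events), length(species),
                dimnames = list(events, species))
  obs[cbind(match(df$event_id, events), match(df$species, species))] <-
    df$observed
  et <- df$event_type[!duplicated(df$event_id)]
  names(et) <- df$event_id[!duplicated(df$event_id)]
  tab <- new_event_table(log_age, event_type = et[events])
  if (any(!obs & !is.na(log_age))) {
    tab$observed <- obs
    tab$imputed <- !obs & !is.na(log_age)
  }
  tab
}
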