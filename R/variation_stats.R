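#' Coefficient-of-variation profile across populations
#'
#' Quantifies within-species variation in event timing: for every event
#' observed in at least two populations, the coefficient of variation
#' (sd / mean) of the linear-scale ages, with the empirical 5th/95th
#' percentile band and the maximum across events.  The band is intended
#' as a guide to the plausible spread of extrapolated age alignments.
#'
#' @param ages Data frame with columns `event_id`, `population`,
#'   `age_days`.
#' @return A `cv_profile`: data frame `event_id`, `n_populations`,
#'   `mean_age_days`, `cv`, with attributes `band` (5th/95th
#'   percentiles), `max_cv` and `excluded` (single-population events).
#' @export
cv_profile <- function(ages) {
  stopifnot(all(c("event_id", "population", "age_days") %in% names(ages)),
            all(ages$age_days > 0))
  np <- tapply(ages$population, ages$event_id,
               function(p) length(unique(p)))
  excluded <- names(np)[np < 2]
  if (length(excluded))
    message(length(excluded), " single-population event(s) excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  keep <- ages$event_id %in% names(np)[np >= 2]
  ages <- ages[keep, , drop = FALSE]
  if (!nrow(ages)) stop("no event observed in >= 2 populations")
  cv <- tapply(ages$age_days, ages$event_id,
               function(x) stats::sd(x) / mean(x))
  mu <- tapply(ages$age_days, ages$event_id, mean)
  out <- data.frame(event_id = names(cv),
                    n_populations = as.integer(np[names(cv)]),
                    mean_age_days = as.numeric(mu),
                    cv = as.numeric(cv), stringsAsFactors = FALSE)
  attr(out, "band") <- stats::quantile(out$cv, c(0.05, 0.95), names = FALSE)
  attr(out, "max_cv") <- max(out$cv)
  attr(out, "excluded") <- excluded
  class(out) <- c("cv_profile", "data.frame")
  out
}

#' Sex-slope regression of matched event ages
#'
#' Ordinary least squares of male log age on female log age over events
#' observed in both sexes.  A slope near 1 with intercept near 0 means
#' the sexes proceed through development and aging at the same pace;
#' events with |studentized residual| > `flag_threshold` are flagged as
#' deviating (e.g. protracted male body growth).  Because OLS is not
#' symmetric in its axes, the swapped-axis slope is also reported.
#'
#' @param ages Data frame with `event_id`, `female_age_days`,
#'   `male_age_days` (>= 5 matched events).
#' @param flag_threshold Studentized-residual cutoff for deviation flags.
#' @return A `sex_slope_fit`: list with `slope`, `se`, `intercept`,
#'   `r_squared`, `swapped_slope`, `flagged` (event ids), and `events`
#'   (per-event residual table).
#' @export
sex_slope <- function(ages, flag_threshold = 3) {
  stopifnot(all(c("event_id", "female_age_days", "male_age_days")
                %in% names(ages)))
  if (nrow(ages) < 5) stop("need >= 5 matched events")
  f <- log(ages$female_age_days)
  m <- log(ages$male_age_days)
  fit <- stats::lm(m ~ f)
  sm <- quiet_summary(fit)
  rs <- stats::rstudent(fit)
  flagged <- ages$event_id[abs(rs) > flag_threshold]
  swapped <- unname(stats::coef(stats::lm(f ~ m))[2])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 swapped_slope = swapped,
                 flagged = flagged,
                 events = data.frame(event_id = ages$event_id,
                                     studentized_residual = unname(rs),
                                     stringsAsFactors = FALSE),
                 lm = fit),
            class = "sex_slope_fit")
}

#' @export
print.sex_slope_fit <- function(x, ...) {
  cat(sprintf("Sex slope: %.3f (SE %.4f), intercept %.3f, R^2 %.3f; %d flagged\n",
              x$slope, x$se, x$intercept, x$r_squared, length(x$flagged)))
  invisible(x)
}
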