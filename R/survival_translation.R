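#' Build a survival curve from death ages or a life table
#'
#' From death ages, the empirical fraction surviving *up to* each
#' distinct age is computed: `S(a) = P(death age >= a)`, so the curve
#' starts at 1 at the first grid age.  Alternatively a published
#' life-table of `(age_days, fraction)` rows is validated (fractions in
#' \[0, 1\], non-increasing) and passed through.  No censoring model is
#' applied: inputs are complete cohorts or life-table fractions.
#'
#' @param death_ages Numeric death ages in days (used when `life_table`
#'   is `NULL`).
#' @param life_table Data frame with `age_days`, `fraction`.
#' @param species,sex Metadata carried on the curve.
#' @return A `survival_curve`: data frame `age_days`, `fraction`, with
#'   `species`, `sex` and `source` attributes.
#' @export
build_survival <- function(death_ages = NULL, life_table = NULL,
                           species = "unknown", sex = "pooled") {
  if (is.null(life_table)) {
    stopifnot(length(death_ages) >= 1, all(death_ages > 0))
    ages <- sort(unique(death_ages))
    frac <- vapply(ages, function(a) mean(death_ages >= a), numeric(1))
    out <- data.frame(age_days = ages, fraction = frac)
    src <- "cohort"
  } else {
    stopifnot(all(c("age_days", "fraction") %in% names(life_table)))
    out <- life_table[order(life_table$age_days),
                      c("age_days", "fraction"), drop = FALSE]
    bad <- which(diff(out$fraction) > 0)
    if (length(bad))
      stop("life table fractions increase at row(s): ",
           paste(bad + 1, collapse = ", "))
    if (any(out$fraction < 0 | out$fraction > 1))
      stop("fractions must lie in [0, 1]")
    src <- "life_table"
  }
  structure(out, species = species, sex = sex, source = src,
            class = c("survival_curve", "data.frame"))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve (", attr(x, "species"), ", ", attr(x, "sex"), "): ",
      nrow(x), " grid ages, S in [", signif(min(x$fraction), 3), ", ",
      signif(max(x$fraction), 3), "]\n", sep = "")
  invisible(x)
}

#' Evaluate a survival curve at arbitrary ages
#'
#' Step evaluation under the "surviving up to age" convention:
#' `S(a)` is the fraction at the largest grid age `<= a` whose value is
#' still valid at `a` (1 before the first grid age).
#'
#' @param curve A `survival_curve`.
#' @param age_days Ages to evaluate at.
#' @return Numeric vector of surviving fractions.
#' @export
survival_at <- function(curve, age_days) {
  stopifnot(inherits(curve, "survival_curve"))
  # between grid ages the cohort that reached the previous age minus
  # those whose death age equals it is still alive: use the next grid
  # value for strictly-greater ages, the grid value at exact hits
  vapply(age_days, function(a) {
    if (a <= curve$age_days[1]) return(1)
    i <- findInterval(a, curve$age_days)
    if (curve$age_days[i] == a) curve$fraction[i]
    else if (i < nrow(curve)) curve$fraction[i + 1]
    else 0
  }, numeric(1))
}

#' Age at which survival first drops to a given fraction
#'
#' Returns the smallest grid age whose surviving fraction is `<= p`
#' (the first crossing of the step curve).  `p = 1` returns the first
#' grid age.
#'
#' @param curve A `survival_curve`.
#' @param p Fraction in (0, 1].
#' @return Age in days.
#' @export
survival_quantile_age <- function(curve, p) {
  stopifnot(inherits(curve, "survival_curve"), p > 0, p <= 1)
  i <- which(curve$fraction <= p)
  if (!length(i))
    stop("follow-up insufficient: curve never drops to ", p,
         " (final fraction ", signif(min(curve$fraction), 3), ")")
  curve$age_days[i[1]]
}

#' Re-express a survival curve on another species' age axis
#'
#' Every grid age is translated with [translate_age()] under the fitted
#' translating-time model; fractions are untouched, and because the
#' translation is monotone in age the curve stays a valid survival
#' curve.  Grid ages whose event-scale solution falls outside \[0, 1\]
#' are kept but flagged as extrapolated.
#'
#' @param curve A `survival_curve`.
#' @param fit A `tt_fit` containing both species.
#' @param to_species Target species label.
#' @return A `survival_curve` on the target species' age axis, with an
#'   `extrapolated` column.
#' @export
rescale_survival <- function(curve, fit, to_species) {
  stopifnot(inherits(curve, "survival_curve"))
  from <- attr(curve, "species")
  tr <- translate_age(fit, from, curve$age_days, to_species)
  out <- data.frame(age_days = tr$to_age_days, fraction = curve$fraction,
                    extrapolated = tr$extrapolated)
  structure(out, species = to_species, sex = attr(curve, "sex"),
            source = attr(curve, "source"),
            translated_from = from,
            class = c("survival_curve", "data.frame"))
}

#' Read a life table CSV
#'
#' Expected columns: `age_days`, `fraction`, `species`, `sex`; one curve
#' per (species, sex) combination.
#'
#' @param path CSV path.
#' @return Named list of `survival_curve` objects.
#' @export
read_life_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age_days", "fraction", "species", "sex") %in% names(df)))
  key <- interaction(df$species, df$sex, drop = TRUE)
  lapply(split(df, key), function(d)
    build_survival(life_table = d, species = d$species[1], sex = d$sex[1]))
}

#' @export
plot.survival_curve <- function(x, ..., add = FALSE, col = 1) {
  if (!add)
    graphics::plot(x$age_days / 365.25, x$fraction, type = "s", col = col,
                   xlab = "age (years)", ylab = "fraction surviving",
                   ylim = c(0, 1), ...)
  else
    graphics::lines(x$age_days / 365.25, x$fraction, type = "s", col = col)
  invisible(x)
}
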