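# noise-free oracle data legitimately fit perfectly; keep lm summaries quiet
muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

quiet_summary <- function(fit) muffle_perfect_fit(summary(fit))

#' Fit the translating-time model
#'
#' Least-squares fit of natural-log age (days post conception) on the
#' event scale, species, event type, their full factorial interaction and
#' a shared quadratic scale term:
#'
#' `log(age) ~ scale * species * event_type + scale^2`
#'
#' Factors use treatment coding; the reference species is `"human"` when
#' present (alignments are conventionally expressed against humans).
#' Event-type terms can be dropped (`include_event_type = FALSE`) to build
#' the reduced model of [heterochrony_test()].  Rank-deficient interaction
#' columns (an event type observed in a single species) are dropped by the
#' fitter with a warning.
#'
#' @param table A completed `event_table`.
#' @param scale The matching [compute_event_scale()] result.
#' @param include_event_type Include event-type main and interaction terms.
#' @param reference_species Treatment-coding reference level.
#' @return A `tt_fit`: the underlying `lm`, the model frame, R-squared,
#'   overall F, residual df, reference levels, and the event-type
#'   frequency weights used for marginal (individual-level) predictions.
#' @export
fit_translating_time <- function(table, scale, include_event_type = TRUE,
                                 reference_species = "human") {
  stopifnot(inherits(table, "event_table"), inherits(scale, "event_scale"))
  if (anyNA(table$log_age))
    stop("table has unobserved cells; run impute_missing() first")
  if (ncol(table$log_age) < 2) stop("need >= 2 species")
  sc <- stats::setNames(scale$score, scale$event_id)
  df <- expand.grid(event_id = rownames(table$log_age),
                    species = colnames(table$log_age),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$log_age <- as.vector(table$log_age)
  df$score <- unname(sc[df$event_id])
  df$event_type <- unname(table$event_type[df$event_id])
  sp_levels <- colnames(table$log_age)
  if (reference_species %in% sp_levels)
    sp_levels <- c(reference_species, setdiff(sp_levels, reference_species))
  df$species <- factor(df$species, levels = sp_levels)
  if (include_event_type && length(unique(df$event_type)) < 2) {
    warning("single event type present; fitting without event-type terms")
    include_event_type <- FALSE
  }
  if (include_event_type) {
    df$event_type <- factor(df$event_type)
    form <- log_age ~ score * species * event_type + I(score^2)
  } else {
    form <- log_age ~ score * species + I(score^2)
  }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit)))
    warning("rank-deficient design: ", sum(is.na(stats::coef(fit))),
            " interaction column(s) dropped")
  sm <- quiet_summary(fit)
  tw <- if (include_event_type) {
    tab <- table(df$event_type)
    tab / sum(tab)
  } else NULL
  structure(list(lm = fit, data = df,
                 include_event_type = include_event_type,
                 reference_species = sp_levels[1],
                 species = sp_levels,
                 type_weights = tw,
                 r_squared = sm$r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 residual_df = fit$df.residual),
            class = "tt_fit")
}

#' @export
print.tt_fit <- function(x, ...) {
  cat("Translating-time fit:", length(x$species), "species,",
      nrow(x$data), "cells; R^2 =", signif(x$r_squared, 4),
      ", F =", signif(x$f_statistic, 4),
      "on", x$residual_df, "residual df\n")
  invisible(x)
}

# model-matrix prediction robust to NA (dropped) coefficients
predict_tt <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$lm))
  mm <- stats::model.matrix(tt, newdata, contrasts.arg = fit$lm$contrasts,
                            xlev = fit$lm$xlevels)
  beta <- stats::coef(fit$lm)
  beta[is.na(beta)] <- 0
  drop(mm %*% beta)
}

# marginal design row at a given scale value for one species:
# event-type dummies averaged with observed frequency weights
marginal_row <- function(fit, species, score, event_type = "marginal") {
  if (!fit$include_event_type || identical(event_type, "none")) {
    nd <- data.frame(score = score, species = species)
    tt <- stats::delete.response(stats::terms(fit$lm))
    return(stats::model.matrix(tt, nd, contrasts.arg = fit$lm$contrasts,
                               xlev = fit$lm$xlevels))
  }
  types <- names(fit$type_weights)
  if (identical(event_type, "marginal")) {
    w <- as.numeric(fit$type_weights)
  } else {
    if (!event_type %in% types) stop("unknown event_type: ", event_type)
    w <- as.numeric(types == event_type)
  }
  tt <- stats::delete.response(stats::terms(fit$lm))
  rows <- lapply(types, function(ty)
    stats::model.matrix(tt, data.frame(score = score, species = species,
                                       event_type = ty),
                        contrasts.arg = fit$lm$contrasts,
                        xlev = fit$lm$xlevels))
  out <- rows[[1]] * w[1]
  for (i in seq_along(rows)[-1]) out <- out + rows[[i]] * w[i]
  out
}

#' Per-species quadratic age curve implied by a fit
#'
#' Collapses a `tt_fit` onto one species' marginal curve
#' `log(age) = A + B * E + gamma * E^2`, with event-type effects averaged
#' using their observed frequencies (translation operates at the
#' individual level, not per organ system).
#'
#' @param fit A `tt_fit`.
#' @param species Species label present in the fit.
#' @param event_type `"marginal"` (default), or a specific event-type
#'   level to get that process' own curve.
#' @return List with `intercept` (A), `slope` (B), `quad` (gamma).
#' @export
species_curve <- function(fit, species, event_type = "marginal") {
  stopifnot(inherits(fit, "tt_fit"))
  if (!species %in% fit$species) stop("species not in fit: ", species)
  beta <- stats::coef(fit$lm)
  beta[is.na(beta)] <- 0
  r0 <- marginal_row(fit, species, 0, event_type)
  r1 <- marginal_row(fit, species, 1, event_type)
  A <- drop(r0 %*% beta)
  gamma <- unname(beta["I(score^2)"])
  B <- drop(r1 %*% beta) - A - gamma
  list(intercept = unname(A), slope = unname(B), quad = gamma)
}

#' Marginal species slopes with standard errors
#'
#' The species' marginal event-scale slope `B_s` as a linear combination
#' of fitted coefficients, with its standard error from the coefficient
#' covariance.  Used for parameter-recovery checks against generator
#' truth.
#'
#' @param fit A `tt_fit`.
#' @return Data frame with `species`, `slope`, `se`.
#' @export
species_slopes <- function(fit) {
  stopifnot(inherits(fit, "tt_fit"))
  beta <- stats::coef(fit$lm)
  ok <- !is.na(beta)
  V <- muffle_perfect_fit(stats::vcov(fit$lm))
  out <- lapply(fit$species, function(s) {
    cvec <- marginal_row(fit, s, 1) - marginal_row(fit, s, 0)
    cvec[, "I(score^2)"] <- 0
    b <- drop(cvec[, ok, drop = FALSE] %*% beta[ok])
    se <- sqrt(drop(cvec[, ok, drop = FALSE] %*% V %*% t(cvec[, ok, drop = FALSE])))
    data.frame(species = s, slope = b, se = se, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Solve a log age back to its event-scale score
#'
#' Inverts the species' quadratic curve: solves
#' `quad * E^2 + B * E + (A - log_age) = 0` on the branch where predicted
#' age increases with the scale (the developmental branch).  Uses the
#' numerically stable quadratic form; a zero quadratic coefficient reduces
#' to linear inversion.  Scores outside \[0, 1\] are returned but flagged
#' as extrapolation.
#'
#' @param fit A `tt_fit`.
#' @param species Species label.
#' @param log_age Natural-log age(s) in days post conception.
#' @param event_type `"marginal"` or a specific level (see
#'   [species_curve()]).
#' @return Data frame with `score` and `extrapolated`.
#' @export
invert_to_scale <- function(fit, species, log_age, event_type = "marginal") {
  cv <- species_curve(fit, species, event_type)
  A <- cv$intercept; B <- cv$slope; g <- cv$quad
  if (B <= 0) stop("non-increasing fitted curve for ", species)
  score <- if (abs(g) < 1e-12) {
    (log_age - A) / B
  } else {
    D <- B^2 - 4 * g * (A - log_age)
    if (any(D < 0)) {
      apex <- A - B^2 / (4 * g)
      stop("no real solution; attainable log-age bound for ", species,
           " is ", signif(apex, 6))
    }
    # increasing-branch root, cancellation-free form
    2 * (A - log_age) / (-B - sqrt(D))
  }
  data.frame(score = score, extrapolated = score < 0 | score > 1)
}

#' Translate an age from one species to another
#'
#' Solves the source species' age back to its event-scale score and
#' predicts the age of the same score in the target species, on each
#' species' marginal (individual-level) curve.  Same-species translation
#' returns the input exactly.
#'
#' @param fit A `tt_fit`.
#' @param from_species,to_species Species labels present in the fit.
#' @param age_days Age(s) in days post conception.
#' @return A `translation_result` data frame: `from_species`,
#'   `from_age_days`, `score`, `extrapolated`, `to_species`,
#'   `to_age_days`.
#' @export
translate_age <- function(fit, from_species, age_days, to_species) {
  stopifnot(inherits(fit, "tt_fit"), all(age_days > 0))
  if (!all(c(from_species, to_species) %in% fit$species))
    stop("both species must be in the fit")
  if (from_species == to_species) {
    inv <- invert_to_scale(fit, from_species, log(age_days))
    out_age <- age_days
  } else {
    inv <- invert_to_scale(fit, from_species, log(age_days))
    cv <- species_curve(fit, to_species)
    out_age <- exp(cv$intercept + cv$slope * inv$score +
                     cv$quad * inv$score^2)
  }
  out <- data.frame(from_species = from_species, from_age_days = age_days,
                    score = inv$score, extrapolated = inv$extrapolated,
                    to_species = to_species, to_age_days = out_age,
                    stringsAsFactors = FALSE)
  class(out) <- c("translation_result", "data.frame")
  out
}

#' Test for heterochrony (event-type timing shifts)
#'
#' Nested-model F test of the event-type main and interaction terms:
#' compares the full translating-time fit against the reduced fit without
#' event-type factors on residual sums of squares.  A significant result
#' means some processes (e.g. carpal ossification) run on shifted
#' timetables in some species.
#'
#' @param full `tt_fit` with event-type terms.
#' @param reduced `tt_fit` without them, fitted to the same cells.
#' @return List with `f`, `p_value`, `df`, and `type_shift` (mean reduced
#'   residual by event type, the direction of each process' deviation).
#' @export
heterochrony_test <- function(full, reduced) {
  stopifnot(inherits(full, "tt_fit"), inherits(reduced, "tt_fit"))
  if (!full$include_event_type || reduced$include_event_type)
    stop("'full' must include event-type terms and 'reduced' must not")
  if (nrow(full$data) != nrow(reduced$data))
    stop("models were not fitted to the same cells")
  a <- stats::anova(reduced$lm, full$lm)
  if (is.na(a$Df[2]) || a$Df[2] == 0)
    stop("designs are identical; F test undefined")
  shift <- tapply(stats::residuals(reduced$lm), full$data$event_type, mean)
  list(f = a$F[2], p_value = a$`Pr(>F)`[2],
       df = c(a$Df[2], a$Res.Df[2]),
       type_shift = shift)
}

#' Align two species' matched log ages by regression
#'
#' Ordinary least squares of one species' (or tissue's) log ages on
#' another's, optionally with a quadratic term and an extra covariate —
#' the form used to cross-check machine-learning age transfers against
#' event-scale alignments and to compare organoid-derived with
#' individual-derived time points.
#'
#' @param x,y Matched natural-log ages (predictor, response).
#' @param quadratic Add `x^2` to the design.
#' @param covariate Optional factor/numeric covariate (e.g. tissue type
#'   in vivo vs in vitro, or an ML-derived age term).
#' @return List with `slope`, `intercept`, `r_squared`, `f_statistic`,
#'   and, when a covariate is given, its `estimate`, `t` and `p`.
#' @export
two_species_alignment <- function(x, y, quadratic = FALSE, covariate = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  df <- data.frame(x = x, y = y)
  form <- y ~ x
  if (quadratic) form <- stats::update(form, . ~ . + I(x^2))
  if (!is.null(covariate)) {
    df$cov <- covariate
    form <- stats::update(form, . ~ . + cov)
  }
  fit <- stats::lm(form, data = df)
  sm <- quiet_summary(fit)
  out <- list(slope = unname(stats::coef(fit)["x"]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              f_statistic = unname(sm$fstatistic[1]),
              lm = fit)
  if (!is.null(covariate)) {
    cr <- sm$coefficients[grep("^cov", rownames(sm$coefficients))[1], ]
    out$estimate <- unname(cr[1])
    out$t <- unname(cr[3])
    out$p <- unname(cr[4])
  }
  out
}
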