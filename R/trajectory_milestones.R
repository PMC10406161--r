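#' Fit a nonlinear growth curve
#'
#' Fits sigmoidal families to an (age, value) series by least squares —
#' logistic `A / (1 + exp(-k (t - t0)))` and Gompertz
#' `A * exp(-exp(-k (t - t0)))` — and returns the lowest-AIC fit.
#' Starting values come from the data (asymptote near the maximum,
#' inflection near the half-maximum age).  If no parametric family
#' converges (or the series is not increasing), a monotone fallback is
#' returned with a warning: isotonic regression interpolated linearly,
#' with the asymptote at the largest fitted value.
#'
#' @param age,value Numeric vectors (>= 6 points, positive ages).
#' @param families Parametric families to try.
#' @return A `growth_fit`: `family`, `parameters` (A, k, t0 for
#'   parametric fits), `asymptote`, `rss`, `aic`, and `curve` (the fitted
#'   function of age).
#' @export
fit_growth <- function(age, value, families = c("logistic", "gompertz")) {
  stopifnot(length(age) == length(value), length(age) >= 6, all(age > 0))
  o <- order(age)
  age <- age[o]; value <- value[o]
  if (stats::sd(value) == 0) {
    warning("constant series; degenerate flat fit")
    return(structure(list(family = "constant",
                          parameters = c(A = value[1]),
                          asymptote = value[1], rss = 0, aic = -Inf,
                          degenerate = TRUE,
                          curve = local({v <- value[1]; function(t) rep(v, length(t))})),
                     class = "growth_fit"))
  }
  fits <- list()
  for (fam in families) {
    A0 <- max(value)
    t00 <- age[which.min(abs(value - A0 / 2))]
    k0 <- 4 / max(diff(range(age)) / 4, 1e-8)
    form <- switch(fam,
      logistic = value ~ A / (1 + exp(-k * (age - t0))),
      gompertz = value ~ A * exp(-exp(-k * (age - t0))))
    f <- tryCatch(
      minpack.lm::nlsLM(form, start = list(A = A0, k = k0, t0 = t00),
                        lower = c(A = 1e-8, k = 1e-8, t0 = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[fam]] <- f
  }
  increasing <- stats::coef(stats::lm(value ~ age))[2] > 0
  if (!length(fits) || !increasing) {
    warning("no parametric growth fit; falling back to a monotone spline")
    iso <- stats::isoreg(age, value)
    yf <- iso$yf
    curve <- stats::approxfun(age, yf, rule = 2)
    return(structure(list(family = "monotone_spline", parameters = NULL,
                          asymptote = max(yf),
                          rss = sum((yf - value)^2), aic = NA_real_,
                          curve = curve),
                     class = "growth_fit"))
  }
  aics <- vapply(fits, stats::AIC, numeric(1))
  best <- names(which.min(aics))
  cf <- stats::coef(fits[[best]])
  structure(list(family = best, parameters = cf, asymptote = unname(cf["A"]),
                 rss = sum(stats::residuals(fits[[best]])^2),
                 aic = unname(aics[best]),
                 curve = growth_curve_fun(best, cf["A"], cf["k"], cf["t0"])),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth fit (", x$family, "): asymptote ", signif(x$asymptote, 5),
      if (!is.na(x$aic)) paste0(", AIC ", signif(x$aic, 5)), "\n", sep = "")
  invisible(x)
}

#' Age at which a growth curve reaches a percentage of its asymptote
#'
#' Returns the smallest age where the fitted curve reaches
#' `(pct/100) * asymptote`.  Because sigmoids approach their asymptote
#' only in the limit, `pct = 100` is operationalised as
#' `(1 - tol) * asymptote` (default `tol = 0.01`).  Parametric families
#' are inverted in closed form; the monotone fallback is inverted on its
#' interpolant.
#'
#' @param fit A `growth_fit`.
#' @param pct Percentage of the asymptote, in (0, 100].
#' @param tol Attainment tolerance used for `pct = 100`.
#' @return Age (same units as the fitted series).
#' @export
milestone_age <- function(fit, pct, tol = 0.01) {
  stopifnot(inherits(fit, "growth_fit"), pct > 0, pct <= 100)
  frac <- if (pct == 100) 1 - tol else pct / 100
  target <- frac * fit$asymptote
  if (fit$family == "logistic") {
    p <- fit$parameters
    return(unname(p["t0"] - log(1 / frac - 1) / p["k"]))
  }
  if (fit$family == "gompertz") {
    p <- fit$parameters
    return(unname(p["t0"] - log(-log(frac)) / p["k"]))
  }
  if (fit$family == "constant") return(NA_real_)
  # monotone interpolant: first crossing on a fine grid, refined exactly
  env <- environment(fit$curve)
  xs <- env$x %||% NULL
  if (is.null(xs)) stop("cannot invert this fit")
  ys <- fit$curve(xs)
  if (max(ys) < target) stop("threshold above the curve maximum")
  i <- which(ys >= target)[1]
  if (i == 1) return(xs[1])
  xs[i - 1] + (target - ys[i - 1]) / (ys[i] - ys[i - 1]) * (xs[i] - xs[i - 1])
}

#' Extract milestone ages for several thresholds
#'
#' @param fit A `growth_fit`.
#' @param pcts Percentages of the adult (asymptotic) value.
#' @param tol See [milestone_age()].
#' @return Data frame `pct`, `age` (non-decreasing in `pct`).
#' @export
milestone_set <- function(fit, pcts = c(90, 100), tol = 0.01) {
  age <- vapply(sort(pcts), milestone_age, numeric(1), fit = fit, tol = tol)
  data.frame(pct = sort(pcts), age = age)
}

#' Age of the peak of a smooth trajectory
#'
#' Fits a smoothing spline (smoothness chosen by generalized
#' cross-validation unless `spar` is given) and returns the age of its
#' maximum on a fine grid.  A maximum at the domain boundary is flagged
#' as censored — the true peak may lie outside the observed range.
#'
#' @param age,value Numeric vectors (>= 5 points).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @param grid_n Evaluation grid size.
#' @return List with `peak_age`, `peak_value`, `boundary` (censored-peak
#'   flag).
#' @export
peak_age <- function(age, value, spar = NULL, grid_n = 2000) {
  stopifnot(length(age) == length(value), length(age) >= 5)
  ss <- if (is.null(spar)) stats::smooth.spline(age, value, cv = FALSE)
        else stats::smooth.spline(age, value, spar = spar)
  grid <- seq(min(age), max(age), length.out = grid_n)
  yhat <- stats::predict(ss, grid)$y
  i <- which.max(yhat)
  list(peak_age = grid[i], peak_value = yhat[i],
       boundary = i == 1L || i == grid_n)
}

#' Age at which a monotone count series attains its adult value
#'
#' Counts (e.g. ossified carpal bones) are fitted with isotonic
#' regression and the smallest *observed* age where the fitted curve
#' reaches `adult_value - 0.5` (count rounding) is returned.  Counts are
#' step-valued, so no interpolation between observation ages is applied
#' — a step from 0 to the adult value at age `a` attains at exactly `a`.
#' Extrapolation beyond the observed age range is refused.
#'
#' @param age Observation ages.
#' @param count Non-negative integer counts.
#' @param adult_value Adult (target) count, > 0.
#' @return Attainment age (same units as `age`).
#' @export
attainment_age <- function(age, count, adult_value) {
  stopifnot(length(age) == length(count), adult_value > 0,
            all(count >= 0), all(count == round(count)))
  o <- order(age)
  age <- age[o]; count <- count[o]
  iso <- stats::isoreg(age, count)
  yf <- iso$yf
  target <- adult_value - 0.5
  if (max(yf) < target)
    stop("adult value ", adult_value, " not reached within the data range; ",
         "refusing to extrapolate")
  age[which(yf >= target)[1]]
}

#' Export milestones as time-point rows
#'
#' @param milestones Data frame from [milestone_set()].
#' @param species,event_prefix,event_type Metadata for the minted rows.
#' @return Data frame in the [read_timepoints()] column layout (ages in
#'   days post conception).
#' @export
milestones_to_timepoints <- function(milestones, species,
                                     event_prefix = "growth",
                                     event_type = "body_growth") {
  data.frame(species = species,
             event_id = sprintf("%s_pct%d", event_prefix, milestones$pct),
             event_type = event_type, age_value = milestones$age,
             age_frame = "days_post_conception", sex = "pooled",
             population = "trajectory", environment = "unknown",
             provenance = "individual", stringsAsFactors = FALSE)
}
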