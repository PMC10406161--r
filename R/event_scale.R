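#' Impute unobserved species-by-event cells
#'
#' Time points are rarely collected in every species, so the table is
#' completed before the event scale and regression are computed.  The
#' scheme mirrors the structure of the translating-time model itself:
#'
#' 1. initialise per-event means from the observed cells;
#' 2. regress each species' observed log ages on the current event means
#'    (an affine fit per species);
#' 3. fill that species' missing cells with the fitted prediction;
#' 4. recompute event means over observed + filled cells;
#'
#' iterating until the largest absolute change in any filled cell drops
#' below `tol`.  Observed cells are never altered; a complete table is
#' returned unchanged.
#'
#' @param table An `event_table`.
#' @param max_iter Iteration cap (warning on hitting it).
#' @param tol Convergence tolerance on filled cells (log-days).
#' @return A completed `event_table` with `imputed` marking filled cells
#'   and a `convergence` attribute (`iterations`, `final_change`,
#'   `converged`).
#' @export
impute_missing <- function(table, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(table, "event_table"))
  M <- table$log_age
  obs <- table$observed
  if (any(rowSums(obs) == 0)) stop("every event must be observed in >= 1 species")
  few <- colSums(obs) < 2
  if (any(few))
    stop("species with < 2 observations cannot be imputed: ",
         paste(colnames(M)[few], collapse = ", "))
  if (all(obs)) {
    out <- table
    out$imputed <- matrix(FALSE, nrow(M), ncol(M), dimnames = dimnames(M))
    attr(out, "convergence") <- list(iterations = 0L, final_change = 0,
                                     converged = TRUE)
    return(out)
  }
  filled <- M
  means <- rowMeans(M, na.rm = TRUE)
  change <- Inf
  iter <- 0L
  while (iter < max_iter && change >= tol) {
    iter <- iter + 1L
    prev <- filled
    for (s in seq_len(ncol(M))) {
      o <- obs[, s]
      if (all(o)) next
      fit <- stats::lm.fit(cbind(1, means[o]), M[o, s])
      filled[!o, s] <- fit$coefficients[1] + fit$coefficients[2] * means[!o]
    }
    means <- rowMeans(filled)
    delta <- abs(filled[!obs] - prev[!obs])
    change <- if (anyNA(delta)) Inf else max(delta, 0)
  }
  if (change >= tol)
    warning("imputation did not converge in ", max_iter,
            " iterations (last change ", signif(change, 3), ")")
  out <- table
  out$log_age <- filled
  out$imputed <- !obs
  attr(out, "convergence") <- list(iterations = iter, final_change = change,
                                   converged = change < tol)
  out
}

#' Compute the 0-1 event scale
#'
#' Each event's log ages (days post conception) are averaged across
#' species, then min-max normalised: the earliest event scores 0, the
#' latest 1.  The scale is therefore invariant to any common affine
#' transform of the log ages.
#'
#' @param table A completed `event_table` (no `NA` cells; run
#'   [impute_missing()] first if needed).
#' @return An `event_scale`: data frame with `event_id`, `mean_log_age`,
#'   `score`, `event_type`.
#' @export
compute_event_scale <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (anyNA(table$log_age))
    stop("table has unobserved cells; impute before computing the scale")
  m <- rowMeans(table$log_age)
  rng <- range(m)
  if (rng[1] == rng[2]) stop("all events share one averaged age; scale undefined")
  out <- data.frame(event_id = rownames(table$log_age),
                    mean_log_age = unname(m),
                    score = unname((m - rng[1]) / (rng[2] - rng[1])),
                    event_type = unname(table$event_type),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_scale", "data.frame")
  out
}
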