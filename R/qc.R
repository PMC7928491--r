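#' Stability profile of a recording
#'
#' Splits the record into consecutive non-overlapping windows and
#' reports, per window, the mean open amplitude, mean open duration,
#' mean closed duration and event rate, plus ordinary-least-squares
#' linear trends of each statistic against the window midpoint. Used
#' to detect run-down and other systematic drifts before analysis.
#' Events are assigned to windows by their onset time.
#'
#' @param events an [EventList].
#' @param windowS window length in seconds (default 10).
#' @return list with `windows` (one row per window) and `trends`
#'   (statistic, slope per second, p-value of the slope).
#' @export
stabilityProfile <- function(events, windowS = 10) {
  ev <- events@events
  if (!nrow(ev)) stop("empty event list")
  span <- max(ev$onset_s + ev$duration_ms / .S_TO_MS)
  nwin <- floor(span / windowS + 1e-9)
  if (nwin < 2) stop("record too short: need at least 2 stability windows")
  win <- pmin(floor(ev$onset_s / windowS) + 1L, nwin)
  rows <- lapply(seq_len(nwin), function(w) {
    e <- ev[win == w, , drop = FALSE]
    op <- e[e$kind == "open", , drop = FALSE]
    cl <- e[e$kind == "closed", , drop = FALSE]
    data.frame(
      window = w, midpoint_s = (w - 0.5) * windowS,
      mean_open_amplitude_pA = if (nrow(op)) mean(op$amplitude_pA) else NA_real_,
      mean_open_duration_ms = if (nrow(op)) mean(op$duration_ms) else NA_real_,
      mean_closed_duration_ms = if (nrow(cl)) mean(cl$duration_ms) else NA_real_,
      event_rate_per_s = nrow(op) / windowS)
  })
  windows <- do.call(rbind, rows)
  stats_cols <- c("mean_open_amplitude_pA", "mean_open_duration_ms",
                  "mean_closed_duration_ms", "event_rate_per_s")
  trends <- do.call(rbind, lapply(stats_cols, function(sc) {
    ok <- is.finite(windows[[sc]])
    if (sum(ok) < 3 || stats::var(windows[[sc]][ok]) == 0)
      return(data.frame(statistic = sc, slope = NA_real_,
                        p_value = NA_real_))
    fit <- stats::lm(windows[[sc]][ok] ~ windows$midpoint_s[ok])
    cf <- summary(fit)$coefficients
    data.frame(statistic = sc, slope = cf[2, 1], p_value = cf[2, 4])
  }))
  list(windows = windows, trends = trends)
}

#' Truncate an event list at an analysis cutoff
#'
#' Retains events with onset before `cutoffS`; an event straddling the
#' cutoff is cut at the cutoff and flagged censored; later events are
#' dropped. Used to restrict analysis to the stable initial portion of
#' a recording (60 s for high-sensitivity-isoform groups, 120 s for
#' low-sensitivity groups by convention).
#'
#' @param events an [EventList].
#' @param cutoffS cutoff in seconds (> 0).
#' @return an [EventList].
#' @export
truncateEvents <- function(events, cutoffS) {
  stopifnot(cutoffS > 0)
  ev <- events@events
  keep <- ev$onset_s < cutoffS
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev)) {
    ends <- ev$onset_s + ev$duration_ms / .S_TO_MS
    straddle <- ends > cutoffS + 1e-12
    ev$duration_ms[straddle] <- (cutoffS - ev$onset_s[straddle]) * .S_TO_MS
    ev$censored[straddle] <- TRUE
  }
  rownames(ev) <- NULL
  md <- events@metadata
  md$truncated_at_s <- cutoffS
  new("EventList", events = ev, metadata = md)
}

#' Flag event-rate outlier patches within a group
#'
#' Applies the two-standard-deviation outlier rule to the events-per-
#' second of patches in each group: the group mean and SD are computed
#' in a single pass over all patches (each candidate included in its
#' own reference), and patches outside mean +/- 2 SD are flagged
#' excluded. No iteration is performed. Groups with fewer than 3
#' patches are left unfiltered with a recorded warning.
#'
#' @param summaries data.frame of patch summaries with a numeric
#'   `events_per_second` column and optionally a `group` column.
#' @return the data.frame with logical `excluded` and character
#'   `exclude_reason` columns filled in.
#' @export
eventRateOutlierFilter <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            "events_per_second" %in% names(summaries))
  if (!"group" %in% names(summaries)) summaries$group <- "all"
  summaries$excluded <- FALSE
  summaries$exclude_reason <- ""
  for (g in unique(summaries$group)) {
    idx <- which(summaries$group == g)
    r <- summaries$events_per_second[idx]
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 patches; no outlier filtering")
      next
    }
    m <- mean(r); s <- stats::sd(r)
    out <- abs(r - m) > 2 * s
    summaries$excluded[idx[out]] <- TRUE
    summaries$exclude_reason[idx[out]] <- sprintf(
      "event rate %.3g outside %.3g +/- 2 x %.3g", r[out], m, s)
  }
  summaries
}
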