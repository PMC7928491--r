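#' Analyze one patch recording
#'
#' Runs the per-patch analysis chain on a current trace: SKM
#' idealization, dead-time imposition, truncation to the stable
#' analysis window, stability profiling, open/closed dwell-time
#' mixture fitting with delta-LL model selection, T_crit computation,
#' burst segmentation with mixed-amplitude discard and (for two-class
#' recordings) amplitude-class separation, and summary statistics.
#'
#' @param trace a [ChannelTrace], already filtered to the analysis
#'   bandwidth (see [refilterTrace()]).
#' @param patchId identifier for reporting.
#' @param nOpenClasses open conductance classes to idealize (1 for
#'   high-sensitivity-like, 2 for low-sensitivity-like recordings).
#' @param analyzedWindowS analysis cutoff in seconds (60 for HS-type,
#'   120 for LS-type groups by convention).
#' @param deadTimeMs imposed resolution dead time in ms (default 0.3,
#'   about the rise time of a 1 kHz Gaussian filter).
#' @param kMaxClosed,kMaxOpen maximum mixture components considered.
#' @param seed integer seed for the stochastic fitting steps.
#' @param stabilityWindowS stability-profile window (s); `NA` skips
#'   profiling.
#' @return a list ("patch summary") with elements `patch_id`,
#'   `analyzed_duration_s`, `n_open_events`, `events_per_second`,
#'   `amplitudes`, `open_fit`, `closed_fit` ([DwellFit]s), `t_crit_ms`,
#'   `bursts` ([BurstSet] or NULL), `burst_stats`, `stability`,
#'   `excluded`, `exclude_reason`.
#' @export
analyzePatch <- function(trace, patchId = "patch", nOpenClasses = 1L,
                         analyzedWindowS = 60, deadTimeMs = 0.3,
                         kMaxClosed = 5L, kMaxOpen = 2L, seed = 1L,
                         stabilityWindowS = 10) {
  skm <- idealizeSKM(trace, nOpenClasses = nOpenClasses)
  events <- applyDeadTime(skm$events, deadTimeMs)
  events <- truncateEvents(events, analyzedWindowS)
  stability <- if (is.finite(stabilityWindowS)) {
    tryCatch(stabilityProfile(events, stabilityWindowS),
             error = function(e) NULL)
  } else NULL
  analyzed_s <- min(analyzedWindowS,
                    length(trace@samples) / trace@samplingRate)
  ev <- events@events
  n_open <- sum(ev$kind == "open")
  closed_d <- dwellDurations(events, "closed")
  open_d <- dwellDurations(events, "open")
  closed_sel <- if (length(closed_d) >= 5)
    selectModel(closed_d, kMaxClosed, tMin = deadTimeMs, seed = seed,
                kind = "closed") else NULL
  open_sel <- if (length(open_d) >= 5)
    selectModel(open_d, kMaxOpen, tMin = deadTimeMs, seed = seed + 500L,
                kind = "open") else NULL
  closed_fit <- if (!is.null(closed_sel)) closed_sel$fits[[closed_sel$k]]
  open_fit <- if (!is.null(open_sel)) open_sel$fits[[open_sel$k]]
  t_crit <- if (!is.null(closed_fit) && nComponents(closed_fit) >= 2)
    computeTcrit(closed_fit) else NA_real_
  bursts <- NULL
  burst_stats <- NULL
  if (is.finite(t_crit)) {
    bursts <- segmentBursts(events, t_crit)
    open_means <- skm$amplitudes$mean_pA[-1]
    bursts <- discardMixedAmplitudeBursts(
      bursts,
      classAmplitudes = if (nOpenClasses > 1L) open_means else NULL,
      tolerance = 0.4)
    if (nOpenClasses > 1L && sum(!bursts@bursts$discarded) >= 2L)
      bursts <- tryCatch(
        classifyBurstAmplitudes(bursts, maxClasses = nOpenClasses,
                                seed = seed + 900L),
        error = function(e) bursts)
    burst_stats <- burstStatistics(bursts, perClass = nOpenClasses > 1L)
  }
  list(patch_id = patchId,
       analyzed_duration_s = analyzed_s,
       n_open_events = n_open,
       events_per_second = n_open / analyzed_s,
       amplitudes = skm$amplitudes,
       open_fit = open_fit, closed_fit = closed_fit,
       open_selection = open_sel, closed_selection = closed_sel,
       t_crit_ms = t_crit,
       bursts = bursts, burst_stats = burst_stats,
       stability = stability,
       excluded = FALSE, exclude_reason = "")
}

#' Simulate and analyze a group of patches
#'
#' Synthetic-study driver: simulates `nPatches` independent patch
#' recordings from a gating model under the default acquisition chain
#' (50 kHz sampling, 5 kHz on-line and 1 kHz off-line Gaussian
#' corners), analyzes each with [analyzePatch()], and applies the
#' group-level 2-SD event-rate outlier filter.
#'
#' @param model a [GatingModel] defining the group's kinetics.
#' @param nPatches number of patches (the study used 5-8 per group).
#' @param durationS simulated record length in seconds.
#' @param seed integer seed; patch `i` uses `seed + i`.
#' @param group group label attached to the summaries.
#' @param noiseSd baseline noise sd in pA before filtering.
#' @param ... further arguments to [analyzePatch()].
#' @return list with `patches` (per-patch summaries) and `qc`
#'   (data.frame with the exclusion flags).
#' @export
simulateGroup <- function(model, nPatches, durationS, seed = 1L,
                          group = "group", noiseSd = 0.15, ...) {
  patches <- lapply(seq_len(nPatches), function(i) {
    sim <- simulatePatch(model, durationS, seed = seed + i,
                         noiseSd = noiseSd)
    p <- analyzePatch(sim$trace, patchId = sprintf("%s_%02d", group, i),
                      seed = seed + i, ...)
    p$group <- group
    p
  })
  qc <- data.frame(
    patch_id = vapply(patches, `[[`, character(1), "patch_id"),
    group = group,
    events_per_second = vapply(patches, `[[`, numeric(1),
                               "events_per_second"))
  qc <- eventRateOutlierFilter(qc)
  for (i in seq_along(patches)) {
    patches[[i]]$excluded <- qc$excluded[i]
    patches[[i]]$exclude_reason <- qc$exclude_reason[i]
  }
  list(patches = patches, qc = qc)
}

#' Collect a per-patch property table from group results
#'
#' Extracts standard per-patch properties (events per second, mean
#' open amplitude, dwell time constants and areas, T_crit, burst
#' summaries) from the non-excluded patches of a [simulateGroup()] /
#' [analyzePatch()] result, as input to [groupComparison()].
#'
#' @param patches list of patch summaries.
#' @param includeExcluded keep patches flagged by the outlier filter.
#' @return named list: property -> numeric per-patch values.
#' @export
patchProperties <- function(patches, includeExcluded = FALSE) {
  if (!includeExcluded)
    patches <- Filter(function(p) !isTRUE(p$excluded), patches)
  grab <- function(f) vapply(patches, function(p) {
    v <- tryCatch(f(p), error = function(e) NA_real_)
    if (length(v) != 1 || !is.numeric(v)) NA_real_ else v
  }, numeric(1))
  out <- list(
    events_per_second = grab(function(p) p$events_per_second),
    amplitude_pA = grab(function(p) p$amplitudes$mean_pA[2]),
    t_crit_ms = grab(function(p) p$t_crit_ms)
  )
  kmax_c <- max(c(0, vapply(patches, function(p)
    if (is.null(p$closed_fit)) 0L else nComponents(p$closed_fit),
    integer(1))))
  for (k in seq_len(kmax_c)) {
    out[[sprintf("closed_tau%d_ms", k)]] <-
      grab(function(p) dwellTau(p$closed_fit)[k])
    out[[sprintf("closed_area%d", k)]] <-
      grab(function(p) dwellArea(p$closed_fit)[k])
  }
  kmax_o <- max(c(0, vapply(patches, function(p)
    if (is.null(p$open_fit)) 0L else nComponents(p$open_fit),
    integer(1))))
  for (k in seq_len(kmax_o)) {
    out[[sprintf("open_tau%d_ms", k)]] <-
      grab(function(p) dwellTau(p$open_fit)[k])
  }
  out$proportion_bursts <- grab(function(p)
    p$burst_stats$proportion_bursts[1])
  out$mean_p_open <- grab(function(p) p$burst_stats$mean_p_open[1])
  out
}
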