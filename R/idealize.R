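## Convert a per-sample open/closed labelling into an alternating
## EventList. `openLevel` gives the amplitude to record for each run of
## open samples (a function of the run's samples).
.runsToEvents <- function(isOpen, samplingRate, openAmplitude, metadata) {
  n <- length(isOpen)
  if (n == 0L) stop("empty trace")
  r <- rle(isOpen)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  amp <- vapply(seq_along(starts), function(i) {
    if (r$values[i]) openAmplitude(starts[i], ends[i]) else 0
  }, numeric(1))
  nev <- length(starts)
  ev <- data.frame(
    onset_s = (starts - 1L) / samplingRate,
    duration_ms = r$lengths / samplingRate * .S_TO_MS,
    kind = ifelse(r$values, "open", "closed"),
    amplitude_pA = amp,
    class_label = ifelse(r$values, "single", ""),
    censored = seq_len(nev) %in% c(1L, nev),
    stringsAsFactors = FALSE
  )
  new("EventList", events = ev, metadata = metadata)
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' Oracle idealization method: each sample is assigned to the nearest
#' of the baseline (0 pA) and the supplied open levels, which for a
#' single level reduces to classic half-amplitude threshold crossing at
#' `thresholdFraction` of the level. Contiguous runs become events;
#' alternation is enforced by pooling all open levels into one open
#' conductance state per run. The first and last events are flagged
#' censored.
#'
#' @param trace a [ChannelTrace].
#' @param openLevels numeric vector of open-channel current levels (pA).
#' @param thresholdFraction open/closed decision threshold as a
#'   fraction of the smallest open level (default 0.5).
#' @return an [EventList]; each open event's amplitude is the measured
#'   mean of its samples (the supplied levels steer detection, so that
#'   drifts such as run-down remain visible to stability profiling).
#' @export
idealizeThreshold <- function(trace, openLevels, thresholdFraction = 0.5) {
  stopifnot(length(openLevels) >= 1, all(openLevels > 0))
  x <- trace@samples
  if (!length(x)) stop("empty trace")
  thr <- thresholdFraction * min(openLevels)
  isOpen <- x > thr
  openAmp <- function(s, e) mean(x[s:e])
  .runsToEvents(isOpen, trace@samplingRate, openAmp,
                list(method = "threshold", open_levels = openLevels))
}

#' Idealize a trace by segmental k-means (SKM)
#'
#' Alternates (a) re-estimation of per-class amplitude means and noise
#' standard deviations from the currently assigned samples with (b)
#' Viterbi restoration of the most likely sample-to-class path under
#' Gaussian emissions and a uniform small switching probability per
#' sample. Iteration stops when the fraction of samples changing class
#' falls below `tol` or after `maxIter` iterations. The joint
#' log-likelihood is non-decreasing across iterations.
#'
#' @param trace a [ChannelTrace].
#' @param nOpenClasses number of open conductance classes (>= 1).
#' @param initLevels optional numeric vector of initial class levels,
#'   `c(baseline, open levels...)`; by default the baseline is
#'   initialized at the sample-density mode and open levels spread
#'   between the baseline and the upper sample quantile.
#' @param maxIter maximum SKM iterations.
#' @param tol convergence threshold on the fraction of reassigned
#'   samples.
#' @param pSwitch per-sample class switching probability of the
#'   discrete-time transition model (default 0.01).
#' @param sharedNoise use one pooled noise sd across classes in the
#'   emission model (default TRUE). Low-pass filtering erodes brief
#'   openings below their full amplitude, which inflates a separately
#'   estimated open-class variance until baseline noise is mistaken
#'   for channel activity; pooling keeps the emission model tight.
#'   Per-class sds of the assigned samples are still reported.
#' @return list with `events` (an [EventList]; open amplitudes are the
#'   fitted class means), `amplitudes` (data.frame: class mean pA and
#'   noise sd per class, baseline first), `logLik` (joint
#'   log-likelihood per iteration) and `iterations`.
#' @export
idealizeSKM <- function(trace, nOpenClasses = 1L, initLevels = NULL,
                        maxIter = 30L, tol = 1e-5, pSwitch = 0.01,
                        sharedNoise = TRUE) {
  stopifnot(nOpenClasses >= 1L)
  x <- trace@samples
  if (!length(x)) stop("empty trace")
  K <- nOpenClasses + 1L
  if (is.null(initLevels)) {
    d <- stats::density(x, n = 512)
    baseline <- d$x[which.max(d$y)]
    top <- stats::quantile(x, 0.999, names = FALSE)
    if (top <= baseline) top <- max(x)
    means <- c(baseline,
               baseline + seq_len(nOpenClasses) / nOpenClasses *
                 (top - baseline))
  } else {
    if (length(initLevels) != K)
      stop("initLevels must have length nOpenClasses + 1 (baseline first)")
    means <- as.numeric(initLevels)
  }
  sds <- rep(max(stats::mad(x), 1e-4), K)
  path <- NULL
  ll <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    newPath <- .viterbi_cpp(x, means, sds, pSwitch)
    counts <- tabulate(newPath, nbins = K)
    if (any(counts == 0L))
      stop("class ", which(counts == 0L)[1],
           " captured zero samples; use fewer open classes or different initLevels")
    for (k in seq_len(K)) {
      xk <- x[newPath == k]
      means[k] <- mean(xk)
      sds[k] <- max(stats::sd(xk), 1e-6)
      if (is.na(sds[k])) sds[k] <- 1e-6
    }
    if (sharedNoise)
      sds <- rep(max(sqrt(mean((x - means[newPath])^2)), 1e-6), K)
    ll <- c(ll, .path_loglik_cpp(x, newPath, means, sds, pSwitch))
    changed <- if (is.null(path)) 1 else mean(newPath != path)
    path <- newPath
    if (changed < tol || iter >= maxIter) break
  }
  ## per-class sds of the assigned samples, for reporting
  sds_report <- vapply(seq_len(K), function(k) {
    s <- stats::sd(x[path == k]); if (is.na(s)) 1e-6 else max(s, 1e-6)
  }, numeric(1))
  ## order classes by mean: class 1 = baseline (smallest mean)
  ord <- order(means)
  rank_of <- match(seq_len(K), ord)
  path <- rank_of[path]
  means <- means[ord]; sds <- sds_report[ord]
  isOpen <- path > 1L
  openAmp <- function(s, e) {
    k <- as.integer(names(which.max(table(path[s:e]))))
    means[k]
  }
  events <- .runsToEvents(isOpen, trace@samplingRate, openAmp,
                          list(method = "skm", p_switch = pSwitch))
  ## label open events by class when more than one open class was fitted
  if (nOpenClasses > 1L) {
    ev <- events@events
    open_means <- means[-1]
    lab <- c("O_S", paste0("O_", seq_len(nOpenClasses - 1L) + 1L))
    lab[nOpenClasses] <- "O_L"
    oi <- which(ev$kind == "open")
    ev$class_label[oi] <- lab[vapply(ev$amplitude_pA[oi], function(a)
      which.min(abs(open_means - a)), integer(1))]
    events@events <- ev
  }
  amplitudes <- data.frame(
    class = c("baseline", paste0("open", seq_len(nOpenClasses))),
    mean_pA = means, sd_pA = sds, n_samples = tabulate(path, K))
  list(events = events, amplitudes = amplitudes, logLik = ll,
       iterations = iter)
}

#' Impose a dead time on an event list
#'
#' Events shorter than the dead time cannot be resolved at the analysis
#' bandwidth; each is merged into its flanking events of the opposite
#' kind (shortest first), which absorb its duration. Alternation and
#' the total record duration are preserved exactly.
#'
#' @param events an [EventList].
#' @param deadTime resolution dead time in ms (0 returns the input
#'   unchanged). The default elsewhere in the package is 0.3 ms,
#'   roughly the rise time of a 1 kHz Gaussian filter.
#' @return an [EventList].
#' @export
applyDeadTime <- function(events, deadTime) {
  stopifnot(deadTime >= 0)
  if (deadTime == 0 || nEvents(events) <= 1L) return(events)
  ev <- events@events
  repeat {
    short <- which(ev$duration_ms < deadTime)
    if (!length(short) || nrow(ev) == 1L) break
    i <- short[which.min(ev$duration_ms[short])]
    n <- nrow(ev)
    if (i > 1L && i < n) {
      ## neighbours share a kind; fuse prev + short + next
      merged <- ev[i - 1L, ]
      merged$duration_ms <- sum(ev$duration_ms[(i - 1L):(i + 1L)])
      if (merged$kind == "open") {
        w <- ev$duration_ms[c(i - 1L, i + 1L)]
        merged$amplitude_pA <-
          sum(ev$amplitude_pA[c(i - 1L, i + 1L)] * w) / sum(w)
      }
      merged$censored <- ev$censored[i - 1L] || ev$censored[i + 1L]
      ev <- rbind(ev[seq_len(i - 2L), , drop = FALSE], merged,
                  ev[seq_len(n - i - 1L) + i + 1L, , drop = FALSE])
    } else if (i == 1L) {
      ev$onset_s[2L] <- ev$onset_s[1L]
      ev$duration_ms[2L] <- ev$duration_ms[2L] + ev$duration_ms[1L]
      ev$censored[2L] <- TRUE
      ev <- ev[-1L, , drop = FALSE]
    } else {
      ev$duration_ms[n - 1L] <- ev$duration_ms[n - 1L] + ev$duration_ms[n]
      ev$censored[n - 1L] <- TRUE
      ev <- ev[-n, , drop = FALSE]
    }
    rownames(ev) <- NULL
  }
  md <- events@metadata
  md$dead_time_ms <- deadTime
  new("EventList", events = ev, metadata = md)
}

#' Dwell durations of one event kind
#'
#' Extracts the durations (ms) of open or closed events, excluding
#' censored events (whose true durations are unknown) by default.
#'
#' @param events an [EventList].
#' @param kind `"open"` or `"closed"`.
#' @param dropCensored exclude censored events (default TRUE).
#' @param classLabel optional open-class filter (`"O_S"`, `"O_L"`,
#'   `"single"`).
#' @return numeric vector of durations in ms.
#' @export
dwellDurations <- function(events, kind = c("open", "closed"),
                           dropCensored = TRUE, classLabel = NULL) {
  kind <- match.arg(kind)
  ev <- events@events
  keep <- ev$kind == kind
  if (dropCensored) keep <- keep & !ev$censored
  if (!is.null(classLabel) && kind == "open")
    keep <- keep & ev$class_label %in% classLabel
  ev$duration_ms[keep]
}
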