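#' Critical closed time between two closed components
#'
#' Computes T_crit, the closed duration separating within-burst from
#' between-burst closures, between adjacent components `i` and `i + 1`
#' of a fitted closed-dwell mixture. The default (`"equal_counts"`)
#' criterion chooses the time at which equal numbers of closed events
#' are misclassified on each side, i.e. the root of
#' `a_i exp(-t/tau_i) = a_{i+1} (1 - exp(-t/tau_{i+1}))`, found by
#' bracketed root-finding to 1e-9 ms. The equal-probability and
#' geometric-mean variants are available for sensitivity analysis.
#'
#' @param closedFit a closed-kind [DwellFit] with >= 2 components.
#' @param boundaryIndex boundary between components `boundaryIndex` and
#'   `boundaryIndex + 1` (default 1: the first component is the
#'   within-burst closure).
#' @param method `"equal_counts"` (default), `"equal_prob"`, or
#'   `"geometric"`.
#' @return T_crit in ms.
#' @export
computeTcrit <- function(closedFit, boundaryIndex = 1L,
                         method = c("equal_counts", "equal_prob",
                                    "geometric")) {
  method <- match.arg(method)
  tau <- closedFit@tau; a <- closedFit@area
  if (length(tau) < 2) stop("need at least 2 closed components for T_crit")
  i <- boundaryIndex
  if (i < 1 || i + 1 > length(tau))
    stop("boundaryIndex out of range")
  t1 <- tau[i]; t2 <- tau[i + 1]; a1 <- a[i]; a2 <- a[i + 1]
  if (method == "geometric") return(sqrt(t1 * t2))
  if (method == "equal_prob") {
    ## (a1/t1) exp(-t/t1) = (a2/t2) exp(-t/t2)
    return(log(a1 * t2 / (a2 * t1)) / (1 / t1 - 1 / t2))
  }
  g <- function(t) a1 * exp(-t / t1) - a2 * (1 - exp(-t / t2))
  lower <- 1e-12
  upper <- t2
  tries <- 0L
  while (g(upper) > 0 && tries < 60L) {
    upper <- upper * 2
    tries <- tries + 1L
  }
  if (g(lower) <= 0 || g(upper) > 0)
    stop("no sign change found when bracketing T_crit")
  stats::uniroot(g, c(lower, upper), tol = 1e-12)$root
}

#' Segment an event list into bursts and isolated openings
#'
#' A burst is a maximal run of two or more openings whose internal
#' closures are all shorter than `tCrit`; a single opening bounded by
#' closures of at least `tCrit` is an isolated opening. Censored events
#' never start or end a burst (censored openings are excluded from the
#' partition; censored closures act as burst separators since their
#' true duration is unknown).
#'
#' @param events an alternating [EventList].
#' @param tCrit critical closed time in ms (> 0).
#' @return a [BurstSet]. Burst durations span from the first opening's
#'   onset to the last opening's end; `p_open` is open time divided by
#'   that span.
#' @export
segmentBursts <- function(events, tCrit) {
  stopifnot(tCrit > 0)
  ev <- events@events
  oi <- which(ev$kind == "open")
  usable <- oi[!ev$censored[oi]]
  nburst <- 0L
  rows <- list()
  isolated <- integer(0)
  if (length(usable)) {
    ## separator between consecutive usable openings: the closed gap
    sep <- logical(max(0L, length(usable) - 1L))
    for (j in seq_along(sep)) {
      gap <- ev[(usable[j] + 1L):(usable[j + 1L] - 1L), , drop = FALSE]
      cl <- gap[gap$kind == "closed", , drop = FALSE]
      sep[j] <- any(cl$censored) || sum(cl$duration_ms) >= tCrit
    }
    grp <- cumsum(c(0L, as.integer(sep)))
    for (g in unique(grp)) {
      members <- usable[grp == g]
      if (length(members) >= 2L) {
        first <- members[1]; last <- members[length(members)]
        span <- (ev$onset_s[last] + ev$duration_ms[last] / .S_TO_MS -
                   ev$onset_s[first]) * .S_TO_MS
        open_time <- sum(ev$duration_ms[members])
        nburst <- nburst + 1L
        rows[[nburst]] <- data.frame(
          first_event = first, last_event = last,
          n_openings = length(members),
          duration_ms = span, open_time_ms = open_time,
          p_open = open_time / span,
          mean_amplitude_pA = mean(ev$amplitude_pA[members]),
          class_label = "single", discarded = FALSE,
          stringsAsFactors = FALSE)
      } else {
        isolated <- c(isolated, members)
      }
    }
  }
  bursts <- if (nburst) do.call(rbind, rows) else
    data.frame(first_event = integer(0), last_event = integer(0),
               n_openings = integer(0), duration_ms = numeric(0),
               open_time_ms = numeric(0), p_open = numeric(0),
               mean_amplitude_pA = numeric(0),
               class_label = character(0), discarded = logical(0),
               stringsAsFactors = FALSE)
  new("BurstSet", tCrit = tCrit, events = events, bursts = bursts,
      isolated = as.integer(isolated))
}

#' Open events belonging to a burst
#'
#' @param burstSet a [BurstSet].
#' @param i burst row number in [burstTable()].
#' @return integer event-table row indices of the burst's openings.
#' @export
burstMembers <- function(burstSet, i) {
  b <- burstSet@bursts[i, ]
  ev <- burstSet@events@events
  idx <- b$first_event:b$last_event
  idx[ev$kind[idx] == "open"]
}

#' Discard bursts containing multiple open-amplitude classes
#'
#' Bursts whose member openings span more than one amplitude class most
#' likely reflect several simultaneously active channels and are
#' removed from analysis (moved to the discarded set; counts are
#' conserved). A burst is discarded when its member amplitudes span
#' more than `tolerance` pA, or, with `classAmplitudes` supplied, when
#' the nearest-class assignments of its members disagree (partial
#' channel overlaps leave amplitudes between class levels, so both
#' criteria are applied).
#'
#' @param burstSet a [BurstSet].
#' @param classAmplitudes optional numeric vector of fitted class
#'   levels in pA.
#' @param tolerance amplitude spread tolerated within a burst (pA).
#' @return the [BurstSet] with the `discarded` column updated.
#' @export
discardMixedAmplitudeBursts <- function(burstSet, classAmplitudes = NULL,
                                        tolerance = 0.4) {
  b <- burstSet@bursts
  if (!nrow(b)) return(burstSet)
  ev <- burstSet@events@events
  for (i in seq_len(nrow(b))) {
    amps <- ev$amplitude_pA[burstMembers(burstSet, i)]
    mixed <- diff(range(amps)) > tolerance
    if (!mixed && !is.null(classAmplitudes)) {
      cls <- vapply(amps, function(a)
        which.min(abs(classAmplitudes - a)), integer(1))
      mixed <- length(unique(cls)) > 1L
    }
    if (mixed) b$discarded[i] <- TRUE
  }
  burstSet@bursts <- b
  burstSet
}

## Spherical-Gaussian BIC for a k-means partition (X-means style):
## pooled variance, k means, k-1 weights, 1 variance.
.kmeansBIC <- function(x, cluster, centers) {
  n <- length(x)
  k <- length(centers)
  W <- sum((x - centers[cluster])^2)
  sig2 <- max(W / max(n - k, 1L), 1e-12)
  nk <- tabulate(cluster, k)
  ll <- sum(nk * log(nk / n)) +
    sum(stats::dnorm(x, centers[cluster], sqrt(sig2), log = TRUE))
  p <- 2 * k
  -2 * ll + p * log(n)
}

#' Separate burst amplitude classes (X-means style)
#'
#' Clusters the per-burst mean open amplitudes of retained bursts with
#' k-means for k = 1..`maxClasses` and selects k by BIC under a
#' spherical Gaussian model. With k = 2 the lower-mean cluster is
#' labelled `O_S` and the higher `O_L`; with k = 1 all bursts are
#' labelled `single`. Candidate k values exceeding the number of
#' distinct burst amplitudes are skipped.
#'
#' @param burstSet a [BurstSet] with >= 2 retained bursts.
#' @param maxClasses maximum number of amplitude classes (default 2).
#' @param seed integer seed for the k-means starts.
#' @return the [BurstSet] with `class_label` filled in for retained
#'   bursts and the chosen k in `metadata`-free form (readable from the
#'   labels).
#' @export
classifyBurstAmplitudes <- function(burstSet, maxClasses = 2L, seed = 1L) {
  b <- burstSet@bursts
  keep <- which(!b$discarded)
  if (length(keep) < 2L) stop("need at least 2 retained bursts to classify")
  x <- b$mean_amplitude_pA[keep]
  best <- NULL
  .withSeed(seed, {
    for (k in seq_len(maxClasses)) {
      if (length(unique(x)) < k || length(x) < k) next
      km <- stats::kmeans(x, centers = k, nstart = 10L)
      bic <- .kmeansBIC(x, km$cluster, as.numeric(km$centers))
      if (is.null(best) || bic < best$bic)
        best <- list(k = k, km = km, bic = bic)
    }
  })
  if (is.null(best)) stop("no feasible number of classes")
  if (best$k == 1L) {
    b$class_label[keep] <- "single"
  } else {
    centers <- as.numeric(best$km$centers)
    lab <- rep("O_M", best$k)
    lab[which.min(centers)] <- "O_S"
    lab[which.max(centers)] <- "O_L"
    b$class_label[keep] <- lab[best$km$cluster]
  }
  burstSet@bursts <- b
  burstSet
}

#' Burst summary statistics
#'
#' Emits, overall or per amplitude class: the proportion of bursts
#' among all events (bursts / (bursts + isolated openings)), the mean
#' number of openings per burst, the burst duration described by a
#' single-exponential maximum-likelihood fit (its time constant equals
#' the mean burst duration), and the mean within-burst open probability
#' P_open. When reporting per class, isolated openings are attributed
#' to the nearest class by amplitude.
#'
#' @param burstSet a segmented (and, for `perClass = TRUE`, classified)
#'   [BurstSet]; discarded bursts are excluded.
#' @param perClass report per amplitude class.
#' @return data.frame with one row overall or per class: `class`,
#'   `n_bursts`, `n_isolated`, `proportion_bursts`,
#'   `mean_openings_per_burst`, `burst_duration_tau_ms`, `mean_p_open`.
#'   Classes with zero bursts report counts and `NA` fits.
#' @export
burstStatistics <- function(burstSet, perClass = FALSE) {
  b <- burstSet@bursts[!burstSet@bursts$discarded, , drop = FALSE]
  ev <- burstSet@events@events
  iso_amp <- ev$amplitude_pA[burstSet@isolated]
  if (!perClass) {
    groups <- list(all = list(bs = b, n_iso = length(burstSet@isolated)))
  } else {
    labs <- sort(unique(b$class_label))
    centers <- vapply(labs, function(l)
      mean(b$mean_amplitude_pA[b$class_label == l]), numeric(1))
    iso_lab <- if (length(iso_amp))
      labs[vapply(iso_amp, function(a)
        which.min(abs(centers - a)), integer(1))] else character(0)
    groups <- lapply(labs, function(l)
      list(bs = b[b$class_label == l, , drop = FALSE],
           n_iso = sum(iso_lab == l)))
    names(groups) <- labs
  }
  out <- lapply(names(groups), function(g) {
    bs <- groups[[g]]$bs; n_iso <- groups[[g]]$n_iso
    nb <- nrow(bs)
    data.frame(
      class = g, n_bursts = nb, n_isolated = n_iso,
      proportion_bursts = if (nb + n_iso > 0) nb / (nb + n_iso) else NA_real_,
      mean_openings_per_burst = if (nb) mean(bs$n_openings) else NA_real_,
      burst_duration_tau_ms = if (nb) mean(bs$duration_ms) else NA_real_,
      mean_p_open = if (nb) mean(bs$p_open) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
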