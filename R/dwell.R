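## Truncated exponential mixture machinery. All durations in ms. The
## observed density on [tMin, Inf) is
##   f(t) = sum_k a_k (1/tau_k) exp(-t/tau_k) / sum_j a_j exp(-tMin/tau_j)
## which is equivalently a mixture of shifted exponentials with
## conditional weights w_k = a_k exp(-tMin/tau_k) / Z. EM runs on the
## (w, tau) parametrization; reported areas are the extrapolated
## untruncated a_k.

.truncMixLogLik <- function(u, w, tau) {
  ## u = t - tMin >= 0
  dens <- sapply(seq_along(tau), function(k) w[k] / tau[k] * exp(-u / tau[k]))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.emTruncMix <- function(u, w, tau, maxIter = 500, tol = 1e-10,
                        tauFloor = 1e-9) {
  n <- length(u)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    comp <- sapply(seq_along(tau), function(k) w[k] / tau[k] * exp(-u / tau[k]))
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
    tot <- pmax(rowSums(comp), 1e-300)
    ll <- sum(log(tot))
    r <- comp / tot
    nk <- colSums(r)
    w <- nk / n
    ## components faster than the resolution floor are unidentifiable;
    ## clamping prevents collapse onto the truncation boundary
    tau <- pmax(colSums(r * u) / pmax(nk, 1e-12), tauFloor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, tau = tau, logLik = .truncMixLogLik(u, w, tau),
       converged = converged)
}

## k-means++-style seeding of k centers on log-durations
.seedTaus <- function(logd, k) {
  centers <- numeric(k)
  centers[1] <- logd[sample.int(length(logd), 1L)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(logd, function(v) min((v - centers[seq_len(j - 1)])^2),
                 numeric(1))
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0)
      p <- rep(1 / length(logd), length(logd))
    centers[j] <- logd[sample.int(length(logd), 1L, prob = p)]
  }
  sort(centers)
}

#' Fit an exponential mixture to dwell times by maximum likelihood
#'
#' Fits a `k`-component exponential mixture to dwell durations by EM,
#' maximizing the likelihood of the mixture density renormalized on
#' `[tMin, Inf)` (left truncation at the imposed dead time). Ten
#' seeded k-means++-style restarts on log-durations guard against the
#' multimodal mixture likelihood; the best log-likelihood is kept, with
#' ties broken towards the lowest first time constant. Reported areas
#' are the extrapolated untruncated fractional areas.
#'
#' @param dwells numeric dwell durations in ms, all `>= tMin`; multi-
#'   component fits require at least 5 dwells per component.
#' @param k number of exponential components (>= 1).
#' @param tMin left-truncation bound in ms (>= 0); typically the dead
#'   time imposed at idealization.
#' @param seed integer seed for the restarts.
#' @param nStarts number of EM restarts (default 10).
#' @param maxIter,tol EM iteration control.
#' @param kind `"open"` or `"closed"` (annotation only).
#' @return a [DwellFit]. A `k` exceeding the distinguishable support is
#'   reported via the `notes` slot (collapsed or empty components), not
#'   an exception.
#' @examples
#' fitExponentialMixture(c(1, 2, 3), k = 1)   # tau = sample mean = 2 ms
#' @export
fitExponentialMixture <- function(dwells, k, tMin = 0, seed = 1L,
                                  nStarts = 10L, maxIter = 500L,
                                  tol = 1e-10, kind = "closed") {
  dwells <- as.numeric(dwells)
  if (any(dwells <= 0)) stop("all dwell durations must be positive")
  if (any(dwells < tMin)) stop("dwells below the truncation bound tMin")
  stopifnot(k >= 1, tMin >= 0)
  if (k > 1 && length(dwells) < 5 * k)
    stop("too few dwells (need at least 5 per component)")
  u <- dwells - tMin
  u <- pmax(u, 1e-12)
  n <- length(u)
  ## fit on mean-normalized durations so the result is exactly
  ## scale-equivariant regardless of convergence thresholds
  sc <- mean(u)
  us <- u / sc
  if (k == 1L) {
    tau <- mean(u)
    fit <- list(w = 1, tau = tau,
                logLik = .truncMixLogLik(u, 1, tau), converged = TRUE)
  } else {
    fit <- .withSeed(seed, {
      logd <- log(us + tMin / sc)
      best <- NULL
      for (s in seq_len(nStarts)) {
        centers <- .seedTaus(logd, k)
        tau0 <- pmax(exp(centers) - tMin / sc, 1e-4)
        ## perturb duplicated centers
        tau0 <- tau0 * (1 + 1e-3 * (seq_len(k) - 1))
        w0 <- rep(1 / k, k)
        cand <- tryCatch(.emTruncMix(us, w0, tau0, maxIter, tol,
                                     tauFloor = max(1e-12, tMin / (2 * sc))),
                         error = function(e) NULL)
        if (is.null(cand)) next
        if (is.null(best) || cand$logLik > best$logLik + 1e-9 ||
            (abs(cand$logLik - best$logLik) <= 1e-9 &&
             min(cand$tau) < min(best$tau)))
          best <- cand
      }
      if (is.null(best)) stop("all EM restarts failed")
      best$tau <- best$tau * sc
      best$logLik <- best$logLik - n * log(sc)
      best
    })
  }
  notes <- character(0)
  if (!fit$converged) notes <- c(notes, "EM did not fully converge")
  if (any(fit$w < 1e-6))
    notes <- c(notes, "component with vanishing weight: k may exceed the distinguishable support")
  if (k > 1 && min(diff(sort(fit$tau))) < 1e-4 * max(fit$tau))
    notes <- c(notes, "nearly coincident time constants: k may exceed the distinguishable support")
  ## untruncated areas: a_k proportional to w_k * exp(tMin/tau_k)
  expo <- pmin(tMin / fit$tau, 50)
  if (any(tMin / fit$tau > 50))
    notes <- c(notes, "component far below the truncation bound: area extrapolation capped")
  a <- fit$w * exp(expo)
  a <- a / sum(a)
  ord <- order(fit$tau)
  new("DwellFit",
      tau = fit$tau[ord], area = a[ord], nDwells = as.integer(n),
      logLik = fit$logLik, tMin = tMin, kind = kind,
      converged = fit$converged, notes = notes)
}

#' Select the number of dwell-time components by the delta-LL rule
#'
#' Fits mixtures with increasing numbers of components and keeps adding
#' a component while the maximized log-likelihood improves by more than
#' 10 units; the first failure to improve by > 10 stops the search.
#' All fits are returned for audit.
#'
#' @param dwells numeric dwell durations in ms.
#' @param kMax largest number of components to consider.
#' @param tMin,seed,kind see [fitExponentialMixture()].
#' @return `list(k = selected count, fits = list of DwellFit,
#'   deltaLL = successive log-likelihood gains)`.
#' @export
selectModel <- function(dwells, kMax, tMin = 0, seed = 1L,
                        kind = "closed") {
  stopifnot(kMax >= 1)
  fits <- vector("list", 0L)
  deltas <- numeric(0)
  sel <- 1L
  for (k in seq_len(kMax)) {
    fits[[k]] <- fitExponentialMixture(dwells, k, tMin = tMin,
                                       seed = seed + k, kind = kind)
    if (k > 1L) {
      d <- fits[[k]]@logLik - fits[[k - 1L]]@logLik
      deltas <- c(deltas, d)
      if (d > 10) sel <- k else break
    }
  }
  list(k = sel, fits = fits, deltaLL = deltas)
}

#' Log-binned dwell-time histogram with square-root ordinate
#'
#' The standard log-binned display of dwell-time distributions
#' (logarithmic abscissa, square-root ordinate), on which a mixture
#' component of time constant tau peaks near t = tau. For display and
#' QC only; fitting always uses the raw durations.
#'
#' @param dwells numeric dwell durations in ms (> 0, non-empty).
#' @param binsPerDecade bins per decade of duration (default 10).
#' @return list with `breaks` (bin edges, ms), `mids` (geometric bin
#'   centres), `counts` and `sqrt_counts`.
#' @export
dwellHistogram <- function(dwells, binsPerDecade = 10) {
  if (!length(dwells)) stop("empty dwell list")
  if (any(dwells <= 0)) stop("dwell durations must be positive")
  lo <- log10(min(dwells)); hi <- log10(max(dwells))
  if (hi - lo < 1e-12) { lo <- lo - 0.05; hi <- hi + 0.05 }
  nb <- max(1L, as.integer(ceiling(binsPerDecade * (hi - lo) - 1e-9)))
  breaks <- 10^seq(lo, hi, length.out = nb + 1L)
  breaks[1] <- breaks[1] * (1 - 1e-12)
  breaks[nb + 1L] <- breaks[nb + 1L] * (1 + 1e-12)
  counts <- tabulate(findInterval(dwells, breaks,
                                  rightmost.closed = TRUE), nbins = nb)
  mids <- sqrt(breaks[-1] * breaks[-(nb + 1L)])
  list(breaks = breaks, mids = mids, counts = counts,
       sqrt_counts = sqrt(counts))
}

#' Mixture density of a dwell fit
#'
#' Evaluates the fitted (untruncated) exponential-mixture probability
#' density at the requested times, e.g. for overlay on a
#' [dwellHistogram()] display after transforming to the log abscissa.
#'
#' @param fit a [DwellFit].
#' @param t_ms times in ms.
#' @return numeric density values (1/ms).
#' @export
mixtureDensity <- function(fit, t_ms) {
  dens <- sapply(seq_along(fit@tau), function(k)
    fit@area[k] / fit@tau[k] * exp(-t_ms / fit@tau[k]))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(t_ms))
  rowSums(dens)
}

#' Draw dwell times from an exponential mixture
#'
#' Seeded sampler for mixture ground truth, used to emulate the
#' dwell-time structure of a recording condition directly.
#'
#' @param n number of draws.
#' @param tau component time constants (ms).
#' @param area fractional areas (normalized internally).
#' @param seed integer seed.
#' @return numeric vector of durations in ms.
#' @export
sampleMixture <- function(n, tau, area, seed = 1L) {
  stopifnot(length(tau) == length(area), all(tau > 0), all(area > 0))
  area <- area / sum(area)
  .withSeed(seed, {
    comp <- sample.int(length(tau), n, replace = TRUE, prob = area)
    stats::rexp(n, rate = 1 / tau[comp])
  })
}
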