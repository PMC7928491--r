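#' Trajectory: a simulated sequence of state sojourns
#'
#' @slot jumpTimes numeric, sojourn start times in seconds (first is 0).
#' @slot states integer, state index per sojourn.
#' @slot totalDuration numeric, record length in seconds.
#' @export
setClass("Trajectory",
  slots = c(jumpTimes = "numeric", states = "integer",
            totalDuration = "numeric")
)

setValidity("Trajectory", function(object) {
  bad <- character(0)
  if (length(object@jumpTimes) != length(object@states))
    bad <- c(bad, "jumpTimes and states lengths differ")
  if (length(object@jumpTimes)) {
    if (object@jumpTimes[1] != 0) bad <- c(bad, "first jump time must be 0")
    if (is.unsorted(object@jumpTimes, strictly = TRUE))
      bad <- c(bad, "jump times must be strictly increasing")
    if (object@jumpTimes[length(object@jumpTimes)] > object@totalDuration)
      bad <- c(bad, "last jump time exceeds total duration")
  }
  if (length(bad)) bad else TRUE
})

## Evaluate expr under a local RNG state seeded with `seed`, restoring
## the caller's RNG stream afterwards.
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a state trajectory by the Gillespie algorithm
#'
#' Samples the continuous-time Markov chain of a gating model: the
#' sojourn in state `s` is exponential with rate `-Q[s,s]` and the next
#' state is chosen in proportion to the off-diagonal rates. The start
#' state is drawn from the model's initial distribution (equilibrium by
#' default). Identical seeds give identical trajectories.
#'
#' @param model a valid [GatingModel].
#' @param duration record length in seconds.
#' @param seed integer seed.
#' @return a [Trajectory].
#' @export
sampleTrajectory <- function(model, duration, seed) {
  .stopIfInvalid(model)
  stopifnot(duration > 0)
  p0 <- model@initialDistribution
  if (!length(p0)) p0 <- as.numeric(equilibriumDistribution(model))
  .withSeed(seed, {
    start <- sample.int(length(p0), 1L, prob = p0)
    res <- .gillespie_cpp(model@Q, start - 1L, duration)
    new("Trajectory",
        jumpTimes = as.numeric(res$jump_times),
        states = as.integer(res$states) + 1L,
        totalDuration = duration)
  })
}

#' Gaussian low-pass filter kernel
#'
#' FIR kernel of a Gaussian filter with the requested -3 dB corner,
#' the standard software approximation of a 4-pole Bessel filter in
#' single-channel work. The kernel is normalized to unit sum (exact DC
#' gain 1); white noise filtered with kernel `h` has its standard
#' deviation multiplied by `sqrt(sum(h^2))`.
#'
#' @param samplingRate sampling rate in Hz.
#' @param cornerHz -3 dB corner frequency in Hz.
#' @return numeric kernel (odd length, symmetric, sums to 1).
#' @export
gaussianFilterKernel <- function(samplingRate, cornerHz) {
  stopifnot(samplingRate > 0, cornerHz > 0, cornerHz < samplingRate / 2)
  ## for a Gaussian filter, fc = 0.1325 / sigma  (sigma in seconds)
  sigma <- 0.1325 * samplingRate / cornerHz
  m <- max(1L, as.integer(ceiling(4 * sigma)))
  h <- stats::dnorm(seq(-m, m), sd = sigma)
  h / sum(h)
}

.applyFIR <- function(x, h) {
  m <- (length(h) - 1L) %/% 2L
  if (m == 0L) return(x)
  n <- length(x)
  pad <- c(rep(x[1], m), x, rep(x[n], m))
  y <- stats::filter(pad, h, method = "convolution", sides = 2)
  as.numeric(y[(m + 1L):(m + n)])
}

.levelsAtSamples <- function(traj, model, times) {
  amps <- stateAmplitudes(model)
  idx <- findInterval(times, traj@jumpTimes)
  idx[idx < 1L] <- 1L
  amps[traj@states[idx]]
}

#' Render a trajectory as a sampled, filtered current trace
#'
#' Converts a state trajectory into a digitized current record the way
#' an acquisition chain would see it: the noiseless level at each
#' sample is the summed unitary amplitude of the occupied states across
#' channels (openings as positive deflections from a 0 pA baseline),
#' optionally scaled by a run-down ramp, plus additive Gaussian noise,
#' then low-pass filtered with a Gaussian FIR at the on-line corner.
#'
#' @param traj a [Trajectory] (channel 1).
#' @param model the generating [GatingModel].
#' @param samplingRate sampling rate in Hz (default 50 kHz).
#' @param noiseSd additive baseline noise sd in pA before filtering.
#' @param onlineFilterHz acquisition low-pass corner (default 5 kHz).
#' @param seed integer seed for the noise (and extra channels).
#' @param rundown optional `list(start_s =, amplitude_slope_per_s =)`;
#'   after `start_s` the noiseless level is scaled by
#'   `max(0, 1 + slope * (t - start_s))`.
#' @param nChannels number of independent channels in the patch;
#'   channels beyond the first are simulated internally with seeds
#'   derived from `seed`.
#' @return a [ChannelTrace].
#' @export
renderTrace <- function(traj, model, samplingRate = 50000, noiseSd = 0.15,
                        onlineFilterHz = 5000, seed = 1L, rundown = NULL,
                        nChannels = 1L) {
  if (nChannels < 1L) stop("nChannels must be >= 1")
  stopifnot(noiseSd >= 0)
  nsamp <- round(traj@totalDuration * samplingRate)
  times <- (seq_len(nsamp) - 0.5) / samplingRate
  level <- .levelsAtSamples(traj, model, times)
  if (nChannels > 1L) {
    for (ch in seq_len(nChannels - 1L)) {
      tr2 <- sampleTrajectory(model, traj@totalDuration,
                              seed = seed + 7919L * ch)
      level <- level + .levelsAtSamples(tr2, model, times)
    }
  }
  if (!is.null(rundown)) {
    scale <- pmax(0, 1 + rundown$amplitude_slope_per_s *
                    pmax(0, times - rundown$start_s))
    level <- level * scale
  }
  x <- .withSeed(seed + 104729L, {
    if (noiseSd > 0) level + stats::rnorm(nsamp, sd = noiseSd) else level
  })
  h <- gaussianFilterKernel(samplingRate, onlineFilterHz)
  x <- .applyFIR(x, h)
  new("ChannelTrace", samples = x, samplingRate = samplingRate,
      onlineFilterHz = onlineFilterHz, offlineFilterHz = NA_real_,
      metadata = list(seed = seed, n_channels = nChannels))
}

#' Re-filter a trace off-line at a lower corner frequency
#'
#' Applies a Gaussian FIR at `cornerHz` (default 1 kHz, the analysis
#' bandwidth used throughout) and records the corner in the trace.
#'
#' @param trace a [ChannelTrace].
#' @param cornerHz analysis low-pass corner in Hz.
#' @return the filtered [ChannelTrace].
#' @export
refilterTrace <- function(trace, cornerHz = 1000) {
  h <- gaussianFilterKernel(trace@samplingRate, cornerHz)
  trace@samples <- .applyFIR(trace@samples, h)
  trace@offlineFilterHz <- cornerHz
  trace
}

#' Ground-truth event list of a trajectory
#'
#' Collapses a state trajectory into the alternating open/closed event
#' sequence it implies (contiguous same-conductance sojourns merged).
#' First and last events are flagged censored.
#'
#' @param traj a [Trajectory].
#' @param model the generating [GatingModel].
#' @return an [EventList] with class labels `O_S`/`O_L` when the model
#'   has two open classes, otherwise `single`.
#' @export
trajectoryEvents <- function(traj, model) {
  cls <- model@conductanceClass[traj@states]
  amps <- stateAmplitudes(model)[traj@states]
  open <- cls != .CLOSED_CLASS
  ends <- c(traj@jumpTimes[-1], traj@totalDuration)
  dur <- ends - traj@jumpTimes
  run <- cumsum(c(TRUE, open[-1] != open[-length(open)]))
  onset <- tapply(traj@jumpTimes, run, `[`, 1)
  dtot <- tapply(dur, run, sum)
  is_open <- tapply(open, run, `[`, 1)
  ## duration-weighted amplitude; class of the longest member sojourn
  amp <- tapply(amps * dur, run, sum) / dtot
  cls_ev <- vapply(split(seq_along(run), run), function(ix) {
    cls[ix][which.max(dur[ix])]
  }, character(1))
  open_classes <- setdiff(unique(model@conductanceClass), .CLOSED_CLASS)
  lab <- rep("single", length(dtot))
  if (length(open_classes) > 1) {
    ord <- order(model@classAmplitude[open_classes])
    lab[cls_ev == open_classes[ord[1]]] <- "O_S"
    lab[cls_ev == open_classes[ord[length(ord)]]] <- "O_L"
  }
  n <- length(dtot)
  ev <- data.frame(
    onset_s = as.numeric(onset),
    duration_ms = as.numeric(dtot) * .S_TO_MS,
    kind = ifelse(as.logical(is_open), "open", "closed"),
    amplitude_pA = ifelse(as.logical(is_open), as.numeric(amp), 0),
    class_label = ifelse(as.logical(is_open), lab, ""),
    censored = c(TRUE, rep(FALSE, max(0L, n - 2L)), if (n > 1) TRUE),
    stringsAsFactors = FALSE
  )
  rownames(ev) <- NULL
  new("EventList", events = ev, metadata = list(source = "trajectory"))
}

#' Simulate a complete patch recording
#'
#' Convenience composite: samples a trajectory, renders the trace with
#' the study's default acquisition chain (50 kHz sampling, 5 kHz
#' on-line Gaussian corner), optionally re-filters off-line (1 kHz by
#' default), and returns the trace together with the exact ground-truth
#' event list implied by the trajectory.
#'
#' @param model a valid [GatingModel].
#' @param duration record length in seconds.
#' @param seed integer seed.
#' @param samplingRate,noiseSd,onlineFilterHz see [renderTrace()].
#' @param offlineFilterHz analysis corner in Hz, or `NA` to skip
#'   off-line re-filtering.
#' @param rundown,nChannels see [renderTrace()].
#' @return `list(trace = ChannelTrace, truth = EventList,
#'   trajectory = Trajectory)`.
#' @export
simulatePatch <- function(model, duration, seed,
                          samplingRate = 50000, noiseSd = 0.15,
                          onlineFilterHz = 5000, offlineFilterHz = 1000,
                          rundown = NULL, nChannels = 1L) {
  traj <- sampleTrajectory(model, duration, seed)
  trace <- renderTrace(traj, model, samplingRate = samplingRate,
                       noiseSd = noiseSd, onlineFilterHz = onlineFilterHz,
                       seed = seed, rundown = rundown,
                       nChannels = nChannels)
  if (is.finite(offlineFilterHz))
    trace <- refilterTrace(trace, offlineFilterHz)
  list(trace = trace, truth = trajectoryEvents(traj, model),
       trajectory = traj)
}
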