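#' @import methods
#' @importFrom stats rnorm rexp runif sd var lm aov t.test kmeans
#'   TukeyHSD pt qnorm dnorm filter coef optimize uniroot setNames
#'   complete.cases
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib sckinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Conductance-class labels. "closed" is mandatory; open classes are
## extensible but these two cover the small/large unitary classes seen
## for the LS-isoform receptor.
.CLOSED_CLASS <- "closed"

#' GatingModel: an aggregated continuous-time Markov gating scheme
#'
#' A `GatingModel` holds the kinetic scheme of a single ion channel:
#' named states, the conductance class of each state (`"closed"` or an
#' open class such as `"open_small"` / `"open_large"`), the unitary
#' current magnitude of each class in pA (0 for closed), the generator
#' (rate) matrix `Q` in s^-1, and an optional initial state
#' distribution (defaulting to the equilibrium distribution).
#'
#' Invariants checked by the validity method: off-diagonal rates are
#' non-negative and rows of `Q` sum to zero (within 1e-10); at least one
#' closed-class and one open-class state exist; the closed-class
#' amplitude is 0 and open-class amplitudes are positive; the initial
#' distribution (when given) is a probability vector.
#'
#' @slot stateNames character vector of state identifiers.
#' @slot conductanceClass character vector, one class label per state.
#' @slot classAmplitude named numeric, unitary current magnitude (pA)
#'   per conductance class; `closed` maps to 0.
#' @slot Q numeric matrix of transition rates in s^-1.
#' @slot initialDistribution numeric probability vector, or length 0 to
#'   request the equilibrium distribution.
#'
#' @seealso [gatingModel()], [validateModel()],
#'   [equilibriumDistribution()], [predictedDwellComponents()]
#' @export
setClass("GatingModel",
  slots = c(
    stateNames = "character",
    conductanceClass = "character",
    classAmplitude = "numeric",
    Q = "matrix",
    initialDistribution = "numeric"
  )
)

.validateGatingModel <- function(object) {
  bad <- character(0)
  ns <- length(object@stateNames)
  if (ns < 1L) bad <- c(bad, "model has no states")
  if (anyDuplicated(object@stateNames))
    bad <- c(bad, "duplicated state names")
  if (length(object@conductanceClass) != ns)
    bad <- c(bad, "conductanceClass length does not match number of states")
  Q <- object@Q
  if (!is.numeric(Q) || nrow(Q) != ns || ncol(Q) != ns) {
    bad <- c(bad, sprintf("Q must be a %d x %d numeric matrix", ns, ns))
    return(bad)
  }
  offd <- Q; diag(offd) <- 0
  neg <- which(offd < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    bad <- c(bad, sprintf("negative off-diagonal rate Q[%d,%d] = %g",
                          neg[1, 1], neg[1, 2], Q[neg[1, 1], neg[1, 2]]))
  }
  rs <- rowSums(Q)
  if (any(abs(rs) > 1e-10))
    bad <- c(bad, sprintf("row %d of Q sums to %g (must be 0 within 1e-10)",
                          which.max(abs(rs)), rs[which.max(abs(rs))]))
  cls <- object@conductanceClass
  if (!any(cls == .CLOSED_CLASS)) bad <- c(bad, "no closed class state")
  if (!any(cls != .CLOSED_CLASS)) bad <- c(bad, "no open class state")
  amp <- object@classAmplitude
  if (is.null(names(amp)) || !all(unique(cls) %in% names(amp))) {
    bad <- c(bad, "classAmplitude must name every conductance class")
  } else {
    if (.CLOSED_CLASS %in% names(amp) &&
        !isTRUE(abs(amp[[.CLOSED_CLASS]]) < 1e-12))
      bad <- c(bad, "closed class amplitude must be 0")
    open_cls <- setdiff(unique(cls), .CLOSED_CLASS)
    if (length(open_cls) && any(amp[open_cls] <= 0))
      bad <- c(bad, "open class amplitudes must be > 0")
  }
  p0 <- object@initialDistribution
  if (length(p0)) {
    if (length(p0) != ns)
      bad <- c(bad, "initialDistribution length does not match states")
    if (any(p0 < 0))
      bad <- c(bad, "initialDistribution has negative entries")
    if (abs(sum(p0) - 1) > 1e-10)
      bad <- c(bad, sprintf("initialDistribution sums to %g (must be 1 within 1e-10)",
                            sum(p0)))
  }
  bad
}

setValidity("GatingModel", function(object) {
  bad <- .validateGatingModel(object)
  if (length(bad)) bad else TRUE
})

#' ChannelTrace: a sampled single-channel current record
#'
#' Holds the digitized current samples (pA) with acquisition metadata:
#' the sampling rate, the on-line (acquisition) low-pass corner, the
#' off-line (analysis) low-pass corner if re-filtered, and free-form
#' metadata such as holding potential, agonist concentration label,
#' seed and source model. Openings are rendered as positive deflections
#' from a 0 pA baseline and all amplitudes are magnitudes.
#'
#' @slot samples numeric vector of current samples in pA.
#' @slot samplingRate sampling rate in Hz.
#' @slot onlineFilterHz acquisition low-pass corner in Hz.
#' @slot offlineFilterHz analysis low-pass corner in Hz, or `NA_real_`.
#' @slot metadata named list of annotations.
#' @export
setClass("ChannelTrace",
  slots = c(
    samples = "numeric",
    samplingRate = "numeric",
    onlineFilterHz = "numeric",
    offlineFilterHz = "numeric",
    metadata = "list"
  )
)

setValidity("ChannelTrace", function(object) {
  bad <- character(0)
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    bad <- c(bad, "samplingRate must be a single positive number")
  nyq <- object@samplingRate / 2
  if (length(object@onlineFilterHz) == 1L && is.finite(object@onlineFilterHz) &&
      object@onlineFilterHz >= nyq)
    bad <- c(bad, "onlineFilterHz must be below the Nyquist frequency")
  if (length(object@offlineFilterHz) == 1L && is.finite(object@offlineFilterHz) &&
      object@offlineFilterHz >= nyq)
    bad <- c(bad, "offlineFilterHz must be below the Nyquist frequency")
  if (length(bad)) bad else TRUE
})

#' EventList: idealized alternating open/closed events
#'
#' The result of idealizing a current record: a contiguous, strictly
#' alternating sequence of open and closed events. Onsets are in
#' seconds; durations in ms (the units used throughout reporting).
#' Open events carry an amplitude in pA and a class label (`"O_S"`,
#' `"O_L"` or `"single"`); closed events have amplitude 0. Events cut
#' by the record edges or by truncation are flagged `censored` and are
#' excluded from dwell fitting.
#'
#' @slot events data.frame with columns `onset_s`, `duration_ms`,
#'   `kind` (`"open"`/`"closed"`), `amplitude_pA`, `class_label`,
#'   `censored`.
#' @slot metadata named list (provenance, acquisition parameters).
#' @export
setClass("EventList",
  slots = c(events = "data.frame", metadata = "list")
)

.eventColumns <- c("onset_s", "duration_ms", "kind", "amplitude_pA",
                   "class_label", "censored")

setValidity("EventList", function(object) {
  ev <- object@events
  bad <- character(0)
  missing_cols <- setdiff(.eventColumns, names(ev))
  if (length(missing_cols))
    return(paste("missing event columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$kind %in% c("open", "closed")))
      bad <- c(bad, "kind must be 'open' or 'closed'")
    if (any(ev$duration_ms <= 0))
      bad <- c(bad, "all durations must be > 0")
    if (nrow(ev) > 1 && any(ev$kind[-1] == ev$kind[-nrow(ev)]))
      bad <- c(bad, "events must strictly alternate open/closed")
    if (any(ev$amplitude_pA[ev$kind == "open"] <= 0))
      bad <- c(bad, "open amplitudes must be > 0")
    if (any(abs(ev$amplitude_pA[ev$kind == "closed"]) > 1e-12))
      bad <- c(bad, "closed amplitudes must be 0")
  }
  if (length(bad)) bad else TRUE
})

#' DwellFit: an exponential mixture fitted to dwell durations
#'
#' Maximum-likelihood fit of a mixture of exponentials to open or
#' closed dwell times, left-truncated at `tMin` (the imposed dead
#' time). Components are sorted by ascending time constant; areas are
#' the extrapolated (untruncated) fractional areas and sum to 1.
#'
#' @slot tau numeric, component time constants in ms (ascending).
#' @slot area numeric, fractional areas summing to 1.
#' @slot nDwells integer, number of dwells fitted.
#' @slot logLik numeric, maximized log-likelihood (nats).
#' @slot tMin numeric, left-truncation bound in ms.
#' @slot kind `"open"` or `"closed"`.
#' @slot converged logical, EM convergence flag of the best restart.
#' @slot notes character, convergence/degeneracy warnings (not errors).
#' @export
setClass("DwellFit",
  slots = c(
    tau = "numeric", area = "numeric", nDwells = "integer",
    logLik = "numeric", tMin = "numeric", kind = "character",
    converged = "logical", notes = "character"
  )
)

setValidity("DwellFit", function(object) {
  bad <- character(0)
  if (length(object@tau) != length(object@area))
    bad <- c(bad, "tau and area lengths differ")
  if (any(object@tau <= 0)) bad <- c(bad, "all tau must be > 0")
  if (is.unsorted(object@tau)) bad <- c(bad, "tau must be ascending")
  if (abs(sum(object@area) - 1) > 1e-9)
    bad <- c(bad, "areas must sum to 1 within 1e-9")
  if (!is.finite(object@logLik)) bad <- c(bad, "logLik must be finite")
  if (length(bad)) bad else TRUE
})

#' BurstSet: burst segmentation of an event list
#'
#' The result of segmenting idealized events into bursts (runs of two
#' or more openings separated by closures shorter than the critical
#' time T_crit), isolated openings, and bursts discarded because their
#' member openings span more than one amplitude class (a signature of
#' multiple simultaneously active channels).
#'
#' @slot tCrit critical closed time in ms.
#' @slot events the [EventList] that was segmented.
#' @slot bursts data.frame, one row per burst: `first_event`,
#'   `last_event` (row indices into the event table), `n_openings`,
#'   `duration_ms`, `open_time_ms`, `p_open`, `mean_amplitude_pA`,
#'   `class_label`, `discarded`.
#' @slot isolated integer vector of event-table row indices of isolated
#'   openings.
#' @export
setClass("BurstSet",
  slots = c(
    tCrit = "numeric",
    events = "EventList",
    bursts = "data.frame",
    isolated = "integer"
  )
)

setValidity("BurstSet", function(object) {
  b <- object@bursts
  bad <- character(0)
  if (nrow(b)) {
    if (any(b$n_openings < 2))
      bad <- c(bad, "every burst must contain >= 2 openings")
    if (any(b$p_open <= 0 | b$p_open > 1 + 1e-12))
      bad <- c(bad, "p_open must lie in (0, 1]")
  }
  if (length(bad)) bad else TRUE
})
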