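#' Number and table of idealized events
#'
#' `nEvents` returns the number of events; `eventTable` the underlying
#' data.frame (onsets in seconds, durations in ms).
#'
#' @param x an [EventList] or [BurstSet].
#' @return `nEvents`: integer; `eventTable`: data.frame.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname nEvents
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname nEvents
#' @export
setMethod("nEvents", "EventList", function(x) nrow(x@events))

#' @rdname nEvents
#' @export
setMethod("eventTable", "EventList", function(x) x@events)

#' Accessors for dwell-time mixture fits
#'
#' @param object a [DwellFit].
#' @return `dwellTau`: time constants in ms; `dwellArea`: fractional
#'   areas; `nComponents`: number of mixture components.
#' @export
setGeneric("dwellTau", function(object) standardGeneric("dwellTau"))

#' @rdname dwellTau
#' @export
setGeneric("dwellArea", function(object) standardGeneric("dwellArea"))

#' @rdname dwellTau
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname dwellTau
#' @export
setMethod("dwellTau", "DwellFit", function(object) object@tau)

#' @rdname dwellTau
#' @export
setMethod("dwellArea", "DwellFit", function(object) object@area)

#' @rdname dwellTau
#' @export
setMethod("nComponents", "DwellFit", function(object) length(object@tau))

#' @rdname dwellTau
#' @param object a [DwellFit].
#' @export
setMethod("logLik", "DwellFit", function(object) object@logLik)

#' Burst-set accessors
#'
#' `tCrit` returns the critical closed time (ms) used for segmentation;
#' `burstTable` the per-burst summary table (retained and discarded
#' bursts, see the `discarded` column); `isolatedOpenings` the event
#' row indices of openings that did not fall in a burst.
#'
#' @param object a [BurstSet].
#' @export
setGeneric("tCrit", function(object) standardGeneric("tCrit"))

#' @rdname tCrit
#' @export
setGeneric("burstTable", function(object) standardGeneric("burstTable"))

#' @rdname tCrit
#' @export
setGeneric("isolatedOpenings", function(object) standardGeneric("isolatedOpenings"))

#' @rdname tCrit
#' @export
setMethod("tCrit", "BurstSet", function(object) object@tCrit)

#' @rdname tCrit
#' @export
setMethod("burstTable", "BurstSet", function(object) object@bursts)

#' @rdname tCrit
#' @export
setMethod("isolatedOpenings", "BurstSet", function(object) object@isolated)

setMethod("show", "GatingModel", function(object) {
  cls <- object@conductanceClass
  cat("GatingModel with", length(object@stateNames), "states\n")
  cat("  states:", paste(sprintf("%s[%s]", object@stateNames, cls),
                         collapse = " "), "\n")
  amp <- object@classAmplitude
  cat("  amplitudes (pA):",
      paste(sprintf("%s=%g", names(amp), amp), collapse = " "), "\n")
})

setMethod("show", "ChannelTrace", function(object) {
  dur <- length(object@samples) / object@samplingRate
  cat(sprintf("ChannelTrace: %d samples, %.3f s at %g kHz\n",
              length(object@samples), dur, object@samplingRate / 1000))
  cat(sprintf("  on-line filter %g kHz; off-line filter %s\n",
              object@onlineFilterHz / 1000,
              if (is.finite(object@offlineFilterHz))
                sprintf("%g kHz", object@offlineFilterHz / 1000) else "none"))
})

setMethod("show", "EventList", function(object) {
  ev <- object@events
  cat(sprintf("EventList: %d events (%d open, %d closed), %d censored\n",
              nrow(ev), sum(ev$kind == "open"), sum(ev$kind == "closed"),
              sum(ev$censored)))
})

setMethod("show", "DwellFit", function(object) {
  cat(sprintf("DwellFit (%s): %d component(s), n = %d, logLik = %.2f, t_min = %g ms\n",
              object@kind, length(object@tau), object@nDwells,
              object@logLik, object@tMin))
  for (i in seq_along(object@tau))
    cat(sprintf("  tau%d = %.4g ms (%.1f%%)\n", i, object@tau[i],
                100 * object@area[i]))
})

setMethod("show", "BurstSet", function(object) {
  b <- object@bursts
  cat(sprintf("BurstSet: T_crit = %.4g ms; %d bursts (%d discarded mixed-amplitude), %d isolated openings\n",
              object@tCrit, sum(!b$discarded), sum(b$discarded),
              length(object@isolated)))
})
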