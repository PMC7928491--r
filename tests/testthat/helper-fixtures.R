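# Shared fixtures. All models are generic schemes whose aggregate
# dwell mixtures are set to the regimes reported for the receptor
# isoforms under study; none encode a specific mechanistic scheme.

# Simple two-state C <-> O scheme
twoStateModel <- function(opening = 100, closing = 500, amp = 1.35) {
  gatingModel(c("C", "O"), c("closed", "open_small"),
              c(closed = 0, open_small = amp),
              matrix(c(0, opening, closing, 0), 2, 2, byrow = TRUE))
}

# Linear C1 <-> C2 <-> O chain with the given rates
chainModel <- function(r12 = 10, r21 = 20, r2o = 500, ro2 = 250) {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- r12; Q[2, 1] <- r21; Q[2, 3] <- r2o; Q[3, 2] <- ro2
  gatingModel(c("C1", "C2", "O"), c("closed", "closed", "open_small"),
              c(closed = 0, open_small = 1.35), Q)
}

# High-sensitivity-isoform-like fixture: single 1.35 pA open class,
# closed mixture 0.8 ms (30%) / 250 ms (70%), open 0.6 / 2.1 ms.
hsModel <- function() {
  mixtureGatingModel(closedTau = c(0.8, 250), closedArea = c(0.3, 0.7),
                     openTau = c(0.6, 2.1), openArea = c(0.64, 0.36),
                     openAmplitude = 1.35)
}

# Low-sensitivity-isoform-like fixture: two open classes (~1.05 and
# ~2.06 pA) with class-segregated bursts.
lsModel <- function() {
  twoClassBurstModel(closedTau = c(0.6, 170, 2000),
                     closedArea = c(0.15, 0.425, 0.425),
                     openTauS = 2.0, openTauL = 2.5,
                     amplitudeS = 1.05, amplitudeL = 2.06,
                     classWeight = 0.6)
}

# Build an alternating EventList directly from dwell vectors (ms),
# starting closed; used where full trace simulation is unnecessary.
eventsFromDwells <- function(closed_ms, open_ms, amp = 1.35,
                             censorEdges = TRUE) {
  n <- 2 * min(length(closed_ms), length(open_ms))
  dur <- numeric(n)
  dur[seq(1, n, 2)] <- closed_ms[seq_len(n / 2)]
  dur[seq(2, n, 2)] <- open_ms[seq_len(n / 2)]
  kind <- rep(c("closed", "open"), n / 2)
  onset <- c(0, cumsum(dur[-n])) / 1000
  amp_v <- ifelse(kind == "open", amp, 0)
  cens <- rep(FALSE, n)
  if (censorEdges) cens[c(1, n)] <- TRUE
  new("EventList",
      events = data.frame(onset_s = onset, duration_ms = dur, kind = kind,
                          amplitude_pA = amp_v,
                          class_label = ifelse(kind == "open", "single", ""),
                          censored = cens, stringsAsFactors = FALSE),
      metadata = list())
}

# Reconstruct a per-sample open/closed labelling from an event list
sampleLabels <- function(events, samplingRate, nSamples) {
  ev <- eventTable(events)
  t_mid <- (seq_len(nSamples) - 0.5) / samplingRate
  idx <- findInterval(t_mid, ev$onset_s)
  idx[idx < 1L] <- 1L
  ev$kind[idx]
}
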