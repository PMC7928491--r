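test_that("threshold idealization is sample-accurate on noiseless traces", {
  # square pulse 0 -> 1.35 -> 0 without filtering distortion: build the
  # trace directly
  fs <- 10000
  x <- c(rep(0, 100), rep(1.35, 50), rep(0, 100))
  tr <- new("ChannelTrace", samples = x, samplingRate = fs,
            onlineFilterHz = NA_real_, offlineFilterHz = NA_real_,
            metadata = list())
  ev <- eventTable(idealizeThreshold(tr, 1.35))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$kind, c("closed", "open", "closed"))
  expect_equal(ev$duration_ms, c(10, 5, 10), tolerance = 1e-12)
  expect_equal(ev$amplitude_pA[2], 1.35)
})

test_that("a flat trace yields a single censored closed event", {
  tr <- new("ChannelTrace", samples = rep(0, 1000), samplingRate = 1000,
            onlineFilterHz = NA_real_, offlineFilterHz = NA_real_,
            metadata = list())
  ev <- eventTable(idealizeThreshold(tr, 1.0))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "closed")
  expect_true(ev$censored)
  expect_error(idealizeThreshold(
    new("ChannelTrace", samples = numeric(0), samplingRate = 1000,
        onlineFilterHz = NA_real_, offlineFilterHz = NA_real_,
        metadata = list()), 1), "empty")
})

test_that("threshold idealization agrees samplewise with ground truth at high SNR", {
  m <- hsModel()
  sim <- simulatePatch(m, 20, seed = 21, noiseSd = 0.15,
                       offlineFilterHz = NA)
  ev <- idealizeThreshold(sim$trace, 1.35)
  got <- sampleLabels(ev, 50000, length(sim$trace@samples))
  want <- sampleLabels(sim$truth, 50000, length(sim$trace@samples))
  expect_gt(mean(got == want), 0.99)
})

test_that("SKM matches threshold idealization on a noiseless trace", {
  m <- hsModel()
  sim <- simulatePatch(m, 10, seed = 6, noiseSd = 0.02,
                       offlineFilterHz = NA)
  thr <- eventTable(idealizeThreshold(sim$trace, 1.35))
  skm <- idealizeSKM(sim$trace, 1)
  sk <- eventTable(skm$events)
  expect_equal(nrow(sk), nrow(thr))
  expect_equal(sk$duration_ms, thr$duration_ms, tolerance = 1e-9)
  expect_false(is.unsorted(skm$logLik))  # SKM objective non-decreasing
})

test_that("SKM recovers the open-class amplitude", {
  m <- mixtureGatingModel(c(1, 100), c(0.3, 0.7), c(3, 6), c(0.6, 0.4),
                          openAmplitude = 1.35)
  sim <- simulatePatch(m, 30, seed = 8, noiseSd = 0.15,
                       offlineFilterHz = NA)
  skm <- idealizeSKM(sim$trace, 1)
  expect_lt(abs(skm$amplitudes$mean_pA[2] - 1.35), 0.05)
})

test_that("SKM separates two amplitude classes", {
  ls <- twoClassBurstModel(closedTau = c(1, 150), closedArea = c(0.2, 0.8),
                           openTauS = 2.5, openTauL = 3,
                           amplitudeS = 1.0, amplitudeL = 2.0)
  sim <- simulatePatch(ls, 60, seed = 12, noiseSd = 0.12,
                       offlineFilterHz = NA)
  skm <- idealizeSKM(sim$trace, 2)
  amps <- sort(skm$amplitudes$mean_pA[-1])
  expect_lt(abs(amps[1] - 1.0), 0.1)
  expect_lt(abs(amps[2] - 2.0), 0.1)
})

test_that("idealization round-trips rendered ground truth", {
  m <- hsModel()
  traj <- sampleTrajectory(m, 5, seed = 31)
  tr <- renderTrace(traj, m, noiseSd = 0, seed = 31)
  truth <- eventTable(trajectoryEvents(traj, m))
  got <- eventTable(idealizeThreshold(tr, 1.35))
  # sub-sample sojourns cannot survive rendering; compare after a
  # one-sample-period dead time on both sides
  dt <- 1000 / 50000
  truth_dt <- eventTable(applyDeadTime(trajectoryEvents(traj, m), dt))
  got_dt <- eventTable(applyDeadTime(idealizeThreshold(tr, 1.35), dt))
  expect_equal(nrow(got_dt), nrow(truth_dt))
  # boundary accuracy: durations within one sample period each side
  expect_lt(max(abs(got_dt$duration_ms - truth_dt$duration_ms)), 2 * dt + 1e-9)
})

test_that("idealizing a time-reversed trace reverses the event list", {
  m <- hsModel()
  sim <- simulatePatch(m, 10, seed = 13, noiseSd = 0.1,
                       offlineFilterHz = NA)
  fwd <- eventTable(idealizeThreshold(sim$trace, 1.35))
  rev_tr <- sim$trace
  rev_tr@samples <- rev(rev_tr@samples)
  bwd <- eventTable(idealizeThreshold(rev_tr, 1.35))
  expect_equal(sort(bwd$duration_ms), sort(fwd$duration_ms),
               tolerance = 1e-9)
  expect_equal(rev(bwd$kind), fwd$kind)
})

test_that("dead-time imposition merges unresolvable events and conserves time", {
  ev <- eventsFromDwells(c(100, 0.1, 100), c(5, 5, 5), censorEdges = FALSE)
  # layout: C(100) O(5) C(0.1) O(5) C(100) O(5)
  merged <- eventTable(applyDeadTime(ev, 0.3))
  expect_equal(merged$duration_ms[2], 10.1, tolerance = 1e-12)
  expect_equal(sum(merged$duration_ms), sum(eventTable(ev)$duration_ms),
               tolerance = 1e-9)

  expect_identical(eventTable(applyDeadTime(ev, 0)), eventTable(ev))

  # conservation on a random alternating list
  set.seed(99)
  rnd <- eventsFromDwells(rexp(200, 1 / 5), rexp(200, 1 / 0.8))
  out <- applyDeadTime(rnd, 0.5)
  expect_equal(sum(eventTable(out)$duration_ms),
               sum(eventTable(rnd)$duration_ms), tolerance = 1e-9)
  expect_true(all(eventTable(out)$duration_ms >= 0.5 - 1e-12))
  k <- eventTable(out)$kind
  expect_true(all(k[-1] != k[-length(k)]))  # alternation preserved
})
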