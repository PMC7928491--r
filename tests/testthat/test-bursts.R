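mkClosedFit <- function(tau, area, tMin = 0) {
  new("DwellFit", tau = tau, area = area / sum(area),
      nDwells = 100L, logLik = 0, tMin = tMin, kind = "closed",
      converged = TRUE, notes = character(0))
}

test_that("T_crit reduces to tau*ln(2) in the symmetric case", {
  # two components with equal tau cannot arise from a fit (sorted
  # ascending), so nudge infinitesimally
  f <- mkClosedFit(c(1, 1 + 1e-9), c(0.5, 0.5))
  expect_equal(computeTcrit(f), log(2), tolerance = 1e-6)
})

test_that("T_crit matches an independent bisection oracle", {
  f <- mkClosedFit(c(0.5, 50), c(0.5, 0.5))
  got <- computeTcrit(f)
  # oracle: bisection on a1 exp(-t/tau1) = a2 (1 - exp(-t/tau2))
  g <- function(t) 0.5 * exp(-t / 0.5) - 0.5 * (1 - exp(-t / 50))
  lo <- 1e-9; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(got, (lo + hi) / 2, tolerance = 1e-9)
  expect_error(computeTcrit(mkClosedFit(1, 1)), "at least 2")
})

test_that("T_crit is scale-equivariant and boundary-selectable", {
  f <- mkClosedFit(c(0.8, 120, 2000), c(0.3, 0.4, 0.3))
  fc <- mkClosedFit(c(0.8, 120, 2000) * 7, c(0.3, 0.4, 0.3))
  expect_equal(computeTcrit(fc) / computeTcrit(f), 7, tolerance = 1e-9)
  t12 <- computeTcrit(f, 1)
  t23 <- computeTcrit(f, 2)
  expect_lt(t12, t23)
  # alternative criteria stay bracketed by the component time scales
  ep <- computeTcrit(f, method = "equal_prob")
  gm <- computeTcrit(f, method = "geometric")
  expect_gt(ep, 0.8); expect_lt(ep, 120)
  expect_equal(gm, sqrt(0.8 * 120), tolerance = 1e-12)
})

test_that("burst segmentation matches hand-worked examples", {
  # O(1) C(0.2) O(1) C(500) O(1), flanked by long closures
  ev <- eventsFromDwells(c(1000, 0.2, 500, 1000), c(1, 1, 1, 1))
  bs <- segmentBursts(ev, tCrit = 3)
  b <- burstTable(bs)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_openings, 2)
  expect_equal(b$duration_ms, 2.2, tolerance = 1e-9)
  # opening 3 is isolated; the 4th opening sits at the censored edge
  # and is excluded from the partition entirely
  expect_equal(length(isolatedOpenings(bs)), 1)
  expect_equal(nrow(b) / (nrow(b) + length(isolatedOpenings(bs))), 1 / 2)

  # p_open arithmetic: O(2) C(1) O(2)
  ev2 <- eventsFromDwells(c(1000, 1, 1000), c(2, 2, 5))
  b2 <- burstTable(segmentBursts(ev2, tCrit = 3))
  expect_equal(b2$p_open[1], 0.8, tolerance = 1e-9)
  expect_equal(b2$open_time_ms[1], 4, tolerance = 1e-9)
  expect_equal(b2$duration_ms[1], 5, tolerance = 1e-9)
})

test_that("segmentation equals an exhaustive scan of ground-truth closures", {
  m <- hsModel()
  sim <- simulatePatch(m, 60, seed = 17, noiseSd = 0, offlineFilterHz = NA)
  truth <- applyDeadTime(sim$truth, 0.3)
  tcrit <- 5
  bs <- segmentBursts(truth, tcrit)
  # oracle: brute-force scan over the open-event sequence
  ev <- eventTable(truth)
  oi <- which(ev$kind == "open" & !ev$censored)
  groups <- list(); cur <- oi[1]
  if (length(oi) > 1) for (j in 2:length(oi)) {
    gap_rows <- (oi[j - 1] + 1):(oi[j] - 1)
    gap <- sum(ev$duration_ms[gap_rows][ev$kind[gap_rows] == "closed"])
    gap_cens <- any(ev$censored[gap_rows])
    if (gap < tcrit && !gap_cens) cur <- c(cur, oi[j])
    else { groups[[length(groups) + 1]] <- cur; cur <- oi[j] }
  }
  groups[[length(groups) + 1]] <- cur
  oracle_bursts <- Filter(function(g) length(g) >= 2, groups)
  oracle_iso <- unlist(Filter(function(g) length(g) == 1, groups))
  b <- burstTable(bs)
  expect_equal(nrow(b), length(oracle_bursts))
  expect_equal(sort(isolatedOpenings(bs)), sort(as.integer(oracle_iso)))
  expect_equal(b$n_openings, vapply(oracle_bursts, length, integer(1)))

  # partition: every non-censored opening is accounted for exactly once
  expect_equal(length(isolatedOpenings(bs)) + sum(b$n_openings), length(oi))

  # monotonicity: larger T_crit never removes openings from bursts
  in_bursts <- function(tc) sum(burstTable(segmentBursts(truth, tc))$n_openings)
  counts <- vapply(c(1, 2, 5, 20, 100), in_bursts, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mixed-amplitude bursts are discarded by class disagreement", {
  ev <- eventsFromDwells(c(1000, 0.5, 1000), c(2, 2, 2))
  et <- eventTable(ev)
  et$amplitude_pA[et$kind == "open"] <- c(1.0, 1.9, 1.0)
  mixed <- new("EventList", events = et, metadata = list())
  bs <- discardMixedAmplitudeBursts(segmentBursts(mixed, 3),
                                    classAmplitudes = c(1.0, 2.0))
  expect_true(burstTable(bs)$discarded[1])

  et$amplitude_pA[et$kind == "open"] <- c(1.0, 1.05, 1.0)
  close_amp <- new("EventList", events = et, metadata = list())
  bs2 <- discardMixedAmplitudeBursts(segmentBursts(close_amp, 3),
                                     classAmplitudes = c(1.0, 2.0))
  expect_false(burstTable(bs2)$discarded[1])
})

test_that("two-channel contamination is caught by the mixed-amplitude rule", {
  m <- twoStateModel(opening = 15, closing = 120, amp = 1.35)
  traj <- sampleTrajectory(m, 60, seed = 23)
  tr <- renderTrace(traj, m, noiseSd = 0.1, seed = 23, nChannels = 2)
  tr <- refilterTrace(tr, 2000)
  ev <- applyDeadTime(idealizeThreshold(tr, c(1.35, 2.70)), 0.3)
  bs <- segmentBursts(ev, tCrit = 40)
  bs <- discardMixedAmplitudeBursts(bs, classAmplitudes = c(1.35, 2.70))
  b <- burstTable(bs)
  et <- eventTable(ev)
  mixes_levels <- vapply(seq_len(nrow(b)), function(i) {
    a <- et$amplitude_pA[burstMembers(bs, i)]
    any(a > 2.1) && any(a < 1.6)  # unambiguous double + unitary member
  }, logical(1))
  # every burst mixing unitary and summed (double) openings is discarded
  expect_true(any(mixes_levels))  # the fixture does produce overlaps
  expect_true(all(b$discarded[mixes_levels]))
})

test_that("amplitude-class number is selected by BIC", {
  ev <- eventsFromDwells(rep(c(1000, 0.5), length.out = 9), rep(2, 9))
  bs0 <- segmentBursts(ev, 3)
  b <- burstTable(bs0)
  expect_equal(nrow(b), 4)
  # perfectly separated burst amplitudes {1, 2, 1, 2} pA
  bs0@bursts$mean_amplitude_pA <- c(1, 2, 1.001, 2.001)
  cl <- classifyBurstAmplitudes(bs0, maxClasses = 2, seed = 1)
  expect_equal(sort(unique(burstTable(cl)$class_label)), c("O_L", "O_S"))
  lab <- burstTable(cl)$class_label
  expect_equal(lab, c("O_S", "O_L", "O_S", "O_L"))

  # single-population null: 50 draws from one Gaussian select k = 1
  set.seed(7)
  bs1 <- bs0
  bs1@bursts <- bs0@bursts[rep(1, 50), ]
  bs1@bursts$mean_amplitude_pA <- rnorm(50, 1.3, 0.07)
  cl1 <- classifyBurstAmplitudes(bs1, maxClasses = 2, seed = 2)
  expect_true(all(burstTable(cl1)$class_label == "single"))
})

test_that("class labels recover the generating amplitude class", {
  ls <- twoClassBurstModel(closedTau = c(0.6, 400), closedArea = c(0.5, 0.5),
                           openTauS = 2, openTauL = 2.5,
                           amplitudeS = 1.05, amplitudeL = 2.06)
  sim <- simulatePatch(ls, 90, seed = 33, noiseSd = 0.1, offlineFilterHz = NA)
  truth <- applyDeadTime(sim$truth, 0.2)
  bs <- segmentBursts(truth, tCrit = 10)
  bs <- classifyBurstAmplitudes(bs, maxClasses = 2, seed = 3)
  b <- burstTable(bs)
  expect_gte(nrow(b), 5)
  et <- eventTable(truth)
  true_lab <- vapply(seq_len(nrow(b)), function(i) {
    labs <- et$class_label[burstMembers(bs, i)]
    names(which.max(table(labs)))
  }, character(1))
  expect_gte(mean(b$class_label == true_lab), 0.95)
})

test_that("burst statistics match their definitions", {
  ev <- eventsFromDwells(c(1000, 0.5, 1000, 500), c(2, 2, 2, 2))
  bs <- segmentBursts(ev, 3)
  st <- burstStatistics(bs)
  expect_equal(st$proportion_bursts, 0.5)  # 1 burst + 1 isolated
  expect_equal(st$mean_openings_per_burst, 2)
  expect_equal(st$mean_p_open,
               burstTable(bs)$p_open[1], tolerance = 1e-12)

  # per-class P_open against ground truth on an LS-like fixture
  ls <- lsModel()
  sim <- simulatePatch(ls, 120, seed = 41, noiseSd = 0.1,
                       offlineFilterHz = NA)
  truth <- applyDeadTime(sim$truth, 0.2)
  f <- fitExponentialMixture(dwellDurations(truth, "closed"), 2,
                             tMin = 0.2, seed = 1)
  tc <- computeTcrit(f)
  bs2 <- classifyBurstAmplitudes(segmentBursts(truth, tc), seed = 2)
  st2 <- burstStatistics(bs2, perClass = TRUE)
  b2 <- burstTable(bs2)
  for (cl in st2$class[st2$n_bursts > 0]) {
    expect_lt(abs(st2$mean_p_open[st2$class == cl] -
                    mean(b2$p_open[b2$class_label == cl])), 1e-12)
  }
  # ground-truth open fraction within bursts, per class
  et <- eventTable(truth)
  for (cl in c("O_S", "O_L")) {
    rows <- which(b2$class_label == cl & !b2$discarded)
    if (!length(rows)) next
    po <- vapply(rows, function(i) {
      idx <- b2$first_event[i]:b2$last_event[i]
      sum(et$duration_ms[idx][et$kind[idx] == "open"]) /
        sum(et$duration_ms[idx])
    }, numeric(1))
    expect_lt(abs(st2$mean_p_open[st2$class == cl] - mean(po)), 0.02)
  }
})
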