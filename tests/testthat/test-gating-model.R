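test_that("validateModel reports every violation and never raises", {
  m <- twoStateModel()
  expect_identical(validateModel(m), character(0))

  bad <- m
  bad@Q[1, 2] <- -5
  bad@Q[1, 1] <- 5  # keep row sum zero so only the sign violation fires
  v <- validateModel(bad)
  expect_length(v, 1)
  expect_match(v, "negative off-diagonal rate Q\\[1,2\\]")

  noOpen <- m
  noOpen@conductanceClass <- c("closed", "closed")
  expect_true(any(grepl("no open class", validateModel(noOpen))))

  badRow <- m
  badRow@Q[2, 2] <- 0
  expect_true(any(grepl("sums to", validateModel(badRow))))
})

test_that("equilibrium distribution solves pi Q = 0", {
  sym <- twoStateModel(100, 100)
  expect_equal(unname(equilibriumDistribution(sym)), c(0.5, 0.5),
               tolerance = 1e-12)

  # independent null-space oracle: SVD null vector of Q^T
  m <- chainModel(10, 20, 500, 250)
  sv <- svd(t(m@Q))
  v <- sv$v[, which.min(sv$d)]
  oracle <- abs(v) / sum(abs(v))
  expect_equal(unname(equilibriumDistribution(m)), oracle,
               tolerance = 1e-8)
  expect_equal(sum(equilibriumDistribution(m)), 1, tolerance = 1e-12)
})

test_that("disconnected state spaces are rejected", {
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 100; Q[2, 1] <- 500  # component 1
  Q[3, 4] <- 10; Q[4, 3] <- 20    # component 2, unreachable
  m <- gatingModel(c("C1", "O1", "C2", "O2"),
                   c("closed", "open_small", "closed", "open_small"),
                   c(closed = 0, open_small = 1), Q)
  expect_error(equilibriumDistribution(m), "disconnected")
  expect_error(predictedDwellComponents(m, "closed"), "reducible|disconnected")
})

test_that("two-state aggregates give tau = 1/exit-rate", {
  m <- twoStateModel(opening = 100, closing = 500)
  cl <- predictedDwellComponents(m, "closed")
  op <- predictedDwellComponents(m, "open")
  expect_equal(cl$tau_ms, 10, tolerance = 1e-12)
  expect_equal(cl$area, 1, tolerance = 1e-12)
  expect_equal(op$tau_ms, 2, tolerance = 1e-12)
})

test_that("chain closed components match an independent eigen oracle", {
  m <- chainModel(10, 20, 500, 250)
  pred <- predictedDwellComponents(m, "closed")
  # oracle: eigenvalues of the closed-closed block computed directly
  Qcc <- m@Q[1:2, 1:2]
  lam <- sort(eigen(Qcc, only.values = TRUE)$values)
  expect_equal(sort(pred$tau_ms), sort(-1000 / lam), tolerance = 1e-9)
  expect_equal(sum(pred$area), 1, tolerance = 1e-9)
  expect_true(all(pred$tau_ms > 0))
})

test_that("predicted closed mixture matches simulated sojourns", {
  # areas against the empirical dwell distribution of simulated closed
  # sojourns, and Kolmogorov distance of the survival curves
  m <- chainModel(10, 20, 500, 250)
  pred <- predictedDwellComponents(m, "closed")
  traj <- sampleTrajectory(m, 1100, seed = 11)
  ev <- eventTable(trajectoryEvents(traj, m))
  d <- ev$duration_ms[ev$kind == "closed" & !ev$censored]
  expect_gt(length(d), 1e5)
  mixSurv <- function(t) {
    s <- 0
    for (i in seq_len(nrow(pred)))
      s <- s + pred$area[i] * exp(-t / pred$tau_ms[i])
    s
  }
  ts <- sort(d)
  empSurv <- 1 - seq_along(ts) / length(ts)
  ks <- max(abs(empSurv - mixSurv(ts)))
  expect_lt(ks, 0.01)
  # component areas against the empirical distribution: the fast/slow
  # split at 5x the fast time constant isolates the slow component
  cut <- 5 * pred$tau_ms[1]
  emp_slow <- mean(d > cut)
  th_slow <- sum(pred$area * exp(-cut / pred$tau_ms))
  expect_lt(abs(emp_slow - th_slow), 0.02)
})

test_that("equilibrium matches long-run occupancy of a long trajectory", {
  m <- twoStateModel(100, 500)
  pi_eq <- equilibriumDistribution(m)
  traj <- sampleTrajectory(m, 3600, seed = 5)
  expect_gt(length(traj@states), 1e5)
  ends <- c(traj@jumpTimes[-1], traj@totalDuration)
  dur <- ends - traj@jumpTimes
  occ <- tapply(dur, traj@states, sum) / sum(dur)
  expect_lt(max(abs(occ - pi_eq)), 0.005)
})

test_that("mixture-design model reproduces its target dwell structure", {
  m <- hsModel()
  cl <- predictedDwellComponents(m, "closed")
  expect_equal(cl$tau_ms, c(0.8, 250), tolerance = 1e-9)
  expect_equal(cl$area, c(0.3, 0.7), tolerance = 1e-9)
  op <- predictedDwellComponents(m, "open")
  expect_equal(op$tau_ms, c(0.6, 2.1), tolerance = 1e-9)
  expect_equal(op$area, c(0.64, 0.36), tolerance = 1e-9)
})

test_that("model JSON files round trip and are validated on load", {
  m <- chainModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeGatingModel(m, path)
  m2 <- readGatingModel(path)
  expect_equal(m2@Q, m@Q, tolerance = 1e-12)
  expect_identical(m2@stateNames, m@stateNames)

  j <- jsonlite::read_json(path)
  j$states <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, bad, auto_unbox = TRUE)
  expect_error(readGatingModel(bad), "states")
})
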