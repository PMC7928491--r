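test_that("fold-change tests follow the closed-form arithmetic", {
  fc <- foldChangeTest(c(0.8, 0.9, 1.0), 1.0)
  expect_equal(fc$mean_fold, 0.9, tolerance = 1e-12)
  expect_equal(fc$t, -sqrt(3), tolerance = 1e-9)
  expect_equal(fc$df, 2)

  same <- foldChangeTest(rep(2.5, 4), 2.5)
  expect_equal(same$mean_fold, 1.0)
  expect_true(same$degenerate)
  expect_true(is.na(same$p))

  five <- foldChangeTest(c(1.1, 0.9, 1.2, 1.05, 0.95), 1.0)
  expect_equal(five$df, 4)  # n = 5 patches
  six <- foldChangeTest(rnorm(6, 1, 0.1), 1.0)
  expect_equal(six$df, 5)
})

test_that("fold-change testing is invariant to common rescaling", {
  v <- c(2.1, 1.8, 2.4, 2.0)
  a <- foldChangeTest(v, 2.0)
  b <- foldChangeTest(10 * v, 20.0)
  expect_equal(a$folds, b$folds, tolerance = 1e-12)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("t statistics match the textbook pooled-variance formulas", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- unpairedT(a, b)
  # independent textbook-formula oracle
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  eq <- unpairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  one <- oneSampleT(c(2, 2, 2, 2), 2)
  expect_true(one$degenerate)

  v <- c(4.2, 5.1, 3.9, 4.8)
  o <- oneSampleT(v, 4)
  t_o <- (mean(v) - 4) / (sd(v) / sqrt(4))
  expect_equal(o$t, t_o, tolerance = 1e-12)
})

test_that("one-sample t p-values are uniform under the null", {
  ps <- vapply(1:2000, function(s) {
    set.seed(s)
    oneSampleT(rnorm(6, 1, 0.2), 1)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("two-way ANOVA reports Type II tables and Tukey contrasts", {
  # 2x2 with 5 + 8 subjects contributing both amplitude classes: the
  # 26-observation design has residual df 22
  set.seed(3)
  conc <- rep(c("low", "high"), times = c(10, 16))
  cls <- rep(c("O_S", "O_L"), times = 13)
  y <- rnorm(26, ifelse(cls == "O_S", 1.05, 2.06), 0.1)
  res <- twoWayAnova(y, conc, cls)
  expect_equal(res$residual_df, 22)
  expect_false(res$degenerate)
  expect_true(all(c("A", "B", "A:B") %in% res$table$term))
  expect_equal(res$table$df[res$table$term == "Residuals"], 22)
  expect_lt(res$table$p[res$table$term == "B"], 1e-4)
  expect_s3_class(res$tukey, "TukeyHSD")

  # degenerate: identical values in every cell
  expect_true(twoWayAnova(rep(1, 8), rep(c("a", "b"), 4),
                          rep(c("x", "y"), each = 4))$degenerate)
  expect_error(twoWayAnova(1:4, c("a", "a", "b", "b"),
                           c("x", "x", "x", "y")), "empty design cell")
})

test_that("balanced designs reduce to textbook sums of squares", {
  set.seed(8)
  A <- rep(c("a1", "a2"), each = 6)
  B <- rep(rep(c("b1", "b2"), each = 3), 2)
  y <- rnorm(12, as.numeric(factor(A)) + 0.5 * as.numeric(factor(B)), 0.3)
  res <- twoWayAnova(y, A, B)
  # independent sums-of-squares oracle for the balanced case
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(A, B), mean)
  ssc <- 3 * sum((cellm - gm)^2)
  ssab <- ssc - ssa - ssb
  tab <- res$table
  expect_equal(tab$sum_sq[tab$term == "A"], ssa, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "B"], ssb, tolerance = 1e-9)
  expect_equal(tab$sum_sq[tab$term == "A:B"], ssab, tolerance = 1e-9)
})

test_that("group comparison mirrors the fold-change report layout", {
  vals <- list(amplitude_pA = c(0.9, 1.0, 1.1),
               t_crit_ms = c(3.2, 3.8, 3.4))
  refs <- c(amplitude_pA = 1.0, t_crit_ms = 3.5)
  tab <- groupComparison(vals, refs)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_fold[tab$property == "amplitude_pA"], 1.0,
               tolerance = 1e-12)
  expect_equal(tab$df, c(2, 2))

  # mutant group at reference means: all folds 1.0
  self <- groupComparison(list(a = c(2, 2, 2)), c(a = 2))
  expect_equal(self$mean_fold, 1)

  expect_warning(out <- groupComparison(list(a = c(1, 2)), c(b = 1)),
                 "no reference")
  expect_equal(nrow(out), 0)

  # single-patch properties are reported without a test
  single <- suppressWarnings(
    groupComparison(list(a = 1.5), c(a = 1.0)))
  expect_equal(single$n, 1)
  expect_true(is.na(single$p))
})

test_that("a suppressed mutant group shows the expected fold deficit", {
  # synthetic group whose amplitudes sit at 0.65x the wildtype mean
  set.seed(14)
  ref <- 1.5
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    v <- rnorm(6, 0.65 * ref, 0.08 * ref)
    fc <- foldChangeTest(v, ref)
    abs(fc$mean_fold - 0.65) < 0.12 && fc$p < 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("significance stars follow the reporting convention", {
  expect_identical(significanceStars(c(0.2, 0.04, 0.009, 5e-4, 5e-5, NA)),
                   c("", "*", "**", "***", "****", ""))
})
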