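#' Significance stars
#'
#' Conventional star coding: `*`, `**`, `***`, `****` for p below 0.05,
#' 0.01, 0.001 and 0.0001; empty string otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' One-sample and unpaired two-sample Student t-tests
#'
#' Thin wrappers over the classical Student formulas (two-tailed; the
#' unpaired test uses the pooled-variance form). Degenerate inputs
#' (zero variance) are flagged rather than raising.
#'
#' @param values,a,b numeric vectors (n >= 2 per group).
#' @param mu null-hypothesis mean for the one-sample test.
#' @return list with `t`, `df`, `p` (two-tailed) and `degenerate`.
#' @export
oneSampleT <- function(values, mu) {
  stopifnot(length(values) >= 2)
  n <- length(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' @rdname oneSampleT
#' @export
unpairedT <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0)
    return(list(t = if (mean(a) == mean(b)) 0 else NA_real_,
                df = length(a) + length(b) - 2L,
                p = if (mean(a) == mean(b)) 1 else NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Fold-change test of a patch group against a reference mean
#'
#' Divides each patch's property value by the reference (wildtype
#' group) mean and tests the per-patch fold changes against the
#' hypothetical value 1.0 (no change) with a two-tailed one-sample
#' Student t-test.
#'
#' @param patchValues numeric per-patch property values (n >= 2).
#' @param referenceMean positive scalar, the published wildtype group
#'   mean of the same property.
#' @param property optional property name for reporting.
#' @return list with `property`, `folds`, `mean_fold`, `sem_fold`,
#'   `t`, `df`, `p` (omitted as `NA` when the fold variance is zero,
#'   with `degenerate = TRUE`), `stars`, `n`, `reference_mean`.
#' @export
foldChangeTest <- function(patchValues, referenceMean,
                           property = "property") {
  stopifnot(referenceMean > 0, length(patchValues) >= 2)
  folds <- patchValues / referenceMean
  n <- length(folds)
  res <- oneSampleT(folds, mu = 1)
  list(property = property, folds = folds,
       mean_fold = mean(folds),
       sem_fold = stats::sd(folds) / sqrt(n),
       t = res$t, df = res$df, p = res$p,
       degenerate = res$degenerate,
       stars = significanceStars(res$p),
       n = n, reference_mean = referenceMean)
}

#' Two-way ANOVA with Type II sums of squares and Tukey HSD
#'
#' Fits the full two-factor interaction model and reports Type II sums
#' of squares (robust to the unbalanced group sizes typical of patch
#' counts), with residual degrees of freedom `N - levels_a * levels_b`,
#' plus Tukey honestly-significant-difference pairwise comparisons.
#' A design with identical values in every cell (zero residual
#' variance) is flagged degenerate rather than reported with
#' meaningless F ratios.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (coerced), >= 2 levels each; every
#'   cell must contain at least one observation.
#' @return list with `table` (term, sum_sq, df, F, p), `residual_df`,
#'   `tukey` (from [stats::TukeyHSD()]), `degenerate`.
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  fa <- factor(factorA); fb <- factor(factorB)
  stopifnot(nlevels(fa) >= 2, nlevels(fb) >= 2,
            length(values) == length(fa), length(fa) == length(fb))
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 levels(fa)[empty[1]], levels(fb)[empty[2]]))
  }
  df <- data.frame(y = values, A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = df)
  rdf <- length(values) - nlevels(fa) * nlevels(fb)
  resid_ss <- sum(stats::residuals(fit)^2)
  if (resid_ss < 1e-12 * max(1, sum(values^2))) {
    return(list(table = NULL, residual_df = rdf, tukey = NULL,
                degenerate = TRUE))
  }
  a2 <- car::Anova(fit, type = 2)
  tab <- data.frame(
    term = rownames(a2), sum_sq = a2[["Sum Sq"]], df = a2[["Df"]],
    F = a2[["F value"]], p = a2[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  tukey <- stats::TukeyHSD(stats::aov(y ~ A * B, data = df))
  list(table = tab, residual_df = rdf, tukey = tukey,
       degenerate = FALSE)
}

#' Fold-change comparison of a mutant group against reference means
#'
#' Runs [foldChangeTest()] for every property present in both the
#' per-patch value table and the reference-mean map, producing a
#' summary table in the layout of a mutant-versus-wildtype report:
#' property, group mean +/- SEM, fold change +/- SEM, t, df, p and
#' significance stars. Properties missing a reference mean are skipped
#' with a warning. Properties observed in fewer than 2 patches are
#' reported with counts only (no test), mirroring the treatment of
#' single-patch amplitude classes.
#'
#' @param patchValues named list: property -> numeric per-patch values.
#' @param referenceMeans named numeric: property -> wildtype group mean.
#' @return data.frame, one row per tested property.
#' @export
groupComparison <- function(patchValues, referenceMeans) {
  stopifnot(is.list(patchValues))
  out <- list()
  for (prop in names(patchValues)) {
    if (!prop %in% names(referenceMeans)) {
      warning("no reference mean for property '", prop, "'; skipped")
      next
    }
    v <- patchValues[[prop]]
    v <- v[is.finite(v)]
    n <- length(v)
    if (n < 2) {
      out[[prop]] <- data.frame(
        property = prop, n = n,
        mean = if (n) mean(v) else NA_real_, sem = NA_real_,
        mean_fold = if (n) mean(v) / referenceMeans[[prop]] else NA_real_,
        sem_fold = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
        stars = "", stringsAsFactors = FALSE)
      next
    }
    fc <- foldChangeTest(v, referenceMeans[[prop]], property = prop)
    out[[prop]] <- data.frame(
      property = prop, n = n, mean = mean(v),
      sem = stats::sd(v) / sqrt(n),
      mean_fold = fc$mean_fold, sem_fold = fc$sem_fold,
      t = fc$t, df = fc$df, p = fc$p, stars = fc$stars,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(property = character(0), n = integer(0),
                      mean = numeric(0), sem = numeric(0),
                      mean_fold = numeric(0), sem_fold = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
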