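#' Choose between ANOVA and Wilcoxon for a two-group comparison
#'
#' Assumption gates: Shapiro-Wilk normality within each group and the
#' classical Levene test (absolute deviations from the group mean)
#' across the two groups. If any gate p-value falls below `alpha` — or a
#' gate cannot be evaluated (group below the Shapiro minimum of 3, or
#' constant values) — the nonparametric Wilcoxon rank-sum test is
#' selected; otherwise the analysis-of-variance model is used.
#'
#' @param values_a,values_b Numeric vectors (missing values removed by
#'   the caller or here).
#' @param alpha Gate significance level.
#' @return List with `test` (`"anova"` or `"wilcoxon"`), `shapiro_p`
#'   (length-2, NA when not evaluable), `levene_p`, and `gates_evaluable`.
#' @export
choose_test <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  sw <- c(NA_real_, NA_real_)
  lv <- NA_real_
  evaluable <- length(values_a) >= 3 && length(values_b) >= 3
  if (evaluable) {
    sw_try <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                                   error = function(e) NA_real_)
    sw <- c(sw_try(values_a), sw_try(values_b))
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    lv <- tryCatch(
      car::leveneTest(c(values_a, values_b), g, center = mean)[1, "Pr(>F)"],
      error = function(e) NA_real_)
    evaluable <- !anyNA(c(sw, lv))
  }
  test <- if (!evaluable || any(c(sw, lv) < alpha)) "wilcoxon" else "anova"
  list(test = test, shapiro_p = sw, levene_p = lv, gates_evaluable = evaluable)
}

# two-group tests on a single feature's values
.test_feature <- function(va, vb, alpha) {
  gate <- choose_test(va, vb, alpha)
  pooled <- c(va, vb)
  zero_var <- stats::var(pooled) == 0
  if (zero_var) {
    gate$test <- "wilcoxon"
    return(c(gate[setdiff(names(gate), "test")],
             list(p = 1, zero_variance = TRUE, test = "wilcoxon")))
  }
  if (gate$test == "anova") {
    g <- factor(rep(c("a", "b"), c(length(va), length(vb))))
    p <- stats::anova(stats::lm(pooled ~ g))[1, "Pr(>F)"]
  } else {
    exact <- max(length(va), length(vb)) <= 25
    p <- suppressWarnings(
      stats::wilcox.test(va, vb, exact = exact, correct = TRUE)$p.value)
  }
  c(gate[setdiff(names(gate), "test")],
    list(p = p, zero_variance = FALSE, test = gate$test))
}

#' Percent change between group means
#'
#' Signed percent difference of group A relative to group B,
#' `100 * (mean_a - mean_b) / mean_b`, computed on raw/corrected-scale
#' arithmetic means (not on log values).
#'
#' @param mean_a,mean_b Raw-scale mean abundances; `mean_b` must be > 0.
#' @return Signed percent change.
#' @export
percent_change <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) stop("reference mean must be > 0")
  100 * (mean_a - mean_b) / mean_b
}

#' Per-feature two-group screening
#'
#' For every feature: missing values are excluded within the feature,
#' the assumption-gated test ([choose_test()]) is applied to the log10
#' intensities, and descriptives (mean, standard error, n per group,
#' percent change) are computed — means and percent change on the
#' back-transformed corrected scale (`10^x`), matching how fold changes
#' are reported for metabolite abundances. Features with fewer than 2
#' present values in either group are flagged untestable and carry
#' `p_raw = NA`; they are excluded from the FDR family.
#'
#' @param table `feature_table` on log10 scale.
#' @param group_a,group_b Group (or subgroup) labels; A is compared
#'   against B, so percent change is relative to B.
#' @param alpha Gate significance level.
#' @return Data frame with one row per feature: `feature_id`,
#'   `comparison`, `test_used`, `p_raw`, `p_fdr` (NA until
#'   [adjust_fdr()]), `percent_change`, `mean_a`, `se_a`, `n_a`,
#'   `mean_b`, `se_b`, `n_b`, `shapiro_p_a`, `shapiro_p_b`, `levene_p`,
#'   `gates_evaluable`, `zero_variance`, `testable`.
#' @export
compare_groups <- function(table, group_a, group_b, alpha = 0.05) {
  if (table$scale != "log10")
    stop("compare_groups expects a log10-scale table; got '", table$scale, "'")
  ia <- group_indices(table, group_a)
  ib <- group_indices(table, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples")
  m <- table$intensities
  comparison <- paste(group_a, "vs", group_b)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    va <- m[ia, j]; va <- va[!is.na(va)]
    vb <- m[ib, j]; vb <- vb[!is.na(vb)]
    raw_a <- 10^va; raw_b <- 10^vb
    base <- data.frame(
      feature_id = table$features$feature_id[j], comparison = comparison,
      n_a = length(va), n_b = length(vb),
      mean_a = if (length(va)) mean(raw_a) else NA_real_,
      se_a = if (length(va) > 1) stats::sd(raw_a) / sqrt(length(va)) else NA_real_,
      mean_b = if (length(vb)) mean(raw_b) else NA_real_,
      se_b = if (length(vb) > 1) stats::sd(raw_b) / sqrt(length(vb)) else NA_real_,
      stringsAsFactors = FALSE)
    if (length(va) < 2 || length(vb) < 2) {
      base$test_used <- NA_character_; base$p_raw <- NA_real_
      base$shapiro_p_a <- NA_real_; base$shapiro_p_b <- NA_real_
      base$levene_p <- NA_real_; base$gates_evaluable <- FALSE
      base$zero_variance <- NA; base$testable <- FALSE
      base$percent_change <- NA_real_
      return(base)
    }
    r <- .test_feature(va, vb, alpha)
    base$test_used <- r$test; base$p_raw <- r$p
    base$shapiro_p_a <- r$shapiro_p[1]; base$shapiro_p_b <- r$shapiro_p[2]
    base$levene_p <- r$levene_p; base$gates_evaluable <- r$gates_evaluable
    base$zero_variance <- r$zero_variance; base$testable <- TRUE
    base$percent_change <- percent_change(base$mean_a, base$mean_b)
    base
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Fills `p_fdr` with step-up adjusted p-values. The family is the set of
#' testable features within one comparison (and one polarity, since a
#' feature table holds a single polarity); untestable features keep
#' `p_fdr = NA`.
#'
#' @param results Data frame from [compare_groups()] (one comparison).
#' @return The same data frame with `p_fdr` filled.
#' @export
adjust_fdr <- function(results) {
  if (length(unique(results$comparison)) > 1)
    stop("adjust_fdr expects a single comparison; split first")
  idx <- which(results$testable)
  results$p_fdr[idx] <- stats::p.adjust(results$p_raw[idx], method = "BH")
  results
}
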