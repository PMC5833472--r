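#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed by pair counting:
#' (# pairs with positive score > negative score + 0.5 * # ties) /
#' (n_pos * n_neg). The reported AUC is auto-oriented to be >= 0.5, with
#' the orientation recorded; `auc_raw` keeps the unoriented value.
#'
#' @param scores_pos,scores_neg Numeric scores for the positive and
#'   negative group.
#' @return List with `auc` (>= 0.5), `auc_raw`, `orientation`
#'   (`"pos_high"` if the positive group scores higher, else
#'   `"neg_high"`).
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (!length(scores_pos) || !length(scores_neg))
    stop("both groups must be non-empty")
  # rank-based pair count: O((n+m) log(n+m))
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  auc_raw <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (auc_raw >= 0.5)
    list(auc = auc_raw, auc_raw = auc_raw, orientation = "pos_high")
  else
    list(auc = 1 - auc_raw, auc_raw = auc_raw, orientation = "neg_high")
}

#' Youden-optimal ROC threshold
#'
#' Scans candidate thresholds (midpoints between adjacent distinct
#' pooled scores, plus -Inf and +Inf) and maximizes the Youden index
#' J = sensitivity + specificity - 1, where a sample is called positive
#' when its score exceeds the threshold. Ties in J are broken toward
#' higher sensitivity, then toward the lower threshold, making the
#' result deterministic.
#'
#' @inheritParams auc_mann_whitney
#' @return List with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_threshold <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (!length(scores_pos) || !length(scores_neg))
    stop("both groups must be non-empty")
  v <- sort(unique(c(scores_pos, scores_neg)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(cand, function(th) mean(scores_pos > th), numeric(1))
  spec <- vapply(cand, function(th) mean(scores_neg <= th), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cand[best])]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], J = J[best])
}

#' DeLong inference for the AUC
#'
#' Structural-components (DeLong) variance of the Mann-Whitney AUC,
#' Wald 95% confidence interval truncated to [0, 1], and a one-sided
#' p-value for H1: AUC > 0.5 from the normal approximation. When the
#' variance degenerates to zero (e.g. perfect separation) the p-value is
#' reported as a floor value with `degenerate = TRUE`.
#'
#' @inheritParams auc_mann_whitney
#' @return List with `auc` (unoriented), `var`, `ci95_low`, `ci95_high`,
#'   `p_greater`, `degenerate`.
#' @export
delong_inference <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  m <- length(scores_pos); n <- length(scores_neg)
  if (m < 2 || n < 2) stop("DeLong inference needs >= 2 scores per group")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  # V10_i: mean kernel of positive i against all negatives; V01_j likewise
  v10 <- vapply(scores_pos, function(x) mean(psi(x, scores_neg)), numeric(1))
  v01 <- vapply(scores_neg, function(y) mean(psi(scores_pos, y)), numeric(1))
  auc <- mean(v10)
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  v <- s10 / m + s01 / n
  degenerate <- v <= 0
  if (degenerate) {
    p <- if (auc > 0.5) 1e-16 else if (auc < 0.5) 1 else 0.5
    ci <- c(auc, auc)
  } else {
    z <- (auc - 0.5) / sqrt(v)
    p <- stats::pnorm(z, lower.tail = FALSE)
    ci <- auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)
    ci <- pmin(pmax(ci, 0), 1)
  }
  list(auc = auc, var = v, ci95_low = ci[1], ci95_high = ci[2],
       p_greater = p, degenerate = degenerate)
}

#' Per-feature ROC analysis for a comparison
#'
#' Runs [auc_mann_whitney()], [youden_threshold()] and
#' [delong_inference()] on each listed feature's log10 intensities,
#' orienting scores so the reported AUC is >= 0.5 (Youden and DeLong run
#' on the oriented scores).
#'
#' @param table `feature_table` (log10 scale).
#' @param group_a,group_b Labels; group A is "positive" before
#'   auto-orientation.
#' @param feature_ids Features to analyse (default all).
#' @return Data frame: `feature_id`, `comparison`, `auc`, `ci95_low`,
#'   `ci95_high`, `p_greater`, `youden_threshold`, `sensitivity`,
#'   `specificity`, `orientation`, `degenerate`.
#' @export
roc_features <- function(table, group_a, group_b, feature_ids = NULL) {
  ia <- group_indices(table, group_a)
  ib <- group_indices(table, group_b)
  if (is.null(feature_ids)) feature_ids <- table$features$feature_id
  j_idx <- match(feature_ids, table$features$feature_id)
  if (anyNA(j_idx)) stop("unknown feature_id: ", feature_ids[which(is.na(j_idx))[1]])
  comparison <- paste(group_a, "vs", group_b)
  rows <- lapply(j_idx, function(j) {
    va <- table$intensities[ia, j]; va <- va[!is.na(va)]
    vb <- table$intensities[ib, j]; vb <- vb[!is.na(vb)]
    a <- auc_mann_whitney(va, vb)
    if (a$orientation == "pos_high") { sp <- va; sn <- vb } else { sp <- vb; sn <- va }
    yj <- youden_threshold(sp, sn)
    dl <- delong_inference(sp, sn)
    data.frame(feature_id = table$features$feature_id[j],
               comparison = comparison,
               auc = a$auc, ci95_low = dl$ci95_low, ci95_high = dl$ci95_high,
               p_greater = dl$p_greater,
               youden_threshold = yj$threshold,
               sensitivity = yj$sensitivity, specificity = yj$specificity,
               orientation = a$orientation, degenerate = dl$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-median imputation
#'
#' Replaces each missing value by the median of the feature's present
#' values within the sample's own group. Features with no present value
#' in some group (among the listed groups) cannot be imputed there and
#' are dropped, with the drop recorded in the `dropped` attribute.
#'
#' @param table `feature_table` (any scale).
#' @param groups Group labels defining the imputation strata; samples
#'   outside these groups (including QCs) are removed from the result.
#' @return A `feature_table` restricted to the listed groups with no
#'   missing values; attribute `dropped` lists removed feature ids.
#' @export
impute_median_by_group <- function(table, groups) {
  idx_list <- lapply(groups, function(g) group_indices(table, g))
  keep_samples <- sort(unique(unlist(idx_list)))
  m <- table$intensities[keep_samples, , drop = FALSE]
  # strata may overlap when one label is a nested subgroup; impute per
  # stratum but write each sample once (later strata win only for cells
  # still missing)
  dropped <- logical(ncol(m))
  for (g in seq_along(groups)) {
    rows <- match(idx_list[[g]], keep_samples)
    sub <- m[rows, , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      miss <- is.na(sub[, j])
      if (!any(miss)) next
      med <- stats::median(sub[!miss, j])
      if (is.na(med)) { dropped[j] <- TRUE; next }
      sub[miss, j] <- med
    }
    m[rows, ] <- sub
  }
  keep_features <- which(!dropped & colSums(is.na(m)) == 0)
  dropped_ids <- table$features$feature_id[setdiff(seq_len(ncol(m)), keep_features)]
  out <- feature_table(m[, keep_features, drop = FALSE],
                       table$samples[keep_samples, , drop = FALSE],
                       table$features[keep_features, , drop = FALSE],
                       scale = table$scale)
  attr(out, "dropped") <- dropped_ids
  out
}

#' SVM leave-one-out classification accuracy
#'
#' Soft-margin support vector machine with radial-basis kernel,
#' evaluated by leave-one-out cross-validation: each sample is predicted
#' by a machine trained on the remaining n - 1. Features are
#' standardized inside each training fold (e1071's `scale = TRUE`), so
#' no information leaks from the held-out sample. Deterministic for
#' given data and hyperparameters.
#'
#' The default workflow imputes the full matrix by group medians before
#' LOOCV (the held-out sample's own intensities contribute to the
#' medians that fill other samples — a mild, documented leakage).
#' `strict_impute = TRUE` instead accepts a matrix with missing values
#' and recomputes the per-group medians inside every training fold,
#' imputing the held-out sample from training members of its group
#' only.
#'
#' @param X Numeric matrix (samples x features); fully observed unless
#'   `strict_impute = TRUE` (e.g. after [impute_median_by_group()]).
#' @param y Two-class labels, >= 2 samples per class.
#' @param cost Soft-margin cost parameter.
#' @param gamma Kernel width; default `1/ncol(X)` (on standardized
#'   features, i.e. 1 / (n_features x unit variance)).
#' @param seed Recorded in the report (the LOOCV itself is
#'   deterministic).
#' @param strict_impute Recompute group medians within each training
#'   fold instead of requiring a pre-imputed matrix.
#' @return An `svm_report` list: `accuracy` (percent), `per_class`
#'   (percent per class), `n`, `predictions`, `hyperparameters`, `seed`.
#' @export
svm_loocv_accuracy <- function(X, y, cost = 1, gamma = NULL, seed = 1,
                               strict_impute = FALSE) {
  X <- as.matrix(X)
  if (!strict_impute && anyNA(X))
    stop("X must be fully observed; impute first or use strict_impute")
  y <- factor(y)
  if (nlevels(y) != 2) stop("two classes required")
  if (any(table(y) < 2)) stop("each class needs >= 2 samples")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  n <- nrow(X)
  fold_impute <- function(Xtr, ytr, xte, yte) {
    for (lv in levels(y)) {
      rows <- ytr == lv
      med <- apply(Xtr[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
      if (anyNA(med))
        stop("a feature has no present training value in class '", lv, "'")
      for (j in which(colSums(is.na(Xtr[rows, , drop = FALSE])) > 0)) {
        miss <- rows & is.na(Xtr[, j])
        Xtr[miss, j] <- med[j]
      }
      if (yte == lv) xte[is.na(xte)] <- med[is.na(xte)]
    }
    list(Xtr = Xtr, xte = xte)
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  .with_seed(seed, for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    xte <- X[i, ]
    if (strict_impute) {
      fi <- fold_impute(Xtr, y[-i], xte, y[i])
      Xtr <- fi$Xtr
      xte <- fi$xte
    }
    scale_col <- apply(Xtr, 2, stats::sd) > 0  # constant columns unscalable
    fit <- e1071::svm(Xtr, y[-i], type = "C-classification",
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = scale_col)
    pred[i] <- stats::predict(fit, matrix(xte, 1, dimnames = list(NULL, colnames(X))))
  })
  correct <- pred == y
  per_class <- vapply(levels(y),
                      function(lv) 100 * mean(correct[y == lv]), numeric(1))
  structure(list(
    accuracy = 100 * mean(correct), per_class = per_class,
    n = as.integer(table(y)), predictions = pred, truth = y,
    hyperparameters = list(kernel = "radial", cost = cost, gamma = gamma,
                           standardized = TRUE, strict_impute = strict_impute),
    seed = seed
  ), class = "svm_report")
}

#' @export
print.svm_report <- function(x, ...) {
  cat("SVM (RBF) leave-one-out accuracy: ",
      sprintf("%.1f%%", x$accuracy), " on ", sum(x$n), " samples\n", sep = "")
  for (lv in names(x$per_class))
    cat("  ", lv, ": ", sprintf("%.1f%%", x$per_class[lv]), "\n", sep = "")
  invisible(x)
}
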