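# "Present" means a non-missing intensity > 0; on a validated raw-scale
# table that reduces to !is.na().
.present <- function(m) !is.na(m) & m > 0

.filter_stage <- function(table, keep, stage, reason) {
  removed <- table$features$feature_id[!keep]
  report <- data.frame(
    stage = stage,
    features_in = ncol(table$intensities),
    features_out = sum(keep),
    stringsAsFactors = FALSE
  )
  report$removed <- list(removed)
  out <- subset_table(table, features = which(keep))
  attr(report, "reasons") <- if (length(removed))
    data.frame(feature_id = removed, stage = stage, reason = reason,
               stringsAsFactors = FALSE)
  else
    data.frame(feature_id = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(table = out, report = report)
}

#' QC-presence filter
#'
#' Removes features detected in fewer than `min_frac` of the QC
#' injections. A feature present in exactly `min_frac` of QCs survives
#' (the removal rule is "less than", so 50% presence passes at the 0.50
#' default).
#'
#' @param table Raw-scale `feature_table` containing QC injections.
#' @param min_frac Minimum QC presence fraction to keep a feature.
#' @return A list with elements `table` (filtered) and `report` (one-row
#'   stage fragment; removed ids in `report$removed[[1]]`).
#' @export
filter_qc_presence <- function(table, min_frac) {
  qc <- table$samples$is_qc
  if (!any(qc)) stop("table contains no QC samples")
  pres <- colMeans(.present(table$intensities[qc, , drop = FALSE]))
  res <- .filter_stage(table, pres >= min_frac, "qc_presence",
                       "QC presence below threshold")
  attr(res$report, "qc_presence_frac") <- pres
  res
}

#' QC coefficient-of-variation filter
#'
#' Removes features whose sd/mean over present QC intensities (raw scale,
#' sample standard deviation, n-1 denominator) exceeds `max_cv`. Features
#' with fewer than two present QC values cannot yield a CV and are
#' removed with reason "insufficient QC values".
#'
#' @inheritParams filter_qc_presence
#' @param max_cv Maximum allowed QC CV (e.g. 0.30 for 30%).
#' @return As [filter_qc_presence()].
#' @export
filter_qc_cv <- function(table, max_cv) {
  qc <- table$samples$is_qc
  if (!any(qc)) stop("table contains no QC samples")
  qcm <- table$intensities[qc, , drop = FALSE]
  cv <- apply(qcm, 2, function(v) {
    v <- v[.present(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  keep <- !is.na(cv) & cv <= max_cv
  reason <- ifelse(is.na(cv[!keep]), "insufficient QC values",
                   "QC CV above threshold")
  res <- .filter_stage(table, keep, "qc_cv", reason)
  attr(res$report, "qc_cv") <- cv
  res
}

#' Group-presence filter
#'
#' Keeps features present in at least `min_frac` of the members of at
#' least one listed study group ("any group" semantics). QC injections do
#' not enter the computation.
#'
#' @inheritParams filter_qc_presence
#' @param min_frac Minimum within-group presence fraction.
#' @param groups Character vector of group labels to consider.
#' @return As [filter_qc_presence()].
#' @export
filter_group_presence <- function(table, min_frac, groups) {
  nf <- ncol(table$intensities)
  fracs <- vapply(groups, function(g) {
    idx <- group_indices(table, g)
    colMeans(.present(table$intensities[idx, , drop = FALSE]))
  }, numeric(nf))
  fracs <- matrix(fracs, nrow = nf, ncol = length(groups))
  maxfrac <- do.call(pmax, c(lapply(seq_along(groups), function(k) fracs[, k]),
                             list(numeric(nf))))
  res <- .filter_stage(table, maxfrac >= min_frac, "group_presence",
                       "below group presence in every group")
  attr(res$report, "max_group_presence_frac") <- maxfrac
  res
}

#' Bracketing-QC drift correction
#'
#' Removes within-batch instrumental drift by rescaling every intensity
#' against the QC signal interpolated at its injection position. For each
#' feature and batch, the expected QC level at injection index i is the
#' linear interpolation (on injection index) between the nearest
#' preceding and following QC injections with a present value; positions
#' before the first or after the last such QC use that QC's value
#' unchanged (constant extrapolation). The corrected value is
#' `raw * ref / expected` where `ref` is the study-wide median of the
#' feature's present QC intensities, so corrected batches share a common
#' reference level. If a batch holds fewer than two present QC values for
#' a feature, that batch's values of the feature are left uncorrected and
#' the (feature, batch) pair is logged in the `uncorrected` attribute.
#'
#' @param table Raw-scale `feature_table`; every batch must contain at
#'   least one QC injection (two or more for correction to act).
#' @return The corrected `feature_table` (`scale = "corrected"`), with
#'   attribute `uncorrected`: a data frame of skipped (feature, batch)
#'   pairs.
#' @export
correct_qc_bracketing <- function(table) {
  if (!table$scale %in% c("raw"))
    stop("drift correction expects a raw-scale table; got '", table$scale, "'")
  smp <- table$samples
  m <- table$intensities
  if (!any(smp$is_qc)) stop("table contains no QC samples")
  for (b in unique(smp$batch)) {
    if (!any(smp$is_qc[smp$batch == b]))
      stop("batch ", b, " contains no QC injections")
  }
  qc_all <- smp$is_qc
  out <- m
  skipped <- list()
  for (j in seq_len(ncol(m))) {
    qv <- m[qc_all, j]
    qv <- qv[!is.na(qv)]
    if (length(qv) == 0) next
    ref <- stats::median(qv)
    for (b in unique(smp$batch)) {
      in_b <- smp$batch == b
      qc_b <- which(in_b & qc_all & !is.na(m[, j]))
      if (length(qc_b) < 2) {
        skipped[[length(skipped) + 1]] <-
          data.frame(feature_id = table$features$feature_id[j], batch = b)
        next
      }
      xi <- smp$injection_index[qc_b]
      yi <- m[qc_b, j]
      o <- order(xi)
      rows <- which(in_b)
      expected <- stats::approx(xi[o], yi[o],
                                xout = smp$injection_index[rows],
                                method = "linear", rule = 2)$y
      out[rows, j] <- m[rows, j] * ref / expected
    }
  }
  res <- feature_table(out, smp, table$features, scale = "corrected")
  attr(res, "uncorrected") <- if (length(skipped))
    do.call(rbind, skipped)
  else
    data.frame(feature_id = character(0), batch = integer(0))
  res
}

#' log10 transform
#'
#' Replaces every present intensity by its common logarithm to bring the
#' per-feature distributions closer to normality; missing values stay
#' missing. Applying it twice is an error.
#'
#' @param table A raw- or corrected-scale `feature_table`.
#' @return The transformed table with `scale = "log10"`.
#' @export
log10_transform <- function(table) {
  if (!table$scale %in% c("raw", "corrected"))
    stop("table is already on scale '", table$scale, "'")
  m <- table$intensities
  if (any(!is.na(m) & m <= 0))
    stop("non-positive intensity cannot be log-transformed")
  res <- table
  res$intensities <- log10(m)
  res$scale <- "log10"
  res
}

#' Run the full preprocessing chain
#'
#' Applies, in order: QC-presence filter, QC-CV filter, group-presence
#' filter, bracketing-QC drift correction, log10 transform. Filtering
#' precedes correction, so the CVs recorded in the report are
#' pre-correction values.
#'
#' @param table Raw-scale `feature_table`.
#' @param config A `study_config`; thresholds are taken from it.
#' @param groups Group labels for the presence filter; defaults to all
#'   group labels found in the table.
#' @return A list with `table` (log10 scale, filtered, corrected),
#'   `report` (a `filter_report`), and `uncorrected` (skipped
#'   feature/batch pairs from the drift correction).
#' @export
run_preprocess <- function(table, config = default_config(), groups = NULL) {
  if (is.null(groups))
    groups <- unique(stats::na.omit(table$samples$group))
  s1 <- filter_qc_presence(table, config$qc_presence_min_frac)
  s2 <- filter_qc_cv(s1$table, config$qc_cv_max)
  s3 <- filter_group_presence(s2$table, config$group_presence_min_frac, groups)
  corrected <- correct_qc_bracketing(s3$table)
  logged <- log10_transform(corrected)
  report <- filter_report(list(s1$report, s2$report, s3$report))
  list(table = logged, report = report,
       uncorrected = attr(corrected, "uncorrected"))
}

#' Assemble a filter report
#'
#' Chains per-stage fragments into one report and checks the chain
#' invariant (`features_out` of stage k equals `features_in` of stage
#' k+1; removal sets disjoint).
#'
#' @param fragments List of one-row stage fragments from the filter
#'   functions.
#' @return A `filter_report`: data frame of stages with a `removed`
#'   list-column, plus a `reasons` attribute (feature_id, stage, reason).
#' @export
filter_report <- function(fragments) {
  rep <- do.call(rbind, fragments)
  for (k in seq_len(nrow(rep) - 1)) {
    if (rep$features_out[k] != rep$features_in[k + 1])
      stop("filter report chain broken between stages ", rep$stage[k],
           " and ", rep$stage[k + 1])
  }
  all_removed <- unlist(rep$removed)
  if (anyDuplicated(all_removed))
    stop("a feature was removed at two different stages")
  reasons <- do.call(rbind, lapply(fragments, attr, "reasons"))
  structure(rep, reasons = reasons, class = c("filter_report", class(rep)))
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(report, path) {
  obj <- list(
    stages = lapply(seq_len(nrow(report)), function(k) list(
      stage = report$stage[k],
      features_in = report$features_in[k],
      features_out = report$features_out[k],
      removed = as.list(report$removed[[k]])
    )),
    reasons = attr(report, "reasons")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
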