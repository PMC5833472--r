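#' Construct a feature table
#'
#' A feature table bundles an aligned LC-MS intensity matrix (samples in
#' rows, features in columns) with per-sample and per-feature metadata.
#' It is the object every pipeline stage consumes and returns. Missing
#' intensities (below-detection or alignment dropouts) are held as `NA`,
#' never as zero: zeros would corrupt both QC coefficients of variation
#' and the log10 transform.
#'
#' @param intensities Numeric matrix, samples x features. `NA` marks a
#'   missing value. Row and column names, if present, must agree with the
#'   metadata identifiers.
#' @param samples Data frame with columns `sample_id`, `group` (NA for QC
#'   injections), `batch` (positive integer), `injection_index` (positive
#'   integer, run order within batch, QC injections included), `is_qc`
#'   (logical) and `polarity` (`"positive"` or `"negative"`). Extra
#'   columns (e.g. `subgroup`) are carried along untouched.
#' @param features Data frame with columns `feature_id`, `neutral_mass`
#'   (Da, > 0), `rt_min` (minutes, >= 0), `polarity`, and optionally
#'   `annotation`.
#' @param scale One of `"raw"`, `"corrected"`, `"log10"`; the scale the
#'   intensities are currently on.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features, scale = "raw") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"annotation" %in% names(features))
    features$annotation <- rep(NA_character_, nrow(features))
  if (nrow(intensities) == nrow(samples))
    rownames(intensities) <- as.character(samples$sample_id)
  if (ncol(intensities) == nrow(features))
    colnames(intensities) <- as.character(features$feature_id)
  x <- structure(
    list(intensities = intensities, samples = samples,
         features = features, scale = scale),
    class = "feature_table"
  )
  validate_feature_table(x)
  x
}

#' Validate a feature table
#'
#' Checks every structural invariant of the container and stops with a
#' message naming the offending sample or feature on the first violation.
#' Called by the constructor and the reader; exported so that externally
#' manipulated tables can be re-checked.
#'
#' @param x A `feature_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  m <- x$intensities
  smp <- x$samples
  ft <- x$features
  if (!x$scale %in% c("raw", "corrected", "log10"))
    stop("unknown scale '", x$scale, "'")

  need_s <- c("sample_id", "group", "batch", "injection_index", "is_qc", "polarity")
  miss <- setdiff(need_s, names(smp))
  if (length(miss)) stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  need_f <- c("feature_id", "neutral_mass", "rt_min", "polarity")
  miss <- setdiff(need_f, names(ft))
  if (length(miss)) stop("feature metadata lacks column(s): ", paste(miss, collapse = ", "))

  if (nrow(m) != nrow(smp))
    stop("intensity matrix has ", nrow(m), " rows but ", nrow(smp), " sample records")
  if (ncol(m) != nrow(ft))
    stop("intensity matrix has ", ncol(m), " columns but ", nrow(ft), " feature records")

  dup <- smp$sample_id[duplicated(smp$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", dup[1])
  dup <- ft$feature_id[duplicated(ft$feature_id)]
  if (length(dup)) stop("duplicate feature_id: ", dup[1])

  pol <- unique(c(as.character(smp$polarity), as.character(ft$polarity)))
  bad <- setdiff(pol, c("positive", "negative"))
  if (length(bad)) stop("unknown polarity '", bad[1], "'")
  if (length(pol) > 1)
    stop("a feature table holds exactly one polarity; found: ",
         paste(pol, collapse = ", "))

  if (any(bad_qc <- x$samples$is_qc & !is.na(smp$group)))
    stop("QC sample with a group label: ", smp$sample_id[bad_qc][1])
  if (any(bad_st <- !smp$is_qc & is.na(smp$group)))
    stop("study sample without a group label: ", smp$sample_id[bad_st][1])

  if (any(smp$batch < 1) || any(smp$batch != round(smp$batch)))
    stop("batch must be a positive integer")
  if (any(smp$injection_index < 1) || any(smp$injection_index != round(smp$injection_index)))
    stop("injection_index must be a positive integer")
  key <- paste(smp$batch, smp$injection_index)
  dup <- smp$sample_id[duplicated(key)]
  if (length(dup))
    stop("injection_index not unique within batch for sample: ", dup[1])

  if (any(!is.na(ft$neutral_mass) & ft$neutral_mass <= 0))
    stop("neutral_mass must be > 0; offending feature: ",
         ft$feature_id[which(ft$neutral_mass <= 0)[1]])
  if (any(!is.na(ft$rt_min) & ft$rt_min < 0))
    stop("rt_min must be >= 0; offending feature: ",
         ft$feature_id[which(ft$rt_min < 0)[1]])

  if (x$scale %in% c("raw", "corrected")) {
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive intensity at sample '", rownames(m)[bad[1, 1]],
           "', feature '", colnames(m)[bad[1, 2]], "' on scale '", x$scale, "'")
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  n_qc <- sum(x$samples$is_qc)
  cat("feature_table: ", nrow(x$intensities), " injections (",
      nrow(x$intensities) - n_qc, " study + ", n_qc, " QC), ",
      ncol(x$intensities), " features\n", sep = "")
  cat("  polarity: ", as.character(x$samples$polarity[1]),
      "; scale: ", x$scale,
      "; batches: ", length(unique(x$samples$batch)), "\n", sep = "")
  cat("  missing entries: ", sum(is.na(x$intensities)),
      " (", round(100 * mean(is.na(x$intensities)), 2), "%)\n", sep = "")
  invisible(x)
}

#' Resolve a group label to sample indices
#'
#' Labels usually match the `group` column; a label may instead match the
#' optional `subgroup` column, which expresses nested subgroups (a subset
#' of a clinical group, e.g. cases delivering within a week of diagnosis).
#' QC injections never match.
#'
#' @param table A `feature_table`.
#' @param label Group or subgroup label.
#' @return Integer vector of sample row indices.
#' @export
group_indices <- function(table, label) {
  smp <- table$samples
  hit <- !smp$is_qc & !is.na(smp$group) & smp$group == label
  if (!any(hit) && "subgroup" %in% names(smp)) {
    sg <- as.character(smp$subgroup)
    hit <- !smp$is_qc & !is.na(sg) & sg == label
  }
  if (!any(hit)) stop("unknown group label '", label, "'")
  which(hit)
}

# sniff the field separator from the file extension
.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a feature table from delimited text
#'
#' Expects three files: the intensity matrix (first column `sample_id`,
#' remaining columns one per feature), sample metadata, and feature
#' metadata. Empty cells and the `NA` token become missing values. Zeros
#' in a raw input matrix are treated as missing (aligned exports encode
#' below-detection signals either way) and reported via a message.
#'
#' @param table_path Path to the intensity matrix (TSV or CSV by
#'   extension).
#' @param sample_meta_path Path to sample metadata with columns
#'   `sample_id`, `group`, `batch`, `injection_index`, `is_qc`,
#'   `polarity`.
#' @param feature_meta_path Path to feature metadata with columns
#'   `feature_id`, `neutral_mass`, `rt_min`, `polarity`, `annotation`.
#' @param scale Scale declared for the values on disk (default `"raw"`).
#' @return A validated `feature_table`.
#' @export
read_feature_table <- function(table_path, sample_meta_path, feature_meta_path,
                               scale = "raw") {
  rd <- function(p) utils::read.table(
    p, sep = .delim_for(p), header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = c("NA", ""), comment.char = "",
    quote = "\"")
  mat_df <- rd(table_path)
  smp <- rd(sample_meta_path)
  ft <- rd(feature_meta_path)
  if (names(mat_df)[1] != "sample_id")
    stop("intensity matrix must have 'sample_id' as its first column")
  smp$is_qc <- as.logical(smp$is_qc)
  smp$group <- as.character(smp$group)

  mat_ids <- as.character(mat_df$sample_id)
  extra <- setdiff(smp$sample_id, mat_ids)
  if (length(extra))
    stop("sample metadata lists id absent from the matrix: ", extra[1])
  extra <- setdiff(mat_ids, smp$sample_id)
  if (length(extra))
    stop("matrix row with id absent from sample metadata: ", extra[1])
  feat_ids <- names(mat_df)[-1]
  extra <- setdiff(ft$feature_id, feat_ids)
  if (length(extra))
    stop("feature metadata lists id absent from the matrix: ", extra[1])
  extra <- setdiff(feat_ids, ft$feature_id)
  if (length(extra))
    stop("matrix column with id absent from feature metadata: ", extra[1])

  m <- as.matrix(mat_df[match(smp$sample_id, mat_ids), -1, drop = FALSE])
  m <- m[, match(ft$feature_id, feat_ids), drop = FALSE]
  storage.mode(m) <- "double"
  if (scale == "raw" && any(!is.na(m) & m == 0)) {
    n0 <- sum(!is.na(m) & m == 0)
    message("read_feature_table: ", n0,
            " zero intensities treated as missing (below detection)")
    m[!is.na(m) & m == 0] <- NA_real_
  }
  feature_table(m, smp, ft, scale = scale)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: values are printed at full double
#' precision (17 significant digits) so that a write/read round trip
#' reproduces the table bit-identically, including the missing pattern
#' (`NA` token) and row/column order.
#'
#' @param table A `feature_table`.
#' @param table_path,sample_meta_path,feature_meta_path Output paths;
#'   extension selects TSV (default) or CSV.
#' @return Invisibly, the three paths.
#' @export
write_feature_table <- function(table, table_path, sample_meta_path,
                                feature_meta_path) {
  validate_feature_table(table)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  sep <- .delim_for(table_path)
  m <- table$intensities
  lines <- c(
    paste(c("sample_id", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], fmt(m[i, ])), collapse = sep), character(1))
  )
  writeLines(lines, table_path)
  wr <- function(df, p) utils::write.table(
    df, p, sep = .delim_for(p), row.names = FALSE, quote = FALSE, na = "NA")
  wr(table$samples, sample_meta_path)
  wr(table$features, feature_meta_path)
  invisible(c(table_path, sample_meta_path, feature_meta_path))
}

#' Subset a feature table
#'
#' @param table A `feature_table`.
#' @param samples,features Index vectors (integer, logical, or names);
#'   `NULL` keeps everything.
#' @return A `feature_table` with the selected rows/columns.
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(table$intensities))
  if (is.null(features)) features <- seq_len(ncol(table$intensities))
  if (is.character(samples)) samples <- match(samples, table$samples$sample_id)
  if (is.character(features)) features <- match(features, table$features$feature_id)
  feature_table(table$intensities[samples, features, drop = FALSE],
                table$samples[samples, , drop = FALSE],
                table$features[features, , drop = FALSE],
                scale = table$scale)
}
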