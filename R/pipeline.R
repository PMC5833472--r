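.pkg_version <- function() as.character(utils::packageVersion("metaboscreen"))

#' Simulate a study and write it to disk
#'
#' Generates a synthetic study and writes the intensity matrix, sample
#' and feature metadata, the ground truth (JSON), the generator settings
#' (YAML) and a run manifest into `out_dir`. Re-running with the same
#' settings and seed reproduces identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_simulation <- function(config = sim_config(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config, seed)
  paths <- c(
    table = file.path(out_dir, "intensities.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    features = file.path(out_dir, "features.tsv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "sim_config.yaml"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_feature_table(sim$table, paths["table"], paths["samples"], paths["features"])
  tr <- sim$truth
  jsonlite::write_json(list(
    differential = tr$differential,
    planted = planted_truth_report(tr),
    designed_failures = tr$designed_failures,
    noise_sd = tr$noise_sd, lod_log10 = tr$lod_log10,
    group_sizes = as.list(tr$group_sizes), seed = tr$seed
  ), paths["truth"], auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  cfg$group_sizes <- as.list(config$group_sizes)
  yaml::write_yaml(cfg, paths["config"])
  jsonlite::write_json(list(
    kind = "simulate", seed = seed, version = .pkg_version(),
    outputs = as.list(paths[names(paths) != "manifest"])
  ), paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.resolve_levels <- function(table, labels) {
  smp <- table$samples
  lab <- rep(NA_character_, nrow(smp))
  for (l in labels) lab[group_indices(table, l)] <- l
  lab
}

#' Run the full analysis workflow
#'
#' Preprocesses the table (filters, drift correction, log10), screens
#' every feature per pairwise comparison with the assumption-gated test
#' and BH-FDR, runs per-feature ROC (Youden, DeLong) and SVM-LOOCV
#' classification on the FDR-significant panel of each comparison, and
#' fits the multivariate models: one PLS-DA over the top-level groups
#' with QC samples projected onto it, and one OPLS-DA per two-group
#' comparison. Comparisons whose two sample sets overlap (a nested
#' subgroup against its parent) are screened univariately but skipped
#' for ROC, SVM and OPLS-DA, as two-class machinery is undefined on
#' overlapping membership; the skip is flagged in the report. Likewise a
#' comparison with zero significant features skips ROC/SVM with a flag
#' rather than erroring.
#'
#' @param table Raw-scale `feature_table`.
#' @param config A `study_config`.
#' @param comparisons List of length-2 character vectors (group A, group
#'   B).
#' @param out_dir Optional output directory; when given, the filter
#'   report (JSON), per-feature results table (TSV), per-comparison
#'   summary (JSON), model scores (TSV) and a manifest are written.
#' @param seed Seed for cross-validation partitions and any permutation
#'   testing.
#' @param n_permutations Label permutations for the multivariate models
#'   (0 = skip permutation testing).
#' @return A list of class `ms_analysis`: `table` (preprocessed),
#'   `filter_report`, `univariate` (per comparison), `roc`, `svm`,
#'   `results_table` (merged per-feature report), `summary` (per
#'   comparison counts and accuracies), `plsda`, `oplsda`, `manifest`.
#' @export
run_analysis <- function(table, config = default_config(),
                         comparisons = list(c("I", "Ia"), c("I", "II"),
                                            c("Ia", "II"), c("I", "III"),
                                            c("II", "III")),
                         out_dir = NULL, seed = config$seed,
                         n_permutations = 0) {
  t0 <- Sys.time()
  for (cmp in comparisons) {
    for (l in cmp) group_indices(table, l)  # fail early on unknown labels
  }
  pp <- run_preprocess(table, config)
  logt <- pp$table

  groups <- unique(stats::na.omit(logt$samples$group))
  univariate <- list(); roc <- list(); svm <- list(); summary_rows <- list()
  for (cmp in comparisons) {
    a <- cmp[1]; b <- cmp[2]
    key <- paste(a, "vs", b)
    res <- adjust_fdr(compare_groups(logt, a, b, config$alpha))
    univariate[[key]] <- res
    sig <- res$feature_id[res$testable & !is.na(res$p_fdr) &
                            res$p_fdr < config$fdr_alpha]
    overlap <- length(intersect(group_indices(logt, a), group_indices(logt, b))) > 0
    skip <- if (overlap) "overlapping groups"
            else if (!length(sig)) "no significant features"
            else NA_character_
    if (is.na(skip)) {
      roc[[key]] <- roc_features(logt, a, b, sig)
      imp <- impute_median_by_group(subset_table(logt, features = sig),
                                    groups = c(a, b))
      lab <- .resolve_levels(imp, c(a, b))
      svm[[key]] <- svm_loocv_accuracy(imp$intensities, lab,
                                       cost = config$svm_cost,
                                       gamma = config$svm_gamma, seed = seed)
    } else {
      roc[[key]] <- NULL
      svm[[key]] <- NULL
    }
    summary_rows[[key]] <- list(
      comparison = key,
      n_testable = sum(res$testable),
      n_significant = length(sig),
      svm_accuracy = if (is.na(skip)) svm[[key]]$accuracy else NA,
      skipped = skip
    )
  }

  # multivariate: PLS-DA across top-level groups, QC samples projected
  study_idx <- which(!logt$samples$is_qc)
  qc_idx <- which(logt$samples$is_qc)
  imp_all <- impute_median_by_group(logt, groups = groups)
  Xg <- imp_all$intensities
  yg <- imp_all$samples$group
  plsda <- list(model = NULL, quality = NULL, qc_scores = NULL,
                permutation = NULL)
  if (length(groups) >= 2 && ncol(Xg) >= config$n_components) {
    plsda$model <- fit_plsda(Xg, yg, config$n_components)
    plsda$quality <- cross_validate(Xg, yg, "plsda", config$n_components,
                                    config$folds, seed)
    if (length(qc_idx)) {
      Xqc <- logt$intensities[qc_idx, colnames(Xg), drop = FALSE]
      for (j in seq_len(ncol(Xqc))) {  # QC gaps -> QC median
        miss <- is.na(Xqc[, j])
        if (any(miss)) Xqc[miss, j] <- stats::median(Xqc[!miss, j], na.rm = TRUE)
      }
      plsda$qc_scores <- project_samples(plsda$model, Xqc)
    }
    if (n_permutations > 0)
      plsda$permutation <- permutation_validate(
        Xg, yg, "plsda", config$n_components, n_permutations,
        config$folds, seed)
  }
  oplsda <- list()
  for (cmp in comparisons) {
    a <- cmp[1]; b <- cmp[2]
    key <- paste(a, "vs", b)
    if (length(intersect(group_indices(logt, a), group_indices(logt, b)))) next
    impc <- impute_median_by_group(logt, groups = c(a, b))
    lab <- .resolve_levels(impc, c(a, b))
    q <- cross_validate(impc$intensities, lab, "oplsda",
                        folds = config$folds, seed = seed,
                        n_orthogonal = config$n_orthogonal)
    oplsda[[key]] <- list(
      model = fit_oplsda(impc$intensities, lab, config$n_orthogonal),
      quality = q,
      permutation = if (n_permutations > 0)
        permutation_validate(impc$intensities, lab, "oplsda",
                             n_permutations = n_permutations,
                             folds = config$folds, seed = seed,
                             n_orthogonal = config$n_orthogonal)
      else NULL)
  }

  results_table <- do.call(rbind, lapply(names(univariate), function(key) {
    u <- univariate[[key]]
    out <- u[, c("feature_id", "comparison", "percent_change", "p_raw",
                 "p_fdr", "test_used", "mean_a", "se_a", "n_a",
                 "mean_b", "se_b", "n_b", "testable")]
    r <- roc[[key]]
    if (!is.null(r)) {
      m <- match(out$feature_id, r$feature_id)
      out$auc <- r$auc[m]
      out$auc_ci95_low <- r$ci95_low[m]
      out$auc_ci95_high <- r$ci95_high[m]
      out$auc_p <- r$p_greater[m]
    } else {
      out$auc <- NA_real_; out$auc_ci95_low <- NA_real_
      out$auc_ci95_high <- NA_real_; out$auc_p <- NA_real_
    }
    out$significant <- out$testable & !is.na(out$p_fdr) & out$p_fdr < config$fdr_alpha
    out
  }))
  rownames(results_table) <- NULL

  manifest <- list(
    kind = "analyze", seed = seed, version = .pkg_version(),
    config = unclass(config),
    comparisons = lapply(comparisons, as.list),
    n_samples = length(study_idx), n_qc = length(qc_idx),
    features_in = nrow(table$features),
    features_surviving = ncol(logt$intensities),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- structure(list(
    table = logt, filter_report = pp$report, uncorrected = pp$uncorrected,
    univariate = univariate, roc = roc, svm = svm,
    results_table = results_table,
    summary = summary_rows, plsda = plsda, oplsda = oplsda,
    manifest = manifest
  ), class = "ms_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' Write analysis outputs to disk
#'
#' @param analysis An `ms_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    filter_report = file.path(out_dir, "filter_report.json"),
    results = file.path(out_dir, "feature_results.tsv"),
    summary = file.path(out_dir, "comparison_summary.json"),
    scores = file.path(out_dir, "plsda_scores.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_filter_report(analysis$filter_report, paths["filter_report"])
  utils::write.table(analysis$results_table, paths["results"], sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  svm_json <- lapply(analysis$summary, function(s) {
    s$svm_accuracy <- if (is.na(s$svm_accuracy)) NULL else s$svm_accuracy
    s$skipped <- if (is.na(s$skipped)) NULL else s$skipped
    s
  })
  jsonlite::write_json(unname(svm_json), paths["summary"],
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(analysis$plsda$model)) {
    sc <- analysis$plsda$model$scores
    df <- data.frame(sample_id = rownames(analysis$table$intensities)[
      !analysis$table$samples$is_qc], sc, check.names = FALSE)
    names(df)[-1] <- paste0("comp", seq_len(ncol(sc)))
    if (!is.null(analysis$plsda$qc_scores)) {
      qcdf <- data.frame(
        sample_id = analysis$table$samples$sample_id[analysis$table$samples$is_qc],
        analysis$plsda$qc_scores, check.names = FALSE)
      names(qcdf)[-1] <- paste0("comp", seq_len(ncol(sc)))
      df <- rbind(df, qcdf)
    }
    utils::write.table(df, paths["scores"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  jsonlite::write_json(analysis$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Human-readable analysis summary
#'
#' One section per comparison: feature counts through the filter
#' cascade, significant features, SVM accuracy (or the skip reason), and
#' the multivariate quality statistics.
#'
#' @param analysis An `ms_analysis`.
#' @param path Optional file to write the summary to.
#' @return Character vector of summary lines, invisibly when `path` is
#'   given.
#' @export
summarize_analysis <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "ms_analysis"))
  fr <- analysis$filter_report
  lines <- c(
    "== Study summary ==",
    sprintf("samples: %d study + %d QC; features: %d in, %d surviving",
            analysis$manifest$n_samples, analysis$manifest$n_qc,
            analysis$manifest$features_in,
            analysis$manifest$features_surviving),
    sprintf("  %s: %d -> %d", fr$stage, fr$features_in, fr$features_out))
  for (key in names(analysis$summary)) {
    s <- analysis$summary[[key]]
    lines <- c(lines, "", paste0("== ", key, " =="),
               sprintf("testable features: %d; significant (FDR < %s): %d",
                       s$n_testable,
                       format(analysis$manifest$config$fdr_alpha),
                       s$n_significant))
    lines <- c(lines, if (!is.na(s$skipped))
      sprintf("ROC/SVM skipped: %s", s$skipped)
      else sprintf("SVM-LOOCV accuracy: %.1f%%", s$svm_accuracy))
    q <- analysis$oplsda[[key]]$quality
    if (!is.null(q))
      lines <- c(lines, sprintf("OPLS-DA: R2Y %.3f, Q2 %.3f, CC %.1f%%",
                                q$R2Y_cum[length(q$R2Y_cum)], q$Q2, q$CC))
  }
  lines <- c(lines, "", "== PLS-DA (all groups) ==",
             if (!is.null(analysis$plsda$quality)) {
               q <- analysis$plsda$quality
               sprintf("R2Y(cum) %.3f, Q2 %.3f, CC %.1f%%",
                       q$R2Y_cum[length(q$R2Y_cum)], q$Q2, q$CC)
             } else "not available (model not fitted)")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
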