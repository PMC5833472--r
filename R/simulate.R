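#' Generator settings for a synthetic LC-MS study
#'
#' Defaults emulate a multi-batch plasma case-control design: three
#' clinical groups of 57/49/25 subjects (131 study samples) with a
#' nested subgroup of 37 inside the first, four analytical batches
#' filled with close to a quarter of each group, pooled-QC injections at
#' the start of each batch, after every 8 study samples, and at batch
#' end, log-normal intensities, linear within-batch signal decay of 20%,
#' per-feature batch offsets, multiplicative group effects on a feature
#' subset, and below-LOD censoring to missing.
#'
#' @param group_sizes Named integer vector of study-group sizes.
#' @param subgroup Either `NULL` or `list(label=, parent=, size=)`
#'   defining a nested subgroup (a subset of `parent`, labelled in the
#'   sample metadata's `subgroup` column).
#' @param n_batches Number of analytical batches.
#' @param n_features Number of aligned features.
#' @param n_differential Number of features carrying a group effect.
#' @param log2_effect Absolute log2 effect size of a differential
#'   feature (its target group is shifted by +/- this amount).
#' @param baseline_log10 Range (length 2) of per-feature baseline log10
#'   intensities.
#' @param noise_sd Per-injection measurement noise sd on the log10 scale.
#' @param batch_offset_sd Sd (log10) of the per-feature, per-batch
#'   instrumental offset.
#' @param drift_start,drift_end Multiplicative drift factor at the first
#'   and last injection of a batch (linear in between unless curved).
#' @param drift_curvature Exponent offset: drift follows
#'   `t^(1 + curvature)` in normalized injection position `t`.
#' @param lod_log10 Detection limit; raw intensities below `10^lod_log10`
#'   become missing.
#' @param qc_every QC injection inserted after this many study samples.
#' @param qc_source_batch Batch whose study samples define the pooled QC
#'   profile.
#' @param n_fail_qc_presence,n_fail_qc_cv,n_fail_group_presence Number
#'   of features engineered to violate exactly one of the three cleaning
#'   filters (disjoint from each other and from differential features).
#' @param polarity Ionization mode recorded in the metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(I = 57, II = 49, III = 25),
                       subgroup = list(label = "Ia", parent = "I", size = 37),
                       n_batches = 4,
                       n_features = 500,
                       n_differential = 30,
                       log2_effect = 0.6,
                       baseline_log10 = c(4, 7),
                       noise_sd = 0.08,
                       batch_offset_sd = 0.05,
                       drift_start = 1.0,
                       drift_end = 0.8,
                       drift_curvature = 0,
                       lod_log10 = 3.8,
                       qc_every = 8,
                       qc_source_batch = 1,
                       n_fail_qc_presence = 0,
                       n_fail_qc_cv = 0,
                       n_fail_group_presence = 0,
                       polarity = "positive") {
  cfg <- as.list(environment())
  if (is.null(names(cfg$group_sizes)) || any(!nzchar(names(cfg$group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(cfg$group_sizes < 2)) {
    bad <- names(cfg$group_sizes)[which(cfg$group_sizes < 2)[1]]
    stop("group_sizes: group '", bad, "' has size < 2")
  }
  if (cfg$n_batches < 1) stop("n_batches must be >= 1")
  if (!is.null(cfg$subgroup)) {
    if (!cfg$subgroup$parent %in% names(cfg$group_sizes))
      stop("subgroup parent '", cfg$subgroup$parent, "' not a group")
    if (cfg$subgroup$size > cfg$group_sizes[[cfg$subgroup$parent]])
      stop("subgroup larger than its parent group")
  }
  n_designed <- cfg$n_fail_qc_presence + cfg$n_fail_qc_cv +
    cfg$n_fail_group_presence
  if (cfg$n_differential + n_designed > cfg$n_features)
    stop("more designed features than n_features")
  structure(cfg, class = "sim_config")
}

#' QC injection schedule for one batch
#'
#' QC at run position 1, after every `qc_every` study samples, and after
#' the final sample; a trailing every-`qc_every` QC that coincides with
#' the end-of-run QC is emitted once.
#'
#' @param n_samples_in_batch Number of study samples in the batch.
#' @param qc_every Study samples between consecutive QC injections.
#' @return Data frame with `injection_index` (1..total) and `is_qc`.
#' @export
qc_schedule <- function(n_samples_in_batch, qc_every = 8) {
  if (n_samples_in_batch < 1) stop("need at least one sample")
  is_qc <- TRUE  # run opens with a QC
  for (s in seq_len(n_samples_in_batch)) {
    is_qc <- c(is_qc, FALSE)
    if (s %% qc_every == 0) is_qc <- c(is_qc, TRUE)
  }
  if (!is_qc[length(is_qc)]) is_qc <- c(is_qc, TRUE)
  data.frame(injection_index = seq_along(is_qc), is_qc = is_qc)
}

#' Simulate a batched LC-MS study with known ground truth
#'
#' Per-sample raw intensity of feature f:
#' `10^(baseline_f + group_effect + batch_offset + noise) * drift(i)`,
#' where the group effect is `log10(2) * log2_offset` of the sample's
#' group, noise is N(0, noise_sd) on log10, and drift depends on the
#' injection position within the batch. QC injections measure the pooled
#' mean profile of the designated source batch's study samples and are
#' subject to the same batch offset, drift, and noise. Raw values below
#' the detection limit become missing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   table bit-identically.
#' @return List with `table` (a raw-scale `feature_table`) and `truth`
#'   (class `simulation_truth`): differential-feature table, per-feature
#'   baselines, log2 offset matrix, batch offsets, per-injection drift
#'   factors, QC pooled profile, designed filter failures, and the
#'   generator settings.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    gs <- config$group_sizes
    groups <- names(gs)
    n_study <- sum(gs)
    group_of <- rep(groups, gs)
    sample_id <- sprintf("S%03d", seq_len(n_study))

    subgroup_of <- rep(NA_character_, n_study)
    if (!is.null(config$subgroup)) {
      pool <- which(group_of == config$subgroup$parent)
      chosen <- sample(pool, config$subgroup$size)
      subgroup_of[chosen] <- config$subgroup$label
    }

    # stratified near-quarters: shuffle within group, deal round-robin
    batch_of <- integer(n_study)
    for (g in groups) {
      idx <- sample(which(group_of == g))
      batch_of[idx] <- rep_len(seq_len(config$n_batches), length(idx))
    }

    nf <- config$n_features
    feature_id <- sprintf("F%04d", seq_len(nf))
    baseline <- stats::runif(nf, config$baseline_log10[1], config$baseline_log10[2])

    # disjoint designed feature sets
    designed_total <- config$n_differential + config$n_fail_qc_presence +
      config$n_fail_qc_cv + config$n_fail_group_presence
    pool <- sample(nf, designed_total)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    diff_idx <- take(config$n_differential)
    fail_pres_idx <- take(config$n_fail_qc_presence)
    fail_cv_idx <- take(config$n_fail_qc_cv)
    fail_grp_idx <- take(config$n_fail_group_presence)

    log2_off <- matrix(0, nf, length(groups), dimnames = list(feature_id, groups))
    if (length(diff_idx)) {
      tgt <- sample(groups, length(diff_idx), replace = TRUE)
      sgn <- sample(c(-1, 1), length(diff_idx), replace = TRUE)
      for (k in seq_along(diff_idx))
        log2_off[diff_idx[k], tgt[k]] <- sgn[k] * config$log2_effect
    }
    batch_off <- matrix(stats::rnorm(nf * config$n_batches, 0, config$batch_offset_sd),
                        nf, config$n_batches)

    # pooled QC profile: mean raw level of the source batch's samples
    src <- which(batch_of == config$qc_source_batch)
    if (!length(src)) src <- seq_len(n_study)
    level_log10 <- function(i) baseline + log10(2) * log2_off[, group_of[i]]
    qc_raw <- rowMeans(matrix(vapply(src, function(i) 10^level_log10(i),
                                     numeric(nf)), nrow = nf))
    qc_log10 <- log10(qc_raw)

    rows <- list(); smeta <- list(); drift_rec <- list()
    for (b in seq_len(config$n_batches)) {
      members <- sample(which(batch_of == b))  # injection order within batch
      layout <- qc_schedule(length(members), config$qc_every)
      L <- nrow(layout)
      tpos <- if (L > 1) (layout$injection_index - 1) / (L - 1) else 0
      drift <- config$drift_start +
        (config$drift_end - config$drift_start) * tpos^(1 + config$drift_curvature)
      s_ptr <- 0; q_ptr <- 0
      for (r in seq_len(L)) {
        if (layout$is_qc[r]) {
          q_ptr <- q_ptr + 1
          id <- sprintf("QC_b%d_%02d", b, q_ptr)
          mu <- qc_log10
          grp <- NA_character_; sg <- NA_character_; qc <- TRUE
        } else {
          s_ptr <- s_ptr + 1
          i <- members[s_ptr]
          id <- sample_id[i]
          mu <- level_log10(i)
          grp <- group_of[i]; sg <- subgroup_of[i]; qc <- FALSE
        }
        val <- 10^(mu + batch_off[, b] +
                     stats::rnorm(nf, 0, config$noise_sd)) * drift[r]
        rows[[id]] <- val
        smeta[[id]] <- data.frame(
          sample_id = id, group = grp, batch = b,
          injection_index = layout$injection_index[r], is_qc = qc,
          polarity = config$polarity, subgroup = sg,
          stringsAsFactors = FALSE)
        drift_rec[[id]] <- drift[r]
      }
    }
    m <- do.call(rbind, rows)
    samples <- do.call(rbind, smeta)
    rownames(samples) <- NULL
    drift_factor <- unlist(drift_rec)

    # engineered filter violations
    qc_rows <- which(samples$is_qc)
    if (length(fail_pres_idx)) {
      n_miss <- ceiling(0.6 * length(qc_rows))
      m[qc_rows[seq_len(n_miss)], fail_pres_idx] <- NA_real_
    }
    if (length(fail_cv_idx)) {
      wob <- rep_len(c(2, 0.5), length(qc_rows))
      m[qc_rows, fail_cv_idx] <- m[qc_rows, fail_cv_idx, drop = FALSE] * wob
    }
    if (length(fail_grp_idx)) {
      for (g in groups) {
        gi <- which(!samples$is_qc & samples$group == g)
        m[gi[seq_along(gi) %% 3 == 0], fail_grp_idx] <- NA_real_
      }
    }

    m[!is.na(m) & m < 10^config$lod_log10] <- NA_real_

    features <- data.frame(
      feature_id = feature_id,
      neutral_mass = round(stats::runif(nf, 80, 1000), 4),
      rt_min = round(stats::runif(nf, 0.5, 35), 3),
      polarity = config$polarity,
      annotation = NA_character_,
      stringsAsFactors = FALSE)

    table <- feature_table(m, samples, features, scale = "raw")
    differential <- if (length(diff_idx)) data.frame(
      feature_id = feature_id[diff_idx],
      target_group = tgt, sign = sgn,
      log2_effect = sgn * config$log2_effect,
      stringsAsFactors = FALSE)
    else data.frame(feature_id = character(0), target_group = character(0),
                    sign = numeric(0), log2_effect = numeric(0))
    truth <- structure(list(
      differential = differential,
      baseline_log10 = stats::setNames(baseline, feature_id),
      log2_offsets = log2_off,
      batch_offsets = batch_off,
      drift_factor = drift_factor,
      qc_profile_log10 = stats::setNames(qc_log10, feature_id),
      designed_failures = list(
        qc_presence = feature_id[fail_pres_idx],
        qc_cv = feature_id[fail_cv_idx],
        group_presence = feature_id[fail_grp_idx]),
      noise_sd = config$noise_sd,
      lod_log10 = config$lod_log10,
      group_sizes = gs,
      config = config,
      seed = seed
    ), class = "simulation_truth")
    list(table = table, truth = truth)
  })
}

#' Tabular ground-truth report of planted effects
#'
#' Expands the truth's per-group log2 offsets into per-comparison
#' planted effects for every ordered pair of labels (nested subgroups
#' inherit their parent group's offsets), suitable for
#' parameter-recovery tests and JSON round-tripping.
#'
#' @param truth A `simulation_truth`.
#' @return Data frame with `feature_id`, `comparison`, `log2_effect`
#'   (offset of A minus offset of B) for every differential feature and
#'   ordered label pair.
#' @export
planted_truth_report <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  groups <- colnames(truth$log2_offsets)
  labels <- groups
  parent <- stats::setNames(groups, groups)
  sg <- truth$config$subgroup
  if (!is.null(sg)) {
    labels <- c(labels, sg$label)
    parent[sg$label] <- sg$parent
  }
  if (!nrow(truth$differential))
    return(data.frame(feature_id = character(0), comparison = character(0),
                      log2_effect = numeric(0)))
  pairs <- utils::combn(labels, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    fid <- truth$differential$feature_id
    eff <- truth$log2_offsets[fid, parent[a]] - truth$log2_offsets[fid, parent[b]]
    data.frame(feature_id = fid, comparison = paste(a, "vs", b),
               log2_effect = unname(eff), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
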