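# 10 QC injections + 10 study samples (two groups of 5); feature columns
# engineered per filter case.
filter_fixture <- function() {
  nqc <- 10; ns <- 10
  base <- matrix(1000, nqc + ns, 6)
  # F1: absent from every QC
  base[1:nqc, 1] <- NA
  # F2: present in exactly 5 of 10 QCs (boundary: survives at 0.5)
  base[1:5, 2] <- NA
  # F3: present in 4 of 10 QCs (below boundary)
  base[1:6, 3] <- NA
  # F4: noisy in QCs -> CV way above 0.30
  base[1:nqc, 4] <- rep(c(10, 100), 5)
  # F5: present in 80% of both groups (4 of 5 each)
  base[nqc + c(1, 6), 5] <- NA
  # F6: present in 100% of group A, absent in B
  base[nqc + 6:10, 6] <- NA
  toy_table(base, groups = rep(c("A", "B"), each = 5))
}

test_that("QC-presence filter keeps the 50% boundary and drops below it", {
  tab <- filter_fixture()
  res <- filter_qc_presence(tab, 0.5)
  kept <- res$table$features$feature_id
  expect_false("F1" %in% kept)   # zero QC presence
  expect_true("F2" %in% kept)    # exactly 50% survives
  expect_false("F3" %in% kept)   # 40% < 50%
  expect_true(all(c("F4", "F5", "F6") %in% kept))
  expect_equal(res$report$features_in, 6)
  expect_equal(res$report$features_out, 4)
  expect_equal(nrow(res$table$samples), nrow(tab$samples))  # samples untouched
})

test_that("QC CV uses sd/mean with the n-1 denominator", {
  m <- matrix(1000, 5, 3)
  m[1:3, 1] <- c(100, 110, 90)   # CV = 10/100
  m[1:3, 2] <- c(120, 120, 120)  # CV = 0
  m[1:3, 3] <- c(10, 100, NA)    # two-point CV = sd(10,100)/55 ~ 1.157
  tab <- toy_table(m, groups = c("A", "B"))
  res <- filter_qc_cv(tab, 0.30)
  cv <- attr(res$report, "qc_cv")
  expect_equal(unname(cv[1]), 0.10)
  expect_equal(unname(cv[2]), 0)
  expect_equal(unname(cv[3]), sd(c(10, 100)) / 55)
  expect_setequal(res$table$features$feature_id, c("F1", "F2"))
})

test_that("a feature with fewer than two present QC values is removed with its own reason", {
  m <- matrix(1000, 4, 2)
  m[1:2, 2] <- c(500, NA)  # single present QC value
  tab <- toy_table(m, groups = c("A", "B"))
  res <- filter_qc_cv(tab, 0.30)
  reasons <- attr(res$report, "reasons")
  expect_equal(reasons$reason[reasons$feature_id == "F2"],
               "insufficient QC values")
})

test_that("group presence uses 'any group' semantics with a >= boundary", {
  nqc <- 2
  m <- matrix(1000, nqc + 20, 3)
  # F1: 100% in A, 0% in B
  m[nqc + 11:20, 1] <- NA
  # F2: 80% in both groups
  m[nqc + c(1, 2, 11, 12), 2] <- NA
  # F3: 9 of 10 in A (boundary 0.9), 0% in B
  m[nqc + c(1, 11:20), 3] <- NA
  tab <- toy_table(m, groups = rep(c("A", "B"), each = 10))
  res <- filter_group_presence(tab, 0.9, c("A", "B"))
  expect_setequal(res$table$features$feature_id, c("F1", "F3"))
  expect_error(filter_group_presence(tab, 0.9, c("A", "Nope")), "Nope")
})

test_that("flat QC signal makes bracketing correction the identity", {
  m <- matrix(c(rep(500, 4), 10, 20, 30, 40), ncol = 1)
  tab <- toy_table(m, groups = c("A", "A", "B", "B"),
                   injection = c(1, 4, 7, 10, 2, 3, 5, 6))
  # order rows: toy_table puts 4 QCs first; all QCs = 500 (= ref)
  cor <- correct_qc_bracketing(tab)
  expect_equal(cor$intensities, tab$intensities, tolerance = 1e-12)
  expect_identical(cor$scale, "corrected")
})

test_that("bracketing interpolation matches the hand-computed expectation", {
  # QCs at injections 1 and 10 with 100 and 200; sample at injection 5
  m <- matrix(c(100, 200, 72.222), ncol = 1)
  samples <- data.frame(
    sample_id = c("QC1", "QC2", "S1"), group = c(NA, NA, "A"),
    batch = 1L, injection_index = c(1L, 10L, 5L),
    is_qc = c(TRUE, TRUE, FALSE), polarity = "positive")
  features <- data.frame(feature_id = "F1", neutral_mass = 100, rt_min = 1,
                         polarity = "positive")
  tab <- feature_table(m, samples, features)
  cor <- correct_qc_bracketing(tab)
  expected_qc_at_5 <- 100 + 100 * (5 - 1) / (10 - 1)  # 144.44...
  ref <- 150  # median of the two QC intensities
  expect_equal(cor$intensities["S1", 1], 72.222 * ref / expected_qc_at_5,
               tolerance = 1e-12)
  # each QC's own corrected value collapses to the study-wide reference
  expect_equal(unname(cor$intensities[c("QC1", "QC2"), 1]), c(150, 150))
})

test_that("injected drift is inverted exactly at QC-bracketed indices when noise is zero", {
  # symmetric drift (1.1 -> 0.9) so the QC median equals the drift-free level
  cfg <- sim_config(group_sizes = c(A = 8, B = 8), subgroup = NULL,
                    n_batches = 1, n_features = 20, n_differential = 0,
                    noise_sd = 0, batch_offset_sd = 0, lod_log10 = -Inf,
                    drift_start = 1.1, drift_end = 0.9)
  sim <- simulate_study(cfg, seed = 3)
  tab <- sim$table
  cor <- correct_qc_bracketing(tab)
  truth_raw <- t(10^vapply(seq_len(nrow(tab$samples)), function(i) {
    g <- tab$samples$group[i]
    if (is.na(g)) sim$truth$qc_profile_log10
    else sim$truth$baseline_log10 + log10(2) * sim$truth$log2_offsets[, g]
  }, numeric(20)))
  qc_idx <- tab$samples$injection_index[tab$samples$is_qc]
  bracketed <- tab$samples$injection_index >= min(qc_idx) &
    tab$samples$injection_index <= max(qc_idx)
  rel_err <- abs(cor$intensities[bracketed, ] / truth_raw[bracketed, ] - 1)
  expect_lt(max(rel_err), 1e-6)
})

test_that("correction reduces QC CV for drifting features", {
  cfg <- sim_config(group_sizes = c(A = 10, B = 10), subgroup = NULL,
                    n_batches = 2, n_features = 100, n_differential = 0,
                    noise_sd = 0.05, drift_start = 1, drift_end = 0.7)
  sim <- simulate_study(cfg, seed = 11)
  qc <- sim$table$samples$is_qc
  cv_of <- function(m) apply(m[qc, , drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]; sd(v) / mean(v)
  })
  pre <- cv_of(sim$table$intensities)
  post <- cv_of(correct_qc_bracketing(sim$table)$intensities)
  expect_gte(mean(post <= pre, na.rm = TRUE), 0.95)
})

test_that("log10 transform maps values, keeps missing, and refuses to repeat", {
  m <- matrix(c(100, 1000, NA, 10), 2, 2)
  tab <- toy_table(m, groups = "A")
  lt <- log10_transform(tab)
  expect_equal(lt$intensities[1, 1], 2)
  expect_true(is.na(lt$intensities[1, 2]))
  expect_identical(lt$scale, "log10")
  expect_error(log10_transform(lt), "already")
})

test_that("the preprocessing cascade chains its report and honors generator ground truth", {
  cfg <- sim_config(group_sizes = c(A = 20, B = 20), subgroup = NULL,
                    n_batches = 2, n_features = 120, n_differential = 10,
                    noise_sd = 0.05, baseline_log10 = c(4.5, 7),
                    batch_offset_sd = 0, drift_end = 0.9,
                    n_fail_qc_presence = 8, n_fail_qc_cv = 7,
                    n_fail_group_presence = 9)
  sim <- simulate_study(cfg, seed = 5)
  pp <- run_preprocess(sim$table, default_config(), groups = c("A", "B"))
  rep <- pp$report
  expect_equal(rep$features_out[-nrow(rep)], rep$features_in[-1])
  expect_equal(rep$features_out[nrow(rep)], 120 - 8 - 7 - 9)
  reasons <- attr(rep, "reasons")
  truth <- sim$truth$designed_failures
  expect_setequal(reasons$feature_id[reasons$stage == "qc_presence"],
                  truth$qc_presence)
  expect_setequal(reasons$feature_id[reasons$stage == "qc_cv"], truth$qc_cv)
  expect_setequal(reasons$feature_id[reasons$stage == "group_presence"],
                  truth$group_presence)
  expect_identical(pp$table$scale, "log10")
})

test_that("a table whose features all fail the first filter empties cleanly", {
  m <- matrix(1000, 4, 2)
  m[1:2, ] <- NA  # both features absent from both QCs
  tab <- toy_table(m, groups = c("A", "B"))
  pp <- run_preprocess(tab, default_config(), groups = c("A", "B"))
  expect_equal(ncol(pp$table$intensities), 0)
  expect_equal(pp$report$features_out[1], 0)
  expect_equal(nrow(attr(pp$report, "reasons")), 2)
})

test_that("pipeline output is invariant to sample row order within a batch", {
  cfg <- sim_config(group_sizes = c(A = 10, B = 10), subgroup = NULL,
                    n_batches = 1, n_features = 40, n_differential = 5)
  sim <- simulate_study(cfg, seed = 9)
  tab <- sim$table
  perm <- sample(nrow(tab$samples))
  tab2 <- feature_table(tab$intensities[perm, , drop = FALSE],
                        tab$samples[perm, , drop = FALSE],
                        tab$features, scale = "raw")
  p1 <- run_preprocess(tab, default_config(), groups = c("A", "B"))
  p2 <- run_preprocess(tab2, default_config(), groups = c("A", "B"))
  ids <- rownames(p1$table$intensities)
  expect_equal(p2$table$intensities[ids, , drop = FALSE],
               p1$table$intensities[ids, , drop = FALSE])
})

test_that("filters never touch samples or surviving values", {
  tab <- filter_fixture()
  res <- filter_qc_presence(tab, 0.5)
  kept <- res$table$features$feature_id
  expect_identical(res$table$intensities[, kept],
                   tab$intensities[, kept])
  expect_identical(res$table$samples, tab$samples)
})
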