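# Small in-code fixtures and independent oracles shared across tests.

# A tiny hand-built table: one batch, QCs at injection 1 and 10, eight
# study samples (two groups) in between. Values are chosen per test.
toy_table <- function(m, groups = rep(c("A", "B"), each = 4),
                      scale = "raw", injection = NULL, batch = NULL) {
  n <- nrow(m)
  n_qc <- n - length(groups)
  samples <- data.frame(
    sample_id = c(sprintf("QC%d", seq_len(n_qc)), sprintf("S%d", seq_along(groups))),
    group = c(rep(NA_character_, n_qc), groups),
    batch = if (is.null(batch)) 1L else batch,
    injection_index = if (is.null(injection)) seq_len(n) else injection,
    is_qc = c(rep(TRUE, n_qc), rep(FALSE, length(groups))),
    polarity = "positive",
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    feature_id = sprintf("F%d", seq_len(ncol(m))),
    neutral_mass = 100 + seq_len(ncol(m)),
    rt_min = seq_len(ncol(m)),
    polarity = "positive",
    stringsAsFactors = FALSE
  )
  feature_table(m, samples, features, scale = scale)
}

# Brute-force Benjamini-Hochberg step-up: adjusted p_(i) =
# min_{j >= i} min(1, m * p_(j) / j), evaluated from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Trapezoidal area under the empirical ROC curve built by a full
# threshold sweep over the pooled score values.
auc_trapezoid <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Exhaustive Youden maximum over every midpoint threshold (and the two
# infinite end points), kept independent of the package implementation.
youden_brute <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  max(vapply(cand, function(th)
    mean(pos > th) + mean(neg <= th) - 1, numeric(1)))
}

# DeLong variance by explicit double-loop enumeration of the structural
# components (no vectorized shortcuts).
delong_var_enum <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  psi <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    psi[i, j] <- if (pos[i] > neg[j]) 1 else if (pos[i] == neg[j]) 0.5 else 0
  }
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  stats::var(v10) / m + stats::var(v01) / n
}

# Deterministic two-group matrix with a planted standardized shift on
# the first `k` features.
shifted_groups <- function(n_per = 20, p = 10, k = 5, delta = 3, seed = 1,
                           sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p, sd = sd), 2 * n_per, p)
  X[seq_len(n_per), seq_len(k)] <- X[seq_len(n_per), seq_len(k)] + delta * sd
  list(X = X, y = rep(c("A", "B"), each = n_per))
}
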