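test_that("the first PLS weight vector is proportional to X'y on scaled data", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rep(c("A", "B"), each = 15)
  fit <- fit_plsda(X, y, n_components = 1)
  Xs <- scale(X)
  ycs <- drop(scale(as.numeric(factor(y)) - 1))
  w_oracle <- drop(crossprod(Xs, ycs))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(sum(fit$W[, 1] * w_oracle)), 1, tolerance = 1e-8)
})

test_that("a single perfectly separating variable yields disjoint class score ranges", {
  set.seed(3)
  X <- cbind(sep = c(rnorm(10, 0), rnorm(10, 10)), matrix(rnorm(40), 20, 2))
  y <- rep(c("A", "B"), each = 10)
  fit <- fit_plsda(X, y, 1)
  sA <- fit$scores[y == "A", 1]; sB <- fit$scores[y == "B", 1]
  expect_true(max(sA) < min(sB) || max(sB) < min(sA))
})

test_that("an exactly linear class indicator reaches cumulative R2Y of 1", {
  set.seed(4)
  y <- rep(c("A", "B"), each = 10)
  X <- cbind(as.numeric(factor(y)), matrix(rnorm(60), 20, 3))
  fit <- fit_plsda(X, y, n_components = 4)
  expect_equal(fit$R2Y_cum[length(fit$R2Y_cum)], 1, tolerance = 1e-8)
  expect_true(all(diff(fit$R2Y_cum) >= -1e-12))  # non-decreasing
  expect_lte(max(fit$R2Y_cum), 1 + 1e-12)
})

test_that("successive predictive score vectors are mutually orthogonal", {
  set.seed(5)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c("A", "B", "C", "D"), each = 10)
  fit <- fit_plsda(X, y, 4)
  Tn <- sweep(fit$scores, 2, sqrt(colSums(fit$scores^2)), "/")
  G <- crossprod(Tn)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("fit errors name zero-variance features and tiny classes", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("ok", "flat")))
  X[, "flat"] <- 7
  y <- rep(c("A", "B"), each = 5)
  expect_error(fit_plsda(X, y, 1), "flat")
  X2 <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X2, c("A", rep("B", 9)), 1), "fewer than 2")
  expect_error(fit_plsda(cbind(X2, NA), y, 1), "missing")
})

test_that("OPLS-DA with zero orthogonal components equals one-component PLS-DA", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rep(c("A", "B"), each = 15)
  p1 <- fit_plsda(X, y, 1)
  o0 <- fit_oplsda(X, y, n_orthogonal = 0)
  expect_equal(drop(o0$scores), drop(p1$scores), tolerance = 1e-8)
})

test_that("OPLS-DA orthogonal scores are orthogonal to predictive scores", {
  set.seed(7)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  # planted y-orthogonal structured variation on top of a weak y signal
  conf <- rnorm(n)
  X <- outer(ifelse(y == "A", -0.5, 0.5), c(rep(1, 3), rep(0, 7))) +
    outer(conf, c(rep(0, 3), rep(2, 7))) + matrix(rnorm(n * 10, sd = 0.3), n, 10)
  fit <- fit_oplsda(X, y, n_orthogonal = 2)
  for (k in seq_len(fit$n_orthogonal)) {
    cosang <- abs(sum(fit$scores[, 1] * fit$scores_ortho[, k])) /
      sqrt(sum(fit$scores[, 1]^2) * sum(fit$scores_ortho[, k]^2))
    expect_lt(cosang, 1e-8)
  }
  # class separation on predictive scores at least as good as PLS comp 1
  smd <- function(s) abs(mean(s[y == "A"]) - mean(s[y == "B"])) /
    sqrt((var(s[y == "A"]) + var(s[y == "B"])) / 2)
  p1 <- fit_plsda(X, y, 1)
  expect_gte(smd(fit$scores[, 1]), smd(p1$scores[, 1]) - 1e-8)
})

test_that("projection reproduces training scores and centers map to zero", {
  set.seed(8)
  X <- matrix(rnorm(24 * 6), 24, 6)
  y <- rep(c("A", "B"), each = 12)
  fit <- fit_plsda(X, y, 2)
  expect_equal(project_samples(fit, X), fit$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(project_samples(fit, matrix(colMeans(X), 1))), c(0, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(project_samples(fit, X[, 1:3]), "mismatch")
})

test_that("a pooled QC profile projects near the centroid of its source groups", {
  set.seed(9)
  n <- 20
  centers <- list(A = c(5, 0, 0), B = c(0, 5, 0), C = c(0, 0, 8))
  X <- do.call(rbind, lapply(centers, function(mu)
    sweep(matrix(rnorm(n * 3, sd = 0.5), n, 3), 2, mu, "+")))
  y <- rep(names(centers), each = n)
  fit <- fit_plsda(X, y, 2)
  qc <- matrix((centers$A + centers$B) / 2, 1)  # pooled from A and B only
  sq <- drop(project_samples(fit, qc))
  centroid <- function(g) colMeans(fit$scores[y == g, ])
  d_ab <- sqrt(sum((sq - (centroid("A") + centroid("B")) / 2)^2))
  d_c <- sqrt(sum((sq - centroid("C"))^2))
  expect_lt(d_ab, d_c)
})

test_that("cross-validation predicts each sample exactly once and is reproducible", {
  set.seed(10)
  X <- matrix(rnorm(42 * 8), 42, 8)
  y <- rep(c("A", "B", "C"), each = 14)
  q <- cross_validate(X, y, "plsda", 2, folds = 7, seed = 33)
  expect_equal(sum(q$classification), 42)
  expect_equal(unname(rowSums(q$classification)), c(14, 14, 14))
  q2 <- cross_validate(X, y, "plsda", 2, folds = 7, seed = 33)
  expect_identical(q, q2)
  q3 <- cross_validate(X, y, "plsda", 2, folds = 7, seed = 34)
  expect_false(identical(q$classification, q3$classification))
})

test_that("widely separated classes are classified perfectly under 7-fold CV", {
  sg <- shifted_groups(n_per = 21, p = 5, k = 5, delta = 10, seed = 11)
  q <- cross_validate(sg$X, sg$y, "plsda", 2, folds = 7, seed = 1)
  expect_equal(q$CC, 100)
  expect_gt(q$Q2, 0.5)
})

test_that("CC is invariant to class-label renaming", {
  sg <- shifted_groups(n_per = 14, p = 6, k = 3, delta = 1, seed = 12)
  q1 <- cross_validate(sg$X, sg$y, "plsda", 2, folds = 7, seed = 5)
  y2 <- ifelse(sg$y == "A", "zeta", "alpha")
  q2 <- cross_validate(sg$X, y2, "plsda", 2, folds = 7, seed = 5)
  expect_equal(q1$CC, q2$CC)
})

test_that("pure-noise labels give non-positive mean Q2 and Q2 <= R2Y", {
  q2s <- numeric(10); r2ok <- logical(10)
  for (s in seq_len(10)) {
    set.seed(100 + s)
    X <- matrix(rnorm(40 * 30), 40, 30)
    y <- rep(c("A", "B"), each = 20)
    q <- cross_validate(X, y, "plsda", 2, folds = 7, seed = 100 + s)
    q2s[s] <- q$Q2
    r2ok[s] <- q$Q2 <= q$R2Y_cum[2] + 1e-12
  }
  expect_lte(mean(q2s), 0)
  expect_gte(mean(r2ok), 0.95)
})

test_that("folds shrink with a warning when the smallest class is small", {
  set.seed(13)
  X <- matrix(rnorm(24 * 5), 24, 5)
  y <- c(rep("A", 20), rep("B", 4))
  expect_warning(q <- cross_validate(X, y, "plsda", 1, folds = 7, seed = 1),
                 "reducing folds to 4")
  expect_equal(q$folds, 4)
  expect_error(
    cross_validate(X[1:5, ], c("A", "A", "A", "B", "B"), "plsda", 1, folds = 7),
    "fewer samples")
})

test_that("permutation p-values obey the add-one bound and detect real separation", {
  sg <- shifted_groups(n_per = 14, p = 5, k = 5, delta = 10, seed = 14)
  pv <- permutation_validate(sg$X, sg$y, "plsda", n_components = 1,
                             n_permutations = 99, folds = 7, seed = 2)
  expect_equal(pv$p_Q2, 1 / 100)
  expect_gte(pv$p_R2Y, 1 / 100)
  expect_error(permutation_validate(sg$X, sg$y, "plsda", 1,
                                    n_permutations = 5), "20")
})

test_that("PLS-DA agrees with an independent implementation on scores and prediction", {
  skip_if_not_installed("mixOmics")
  set.seed(15)
  X <- matrix(rnorm(30 * 12), 30, 12)
  colnames(X) <- paste0("V", 1:12)
  y <- rep(c("A", "B"), each = 15)
  fit <- fit_plsda(X, y, 2)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = TRUE)
  for (k in 1:2) {
    r <- abs(cor(fit$scores[, k], ref$variates$X[, k]))
    expect_gt(r, 1 - 1e-6)
  }
})
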