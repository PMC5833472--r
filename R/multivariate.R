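# Run code under a local RNG state so seeded routines do not disturb the
# caller's random stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.check_X <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute before fitting")
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < 2))
    stop("class '", names(tab)[which(tab < 2)[1]], "' has fewer than 2 members")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[which(sds == 0)[1]]
    if (is.null(nm)) nm <- which(sds == 0)[1]
    stop("constant (zero-variance) feature: ", nm)
  }
  list(X = X, y = y)
}

.autoscale <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  list(Xs = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.one_hot <- function(y) {
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Y
}

# NIPALS PLS2 on already centered/scaled X and Y.
.nipals_pls <- function(Xs, Ys, n_components, tol = 1e-12, max_iter = 500) {
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Ys)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components); Tm <- matrix(0, n, n_components)
  r2y <- numeric(n_components)
  ssy0 <- sum(Ys^2)
  Xr <- Xs; Yr <- Ys
  for (k in seq_len(n_components)) {
    u <- Yr[, which.max(apply(Yr, 2, stats::var)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xr, u)) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xr %*% w)
      qq <- drop(crossprod(Yr, tt)) / sum(tt^2)
      u <- drop(Yr %*% qq) / sum(qq^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), .Machine$double.eps) < tol) break
      t_old <- tt
    }
    # deterministic sign convention: largest-|w| element positive
    if (w[which.max(abs(w))] < 0) { w <- -w; tt <- -tt; qq <- -qq }
    pp <- drop(crossprod(Xr, tt)) / sum(tt^2)
    Xr <- Xr - tcrossprod(tt, pp)
    Yr <- Yr - tcrossprod(tt, qq)
    W[, k] <- w; P[, k] <- pp; Q[, k] <- qq; Tm[, k] <- tt
    r2y[k] <- 1 - sum(Yr^2) / ssy0
  }
  list(W = W, P = P, Q = Q, scores = Tm, R2Y_cum = r2y)
}

#' Fit a PLS-DA model
#'
#' Partial least squares regression of a one-indicator-column-per-class
#' response on the autoscaled (mean-centered, unit-variance) feature
#' matrix, fitted by NIPALS. The fit is deterministic given input order.
#'
#' @param X Numeric matrix, samples x features, no missing values
#'   (log10-scale intensities in the standard workflow).
#' @param y Class labels (factor or character), >= 2 classes with >= 2
#'   members each.
#' @param n_components Number of predictive components.
#' @return A `da_model` (kind `"plsda"`) holding weights `W`, loadings
#'   `P`, y-loadings `Q`, training `scores`, cumulative `R2Y_cum`, and
#'   the centering/scaling vectors for X and Y.
#' @export
fit_plsda <- function(X, y, n_components = 2) {
  chk <- .check_X(X, y)
  X <- chk$X; y <- chk$y
  n_components <- as.integer(n_components)
  rank_bound <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > rank_bound)
    stop("n_components must be between 1 and ", rank_bound)
  xs <- .autoscale(X)
  Y <- .one_hot(y)
  ys <- .autoscale(Y)
  fit <- .nipals_pls(xs$Xs, ys$Xs, n_components)
  structure(list(
    kind = "plsda", levels = levels(y), y = y,
    W = fit$W, P = fit$P, Q = fit$Q, scores = fit$scores,
    R2Y_cum = fit$R2Y_cum, n_predictive = n_components, n_orthogonal = 0L,
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center, y_scale = ys$scale,
    feature_names = colnames(X)
  ), class = "da_model")
}

#' Fit an OPLS-DA model
#'
#' Two-class orthogonal PLS-DA: orthogonal-signal-correction components
#' capturing systematic variation uncorrelated with class are removed
#' from the autoscaled X, then a single predictive PLS component is
#' fitted on the deflated matrix. With `n_orthogonal = 0` the predictive
#' scores coincide with one-component PLS-DA scores.
#'
#' @param X As in [fit_plsda()].
#' @param y Exactly two classes.
#' @param n_orthogonal Number of orthogonal components (>= 0).
#' @return A `da_model` (kind `"oplsda"`) with predictive weight/loading
#'   vectors plus `W_ortho`/`P_ortho` and orthogonal scores.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1) {
  chk <- .check_X(X, y)
  X <- chk$X; y <- chk$y
  if (nlevels(y) != 2) stop("OPLS-DA requires exactly 2 classes")
  n_orthogonal <- as.integer(n_orthogonal)
  xs <- .autoscale(X)
  Y <- .one_hot(y)
  ys <- .autoscale(Y)
  yv <- ys$Xs[, 2]  # single centered-scaled indicator carries both columns
  Xr <- xs$Xs
  p <- ncol(Xr); n <- nrow(Xr)
  W_o <- matrix(0, p, n_orthogonal); P_o <- matrix(0, p, n_orthogonal)
  T_o <- matrix(0, n, n_orthogonal)
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xr, yv)) / sum(yv^2)
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xr %*% w)
    pp <- drop(crossprod(Xr, tt)) / sum(tt^2)
    wo <- pp - drop(crossprod(w, pp)) * w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-12) {  # no y-orthogonal structure left
      W_o <- W_o[, seq_len(k - 1), drop = FALSE]
      P_o <- P_o[, seq_len(k - 1), drop = FALSE]
      T_o <- T_o[, seq_len(k - 1), drop = FALSE]
      n_orthogonal <- k - 1L
      break
    }
    wo <- wo / nw
    to <- drop(Xr %*% wo)
    po <- drop(crossprod(Xr, to)) / sum(to^2)
    Xr <- Xr - tcrossprod(to, po)
    W_o[, k] <- wo; P_o[, k] <- po; T_o[, k] <- to
  }
  w <- drop(crossprod(Xr, yv)) / sum(yv^2)
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w  # same sign convention as PLS-DA
  tt <- drop(Xr %*% w)
  pp <- drop(crossprod(Xr, tt)) / sum(tt^2)
  qq <- sum(yv * tt) / sum(tt^2)
  r2y <- 1 - sum((yv - tt * qq)^2) / sum(yv^2)
  structure(list(
    kind = "oplsda", levels = levels(y), y = y,
    W = matrix(w, ncol = 1), P = matrix(pp, ncol = 1), Q = matrix(qq, 1, 1),
    scores = matrix(tt, ncol = 1),
    W_ortho = W_o, P_ortho = P_o, scores_ortho = T_o,
    R2Y_cum = r2y, n_predictive = 1L, n_orthogonal = n_orthogonal,
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center[2], y_scale = ys$scale[2],
    feature_names = colnames(X)
  ), class = "da_model")
}

#' @export
print.da_model <- function(x, ...) {
  cat(toupper(x$kind), " model: ", length(x$levels), " classes (",
      paste(x$levels, collapse = ", "), "), ",
      x$n_predictive, " predictive + ", x$n_orthogonal,
      " orthogonal component(s)\n", sep = "")
  cat("  cumulative R2Y:", paste(sprintf("%.3f", x$R2Y_cum), collapse = " "), "\n")
  invisible(x)
}

# apply stored scaling and (for oplsda) orthogonal-component removal
.prepare_new <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_center))
    stop("feature count mismatch: model has ", length(model$x_center),
         ", new data has ", ncol(X_new))
  if (!is.null(model$feature_names) && !is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$feature_names))
    stop("feature names/order differ from the training matrix")
  Xs <- sweep(sweep(X_new, 2, model$x_center), 2, model$x_scale, "/")
  if (model$kind == "oplsda" && model$n_orthogonal > 0) {
    for (k in seq_len(model$n_orthogonal)) {
      to <- drop(Xs %*% model$W_ortho[, k])
      Xs <- Xs - tcrossprod(to, model$P_ortho[, k])
    }
  }
  Xs
}

#' Project new samples onto a fitted model
#'
#' Applies the stored centering/scaling (and, for OPLS-DA, removal of the
#' orthogonal components) and returns predictive component scores.
#' Projecting the training matrix reproduces the training scores.
#'
#' @param model A `da_model`.
#' @param X_new Matrix with the training feature set, same order.
#' @return Numeric matrix of scores (samples x predictive components).
#' @export
project_samples <- function(model, X_new) {
  Xs <- .prepare_new(model, X_new)
  # W* = W (P'W)^-1 gives scores in one pass, identical to sequential
  # NIPALS deflation
  Wstar <- model$W %*% solve(crossprod(model$P, model$W))
  Xs %*% Wstar
}

#' Predict class membership
#'
#' @param object A `da_model`.
#' @param X_new New data matrix (training feature set and order).
#' @param ... Unused.
#' @return List with `scores`, `y_hat` (predicted indicator values on the
#'   0/1 scale) and `class` (argmax rule; ties resolved toward the
#'   earlier class level).
#' @export
predict.da_model <- function(object, X_new, ...) {
  model <- object
  scores <- project_samples(model, X_new)
  Ys_hat <- scores %*% t(model$Q)
  if (model$kind == "plsda") {
    Y_hat <- sweep(sweep(Ys_hat, 2, model$y_scale, "*"), 2, model$y_center, "+")
    colnames(Y_hat) <- model$levels
  } else {
    yh <- drop(Ys_hat) * model$y_scale + model$y_center
    Y_hat <- cbind(1 - yh, yh)
    colnames(Y_hat) <- model$levels
  }
  cls <- model$levels[apply(Y_hat, 1, which.max)]  # which.max: first max wins
  list(scores = scores, y_hat = Y_hat, class = factor(cls, levels = model$levels))
}

.stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  assignment <- integer(length(y))
  .with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validate a discriminant model
#'
#' Stratified random partition into `folds` subsets (default 7); each
#' subset is predicted by a model fitted on the remaining samples, so
#' every sample is predicted exactly once. Q2 is computed per cumulative
#' component count as 1 - PRESS/TSS on the globally centered/scaled
#' indicator matrix, with PRESS pooled over folds. The classification
#' table and CC% come from the argmax class predictions.
#'
#' @param X,y As in [fit_plsda()].
#' @param kind `"plsda"` or `"oplsda"`.
#' @param n_components Predictive components (plsda) — Q2 is reported
#'   cumulatively up to this count.
#' @param folds Number of folds; reduced (with a warning) to the smallest
#'   class size when a class has fewer members than folds.
#' @param seed Integer seed for the fold partition.
#' @param n_orthogonal Orthogonal components for `kind = "oplsda"`.
#' @return A `model_quality` list: `R2Y_cum` (full-data fit), `Q2_cum`,
#'   `Q2` (last element), `classification` (true x predicted counts),
#'   `CC` (percent correctly classified), `folds`, `seed`.
#' @export
cross_validate <- function(X, y, kind = c("plsda", "oplsda"),
                           n_components = 2, folds = 7, seed = 1,
                           n_orthogonal = 1) {
  kind <- match.arg(kind)
  chk <- .check_X(X, y)
  X <- chk$X; y <- chk$y
  n <- nrow(X)
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class (", min_class, ") smaller than folds (", folds,
            "); reducing folds to ", min_class)
    folds <- min_class
  }
  fold_of <- .stratified_folds(y, folds, seed)

  fit_fun <- function(Xtr, ytr) {
    if (kind == "plsda") fit_plsda(Xtr, ytr, n_components)
    else fit_oplsda(Xtr, ytr, n_orthogonal)
  }
  full <- fit_fun(X, y)

  Y <- .one_hot(y)
  ys <- .autoscale(Y)
  ncomp_eff <- if (kind == "plsda") as.integer(n_components) else 1L
  press <- matrix(0, ncomp_eff, 1)
  pred_class <- factor(rep(NA_character_, n), levels = levels(y))
  for (f in seq_len(folds)) {
    hold <- fold_of == f
    m <- fit_fun(X[!hold, , drop = FALSE], droplevels(y[!hold]))
    if (!identical(levels(droplevels(y[!hold])), levels(y)))
      stop("a training fold lost a class; increase class sizes or reduce folds")
    Xs <- .prepare_new(m, X[hold, , drop = FALSE])
    for (k in seq_len(ncomp_eff)) {
      Wk <- m$W[, seq_len(k), drop = FALSE]
      Pk <- m$P[, seq_len(k), drop = FALSE]
      Qk <- m$Q[, seq_len(k), drop = FALSE]
      Tk <- Xs %*% Wk %*% solve(crossprod(Pk, Wk))
      Ys_hat <- Tk %*% t(Qk)
      if (kind == "plsda") {
        Y_hat <- sweep(sweep(Ys_hat, 2, m$y_scale, "*"), 2, m$y_center, "+")
      } else {
        yh <- drop(Ys_hat) * m$y_scale + m$y_center
        Y_hat <- cbind(1 - yh, yh)
      }
      # residual in the global centered/scaled indicator space
      Yh_cs <- sweep(sweep(Y_hat, 2, ys$center), 2, ys$scale, "/")
      press[k] <- press[k] + sum((ys$Xs[hold, , drop = FALSE] - Yh_cs)^2)
      if (k == ncomp_eff)
        pred_class[hold] <- levels(y)[apply(Y_hat, 1, which.max)]
    }
  }
  tss <- sum(ys$Xs^2)
  q2_cum <- 1 - drop(press) / tss
  ctab <- table(true = y, predicted = pred_class)
  cc <- 100 * sum(diag(ctab)) / sum(ctab)
  structure(list(
    kind = kind, R2Y_cum = full$R2Y_cum, Q2_cum = q2_cum,
    Q2 = q2_cum[length(q2_cum)],
    classification = ctab, CC = cc, folds = folds, seed = seed,
    p_R2Y = NA_real_, p_Q2 = NA_real_, n_permutations = 0L
  ), class = "model_quality")
}

#' @export
print.model_quality <- function(x, ...) {
  cat(toupper(x$kind), " ", x$folds, "-fold cross-validation\n", sep = "")
  cat("  R2Y(cum):", paste(sprintf("%.3f", x$R2Y_cum), collapse = " "), "\n")
  cat("  Q2(cum): ", paste(sprintf("%.3f", x$Q2_cum), collapse = " "), "\n")
  cat("  CC: ", sprintf("%.1f%%", x$CC), "\n")
  if (x$n_permutations > 0)
    cat("  permutation p (R2Y, Q2): ", x$p_R2Y, ", ", x$p_Q2,
        " [", x$n_permutations, " permutations]\n", sep = "")
  print(x$classification)
  invisible(x)
}

#' Permutation validation of model quality
#'
#' Refits and cross-validates the model under `n_permutations` random
#' relabelings of `y` and reports add-one permutation p-values for R2Y
#' and Q2: p = (1 + #\{permuted >= observed\}) / (1 + n_permutations), so
#' p is never smaller than 1/(n_permutations + 1).
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations (>= 20).
#' @return List with `p_R2Y`, `p_Q2`, `observed` (R2Y, Q2), and the
#'   permuted statistics.
#' @export
permutation_validate <- function(X, y, kind = c("plsda", "oplsda"),
                                 n_components = 2, n_permutations = 200,
                                 folds = 7, seed = 1, n_orthogonal = 1) {
  kind <- match.arg(kind)
  if (n_permutations < 20) stop("use at least 20 permutations")
  obs <- cross_validate(X, y, kind, n_components, folds, seed, n_orthogonal)
  obs_r2 <- obs$R2Y_cum[length(obs$R2Y_cum)]
  obs_q2 <- obs$Q2
  perm_seeds <- .with_seed(seed, sample.int(2^31 - 2, n_permutations))
  stats <- vapply(seq_len(n_permutations), function(b) {
    yp <- .with_seed(perm_seeds[b], sample(y))
    q <- cross_validate(X, yp, kind, n_components, folds,
                        seed = perm_seeds[b], n_orthogonal = n_orthogonal)
    c(q$R2Y_cum[length(q$R2Y_cum)], q$Q2)
  }, numeric(2))
  p_r2 <- (1 + sum(stats[1, ] >= obs_r2)) / (1 + n_permutations)
  p_q2 <- (1 + sum(stats[2, ] >= obs_q2)) / (1 + n_permutations)
  list(p_R2Y = p_r2, p_Q2 = p_q2,
       observed = c(R2Y = obs_r2, Q2 = obs_q2),
       permuted_R2Y = stats[1, ], permuted_Q2 = stats[2, ],
       n_permutations = n_permutations, seed = seed)
}
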