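#' @title Multivariate class models
#' @description PCA and PLS-DA in the style of the SIMCA-era modelling
#'   software: sequential (NIPALS) component extraction on centered,
#'   unit-variance-scaled data, cross-validated Q2, Hotelling T2 and DModX
#'   diagnostics, VIP scores with jackknife confidence intervals, the
#'   group-median (Xclass - Xtot) transform, and complete-linkage
#'   hierarchical clustering.
#' @name multivariate
NULL

preprocess_xy <- function(X, scale = c("uv", "center")) {
  scale <- match.arg(scale)
  center <- colMeans(X)
  if (scale == "uv") {
    s <- apply(X, 2L, stats::sd)
    zero <- which(s < .Machine$double.eps^0.5)
    if (length(zero))
      stop("zero-variance variable(s): ",
           paste(colnames(X)[zero] %||% zero, collapse = ", "))
  } else s <- rep(1, ncol(X))
  list(X = sweep(sweep(X, 2L, center), 2L, s, "/"), center = center, scale = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic row-wise fold assignment (whole observations per fold).
cv_fold_ids <- function(n, k) rep_len(seq_len(k), n)

# Fix component sign so the largest-magnitude loading/weight is positive.
fix_sign <- function(vec) if (vec[which.max(abs(vec))] < 0) -vec else vec

nipals_pca_core <- function(X, A, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X)
  T <- matrix(0, n, A); P <- matrix(0, p, A)
  for (a in seq_len(A)) {
    j0 <- which.max(colSums(X^2))
    t <- X[, j0]
    if (sum(t^2) == 0) { T <- T[, seq_len(a - 1L), drop = FALSE]
                         P <- P[, seq_len(a - 1L), drop = FALSE]; break }
    for (it in seq_len(max_iter)) {
      pl <- drop(crossprod(X, t)) / sum(t^2)
      pl <- pl / sqrt(sum(pl^2))
      t_new <- drop(X %*% pl)
      if (sqrt(sum((t_new - t)^2)) < tol * sqrt(sum(t_new^2))) { t <- t_new; break }
      t <- t_new
    }
    pl <- fix_sign(pl)
    t <- drop(X %*% pl)
    T[, a] <- t; P[, a] <- pl
    X <- X - tcrossprod(t, pl)
  }
  list(T = T, P = P, residual = X)
}

#' Fit a PCA model with cross-validated Q2 and diagnostics
#'
#' Components are extracted sequentially (NIPALS) from the centered and
#' (by default) unit-variance-scaled matrix, each maximizing residual
#' variance. Q2 comes from K-fold cross-validation assigning whole
#' observations (rows) to folds: per fold the model is refit on the training
#' rows, held-out rows are projected onto the training loadings, and the
#' reconstruction PRESS is accumulated; `Q2_a = 1 - PRESS_a / SS_{a-1}` with
#' `SS_{a-1}` the full-data residual sum of squares after a-1 components.
#'
#' @param X Numeric matrix, observations x variables, no missing values.
#' @param n_components Number of components A (<= min(dim)).
#' @param cv_folds Folds for Q2 (default 7, the conventional default of the
#'   era's modelling software); must be >= 2.
#' @param scale `"uv"` (unit variance, default) or `"center"` (centering
#'   only).
#' @param t2_level,dcrit_level Tolerance levels for the Hotelling T2 region
#'   and the DModX critical distance.
#' @return list with `model` (a `latent_model`: scores, loadings,
#'   eigenvalues, per-component and cumulative R2X and Q2) and `diagnostics`
#'   (per-observation T2 and DModX with their limits).
#' @export
fit_pca <- function(X, n_components = 2, cv_folds = 7,
                    scale = c("uv", "center"),
                    t2_level = 0.95, dcrit_level = 0.05) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values (filter upstream)")
  n <- nrow(X); p <- ncol(X)
  A <- n_components
  if (A > min(n, p)) stop("n_components exceeds min(dim(X))")
  scale <- match.arg(scale)
  pp <- preprocess_xy(X, scale)
  X0 <- pp$X
  ss0 <- sum(X0^2)
  fit <- nipals_pca_core(X0, A)
  A <- ncol(fit$T)
  rownames(fit$T) <- rownames(X)
  rownames(fit$P) <- colnames(X)
  expl <- colSums(fit$T^2)
  r2x <- expl / ss0
  eig <- apply(fit$T, 2L, stats::var) * (n - 1)

  # K-fold row-wise cross-validation
  k <- min(cv_folds, n)
  if (k < 2) stop("cv_folds must be >= 2")
  folds <- cv_fold_ids(n, k)
  press <- numeric(A)
  for (f in seq_len(k)) {
    tr <- folds != f
    pp_tr <- preprocess_xy(X[tr, , drop = FALSE], scale)
    fit_tr <- nipals_pca_core(pp_tr$X, A)
    Xh <- sweep(sweep(X[!tr, , drop = FALSE], 2L, pp_tr$center), 2L, pp_tr$scale, "/")
    for (a in seq_len(ncol(fit_tr$P))) {
      pa <- rbind(fit_tr$P[, a])
      th <- Xh %*% t(pa)
      Xh <- Xh - th %*% pa
      press[a] <- press[a] + sum(Xh^2)
    }
  }
  ss_before <- c(ss0, ss0 - cumsum(expl))[seq_len(A)]
  q2 <- 1 - press / ss_before
  q2_cum <- 1 - cumprod(press / ss_before)

  # diagnostics on the full model
  s2 <- apply(fit$T, 2L, stats::var)
  t2 <- rowSums(sweep(fit$T^2, 2L, s2, "/"))
  t2_limit <- A * (n^2 - 1) / (n * (n - A)) *
    stats::qf(t2_level, A, n - A)
  E <- fit$residual
  dof_row <- p - A
  s0 <- sqrt(sum(E^2) / ((n - A - 1) * dof_row))
  dmodx <- sqrt(rowSums(E^2) / dof_row) / s0
  dcrit <- sqrt(stats::qf(1 - dcrit_level, dof_row, (n - A - 1) * dof_row))

  model <- structure(list(
    kind = "PCA", center = pp$center, scale = pp$scale, scale_mode = scale,
    scores = fit$T, loadings = fit$P, eigenvalues = eig,
    r2x = r2x, r2x_cum = cumsum(r2x), q2 = q2, q2_cum = q2_cum,
    n_components = A, n_obs = n, n_var = p), class = "latent_model")
  diagnostics <- list(t2 = t2, t2_limit = t2_limit,
                      dmodx = dmodx, dcrit = dcrit)
  list(model = model, diagnostics = diagnostics)
}

nipals_pls_core <- function(X, Y, A, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  T <- matrix(0, n, A); W <- matrix(0, p, A)
  P <- matrix(0, p, A); C <- matrix(0, q, A)
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    if (sum(u^2) == 0) break
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u)); w <- w / sqrt(sum(w^2))
      t <- drop(X %*% w)
      cc <- drop(crossprod(Y, t)) / sum(t^2)
      u <- drop(Y %*% cc) / sum(cc^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    sgn <- if (w[which.max(abs(w))] < 0) -1 else 1
    w <- sgn * w; t <- sgn * t; cc <- sgn * cc
    pl <- drop(crossprod(X, t)) / sum(t^2)
    T[, a] <- t; W[, a] <- w; P[, a] <- pl; C[, a] <- cc
    X <- X - tcrossprod(t, pl)
    Y <- Y - tcrossprod(t, cc)
  }
  list(T = T, W = W, P = P, C = C, Xres = X, Yres = Y)
}

#' Fit a PLS-DA model
#'
#' Y is the K-column class-indicator (dummy) matrix, column-centered;
#' components are extracted by the iterative two-block (NIPALS) algorithm —
#' the weight vector converges to the dominant direction of X'Y Y'X — with
#' deflation of X and Y per component. Q2 comes from K-fold row-wise
#' cross-validation of the Y predictions.
#'
#' @param X Numeric matrix, observations x variables, no missing values.
#' @param classes Factor or character vector of class labels (K >= 2, every
#'   class represented).
#' @param n_components Number of components.
#' @param cv_folds CV folds for Q2; every training fold must contain every
#'   class.
#' @param scale `"uv"` or `"center"` preprocessing for X.
#' @return A `latent_model` with X-weights `weights` (W), loadings, Y-loadings
#'   `y_loadings` (C), combined weights `wstar` (W(P'W)^-1), scores, dummy
#'   column names `classes`, per-component and cumulative R2X, R2Y and Q2.
#' @export
fit_plsda <- function(X, classes, n_components = 2, cv_folds = 7,
                      scale = c("uv", "center")) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  classes <- as.factor(classes)
  if (nlevels(classes) < 2) stop("need at least 2 classes")
  if (any(table(classes) == 0)) stop("every class must be represented")
  n <- nrow(X)
  if (length(classes) != n) stop("classes must match rows of X")
  scale <- match.arg(scale)
  A <- n_components
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  y_center <- colMeans(Y)
  Y0 <- sweep(Y, 2L, y_center)
  pp <- preprocess_xy(X, scale)
  ssx0 <- sum(pp$X^2); ssy0 <- sum(Y0^2)
  fit <- nipals_pls_core(pp$X, Y0, A)
  rownames(fit$T) <- rownames(X)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X)
  r2x <- sapply(seq_len(A), function(a)
    sum(tcrossprod(fit$T[, a], fit$P[, a])^2)) / ssx0
  ssy_expl <- sapply(seq_len(A), function(a)
    sum(tcrossprod(fit$T[, a], fit$C[, a])^2))
  r2y <- ssy_expl / ssy0
  wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))

  k <- min(cv_folds, n)
  if (k < 2) stop("cv_folds must be >= 2")
  folds <- cv_fold_ids(n, k)
  press <- numeric(A)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (any(table(classes[tr]) == 0))
      stop("cross-validation fold ", f, " excludes class(es) ",
           paste(names(which(table(classes[tr]) == 0)), collapse = ", "),
           " entirely from training")
    pp_tr <- preprocess_xy(X[tr, , drop = FALSE], scale)
    Ytr <- Y[tr, , drop = FALSE]
    yc_tr <- colMeans(Ytr)
    fit_tr <- nipals_pls_core(pp_tr$X, sweep(Ytr, 2L, yc_tr), A)
    Xh <- sweep(sweep(X[!tr, , drop = FALSE], 2L, pp_tr$center), 2L, pp_tr$scale, "/")
    Yh <- sweep(Y[!tr, , drop = FALSE], 2L, yc_tr)
    Yhat <- matrix(0, nrow(Yh), ncol(Yh))
    for (a in seq_len(A)) {
      th <- Xh %*% fit_tr$W[, a, drop = FALSE]
      Xh <- Xh - th %*% rbind(fit_tr$P[, a])
      Yhat <- Yhat + th %*% rbind(fit_tr$C[, a])
      press[a] <- press[a] + sum((Yh - Yhat)^2)
    }
  }
  ssy_before <- c(ssy0, ssy0 - cumsum(ssy_expl))[seq_len(A)]
  q2 <- 1 - press / ssy_before
  q2_cum <- 1 - cumprod(press / ssy_before)

  structure(list(
    kind = "PLSDA", center = pp$center, scale = pp$scale, scale_mode = scale,
    y_center = y_center, classes = levels(classes), class_labels = classes,
    scores = fit$T, weights = fit$W, loadings = fit$P, y_loadings = fit$C,
    wstar = wstar, eigenvalues = apply(fit$T, 2L, stats::var) * (n - 1),
    r2x = r2x, r2x_cum = cumsum(r2x), r2y = r2y, r2y_cum = cumsum(r2y),
    ssy_explained = ssy_expl, q2 = q2, q2_cum = q2_cum,
    n_components = A, n_obs = n, n_var = ncol(X)), class = "latent_model")
}

#' Predict classes from a PLS-DA model
#'
#' @param model A PLS-DA `latent_model`.
#' @param X New observations (same variables).
#' @return list with `y_hat` (predicted dummy values) and `class` (argmax
#'   over dummy columns).
#' @export
plsda_predict <- function(model, X) {
  stopifnot(model$kind == "PLSDA")
  Xh <- sweep(sweep(as.matrix(X), 2L, model$center), 2L, model$scale, "/")
  Th <- Xh %*% model$wstar
  Yhat <- sweep(tcrossprod(Th, model$y_loadings), 2L, model$y_center, "+")
  colnames(Yhat) <- model$classes
  list(y_hat = Yhat, class = model$classes[max.col(Yhat)])
}

#' Variable importance in the projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a )` where
#' `SSY_a` is the Y sum of squares explained by component a and p the number
#' of variables; mean(VIP^2) = 1, so VIP > 1 marks the variables most
#' relevant for class separation.
#'
#' @param model A PLS-DA `latent_model`.
#' @return Numeric vector of VIP scores (named when X had column names).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$kind != "PLSDA") stop("VIP is defined for PLS-DA models")
  ssy <- model$ssy_explained
  if (sum(ssy) <= 0) stop("model explains zero Y variance")
  W <- model$weights
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(wn^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(W)
  vip
}

#' Jackknife confidence intervals for VIP
#'
#' Leave-one-observation-out refits give n VIP vectors; the interval is the
#' point estimate plus/minus `t(0.975, n-1)` times the jackknife standard
#' error `sqrt((n-1)/n * sum((vip_i - mean)^2))`.
#'
#' @param X,classes,n_components,scale As in [fit_plsda()].
#' @param conf Confidence level.
#' @param cv_folds Folds used for the point-estimate fit (Q2 only; does not
#'   affect VIP).
#' @return data.frame with columns `variable`, `vip`, `se`, `lower`, `upper`.
#' @export
jackknife_vip <- function(X, classes, n_components = 2, scale = "uv",
                          conf = 0.95, cv_folds = 7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations for jackknifing")
  point <- compute_vip(fit_plsda(X, classes, n_components,
                                 cv_folds = min(cv_folds, n), scale = scale))
  reps <- matrix(NA_real_, n, length(point))
  for (i in seq_len(n)) {
    res <- tryCatch(
      compute_vip(fit_plsda(X[-i, , drop = FALSE], classes[-i], n_components,
                            cv_folds = 2, scale = scale)),
      error = function(e)
        stop("jackknife refit failed leaving out observation ", i, ": ",
             conditionMessage(e)))
    reps[i, ] <- res
  }
  m <- colMeans(reps)
  se <- sqrt((n - 1) / n * colSums(sweep(reps, 2L, m)^2))
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  data.frame(variable = names(point) %||% seq_along(point),
             vip = unname(point), se = se,
             lower = unname(point) - tq * se,
             upper = unname(point) + tq * se,
             stringsAsFactors = FALSE)
}

#' Group-median transform (Xclass - Xtot)
#'
#' For every peptide, the difference between each group's median log2
#' intensity and the peptide's median over all included runs — the transform
#' used for the two-way clustered heatmaps.
#'
#' @param mat [intensity_matrix()].
#' @param groups Named character vector run id -> group label.
#' @return Numeric matrix peptides x groups (NA where a group is entirely
#'   missing for a peptide).
#' @export
group_median_transform <- function(mat, groups) {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- mat$values
  g <- groups[colnames(v)]
  if (anyNA(g)) stop("groups do not cover all runs")
  glev <- unique(unname(g))
  out <- matrix(NA_real_, nrow(v), length(glev),
                dimnames = list(rownames(v), glev))
  for (p in seq_len(nrow(v))) {
    xtot <- stats::median(v[p, ], na.rm = TRUE)
    for (k in seq_along(glev)) {
      x <- v[p, g == glev[k]]
      if (!all(is.na(x))) out[p, k] <- stats::median(x, na.rm = TRUE) - xtot
    }
  }
  out
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with complete linkage on Euclidean distances,
#' applied to rows, columns, or both axes independently (two-way clustering).
#'
#' @param x Numeric matrix without missing entries.
#' @param axis `"rows"`, `"columns"` or `"both"`.
#' @return An `hclust` object, or for `"both"` a list with elements `rows`
#'   and `columns`.
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "columns", "both")) {
  axis <- match.arg(axis)
  if (anyNA(x)) stop("clustering requires a complete (no missing) grid")
  one <- function(m) {
    if (nrow(m) < 2) stop("fewer than 2 items to cluster")
    stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  }
  switch(axis,
         rows = one(x),
         columns = one(t(x)),
         both = list(rows = one(x), columns = one(t(x))))
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @return Single Newick-format character string (branch lengths from merge
#'   heights).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
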