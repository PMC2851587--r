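test_that("PCA matches an SVD oracle up to component sign", {
  set.seed(42)
  X <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("o", 1:10), paste0("v", 1:6)))
  f <- fit_pca(X, 3, cv_folds = 5)
  sv <- svd(scale(X))
  for (a in 1:3) {
    s <- sign(sum(sv$v[, a] * f$model$loadings[, a]))
    expect_lt(max(abs(f$model$scores[, a] - s * sv$u[, a] * sv$d[a])), 1e-8)
    expect_lt(max(abs(f$model$loadings[, a] - s * sv$v[, a])), 1e-8)
  }
  expect_equal(f$model$r2x, sv$d[1:3]^2 / sum(sv$d^2), tolerance = 1e-10)
  # eigenvalues are (n-1) * score variance
  expect_equal(f$model$eigenvalues,
               apply(f$model$scores, 2, var) * 9, tolerance = 1e-12)
})

test_that("PCA explains rank-deficient data completely", {
  set.seed(1)
  u <- rnorm(8); w <- rnorm(5)
  X1 <- outer(u, w)                      # rank 1 after centering (approx)
  X1 <- sweep(X1, 2, colMeans(X1))       # exactly rank 1 centered
  f1 <- fit_pca(X1 + 0, 1, cv_folds = 4, scale = "center")
  expect_equal(f1$model$r2x[1], 1, tolerance = 1e-8)

  X2 <- outer(rnorm(10), rnorm(6)) + outer(rnorm(10), rnorm(6))
  f2 <- fit_pca(X2, 2, cv_folds = 5, scale = "center")
  expect_equal(f2$model$r2x_cum[2], 1, tolerance = 1e-8)
})

test_that("T2 and DModX behave at their degenerate anchors", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  # append the variable-wise mean as an observation: its scores are 0
  Xm <- rbind(X, colMeans(X))
  f <- fit_pca(Xm, 2, cv_folds = 5, scale = "center")
  expect_lt(f$diagnostics$t2[11], 1e-16)
  # rank-2 data: every observation lies in the model plane (zero residual)
  X2 <- outer(rnorm(9), rnorm(5)) + outer(rnorm(9), rnorm(5))
  f2 <- fit_pca(X2, 2, cv_folds = 3, scale = "center")
  recon <- f2$model$scores %*% t(f2$model$loadings)
  expect_lt(max(abs(sweep(X2, 2, colMeans(X2)) - recon)), 1e-8)
  # DModX follows its documented normalized-residual formula
  E <- sweep(Xm, 2, colMeans(Xm)) - f$model$scores %*% t(f$model$loadings)
  s0 <- sqrt(sum(E^2) / ((11 - 2 - 1) * (4 - 2)))
  expect_equal(f$diagnostics$dmodx,
               sqrt(rowSums(E^2) / (4 - 2)) / s0, tolerance = 1e-10)
  expect_gt(f$diagnostics$t2_limit, 0)
  expect_gt(f$diagnostics$dcrit, 0)
})

test_that("Q2 of pure noise is near zero or below (seeded runs)", {
  q2s <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(20 * 8), 20, 8)
    fit_pca(Xn, 1, cv_folds = 7)$model$q2[1]
  })
  expect_gte(mean(q2s <= 0.05), 0.95)
})

test_that("zero-variance variables are rejected by name", {
  X <- cbind(v1 = rnorm(6), v2 = rep(1, 6))
  expect_error(fit_pca(X, 1, cv_folds = 3), "v2")
})

test_that("PLS-DA recovers an exactly separating variable", {
  cl <- rep(c("a", "b"), each = 6)
  X <- cbind(v1 = rep(c(0, 5), each = 6), v2 = 1, v3 = 2)
  m <- fit_plsda(X, cl, 1, cv_folds = 3, scale = "center")
  expect_lt(abs(abs(m$weights["v1", 1]) - 1), 1e-8)
  expect_equal(m$r2y[1], 1, tolerance = 1e-8)
})

test_that("the first weight vector has its closed form", {
  set.seed(3)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  cl <- rep(c("a", "b"), each = 6)
  m <- fit_plsda(X, cl, 1, cv_folds = 3)
  # dominant eigenvector of X'Y Y'X on the preprocessed blocks
  Y0 <- scale(stats::model.matrix(~ factor(cl) - 1), scale = FALSE)
  X0 <- scale(X)
  ev <- eigen(t(X0) %*% Y0 %*% t(Y0) %*% X0)$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  s <- sign(sum(ev * m$weights[, 1]))
  expect_lt(max(abs(m$weights[, 1] - s * ev)), 1e-8)
  # for 2 centered classes this direction is proportional to X'y
  y <- Y0[, 1]
  xy <- drop(crossprod(X0, y)); xy <- xy / sqrt(sum(xy^2))
  s2 <- sign(sum(xy * m$weights[, 1]))
  expect_lt(max(abs(m$weights[, 1] - s2 * xy)), 1e-8)
})

test_that("a separable 4-class design is classified perfectly", {
  set.seed(2)
  cls <- rep(paste0("c", 1:4), each = 5)
  X <- matrix(rnorm(20 * 12, 0, 0.3), 20, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  for (k in 1:4) X[cls == paste0("c", k), k] <- X[cls == paste0("c", k), k] + 4
  m <- fit_plsda(X, cls, 3, cv_folds = 5)
  expect_equal(mean(plsda_predict(m, X)$class == cls), 1)
  # scores of successive components are orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # the signature variables carry the class signal: VIP > 1
  vip <- compute_vip(m)
  expect_true(all(vip[1:4] > 1))
})

test_that("a fold that loses a class entirely is an error", {
  X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("v", 1:3)))
  cl <- c("a", rep("b", 9))   # class a has 1 observation
  expect_error(fit_plsda(X, cl, 1, cv_folds = 10), "excludes class")
})

test_that("VIP obeys its algebraic identities", {
  # single component, all |w| equal -> VIP = 1 everywhere
  cl <- rep(c("a", "b"), each = 4)
  X <- cbind(v1 = rep(c(0, 1), each = 4), v2 = rep(c(0, -1), each = 4),
             v3 = rep(c(1, 0), each = 4))
  X <- X + matrix(rnorm(24, 0, 1e-6), 8, 3)
  m <- fit_plsda(X, cl, 1, cv_folds = 2)
  expect_equal(unname(compute_vip(m)), rep(1, 3), tolerance = 1e-3)
  # mean(VIP^2) = 1 for arbitrary fitted models
  set.seed(10)
  for (i in 1:5) {
    Xr <- matrix(rnorm(14 * 7), 14, 7, dimnames = list(NULL, paste0("v", 1:7)))
    clr <- sample(rep(c("a", "b"), 7))
    v <- compute_vip(fit_plsda(Xr, clr, 3, cv_folds = 3))
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
  }
})

test_that("an irrelevant variable gets VIP below 1 in separable designs", {
  hits <- sapply(1:100, function(s) {
    set.seed(5000 + s)
    cl <- rep(c("a", "b"), each = 5)
    X <- cbind(v1 = rep(c(0, 3), each = 5) + rnorm(10, 0, 0.3),
               v2 = rep(c(0, 3), each = 5) + rnorm(10, 0, 0.3),
               noise = rnorm(10))
    compute_vip(fit_plsda(X, cl, 1, cv_folds = 2))["noise"] < 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("jackknife intervals equal an explicit leave-one-out loop", {
  set.seed(11)
  n <- 8
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  X[, 1] <- X[, 1] + rep(c(0, 3), each = 4)
  cl <- rep(c("a", "b"), each = 4)
  jk <- jackknife_vip(X, cl, 2)
  # brute-force oracle
  point <- compute_vip(fit_plsda(X, cl, 2, cv_folds = 7))
  loo <- t(sapply(1:n, function(i)
    compute_vip(fit_plsda(X[-i, ], cl[-i], 2, cv_folds = 2))))
  se <- sqrt((n - 1) / n * colSums(sweep(loo, 2, colMeans(loo))^2))
  tq <- qt(0.975, n - 1)
  expect_lt(max(abs(jk$vip - unname(point))), 1e-10)
  expect_lt(max(abs(jk$se - se)), 1e-10)
  expect_lt(max(abs(jk$lower - (unname(point) - tq * se))), 1e-10)
  expect_lt(max(abs(jk$upper - (unname(point) + tq * se))), 1e-10)
  # the point estimate lies inside its own interval
  expect_true(all(jk$vip >= jk$lower & jk$vip <= jk$upper))
})

test_that("jackknife intervals shrink with replicated data", {
  set.seed(13)
  base <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  base[, 1] <- base[, 1] + rep(c(0, 2), each = 3)
  cl <- rep(c("a", "b"), each = 3)
  w2 <- jackknife_vip(base[rep(1:6, 2), ], rep(cl, 2), 1)
  w6 <- jackknife_vip(base[rep(1:6, 6), ], rep(cl, 6), 1)
  expect_lt(mean(w6$upper - w6$lower), mean(w2$upper - w2$lower))
})

test_that("the group-median transform centers on the total median", {
  groups <- c(r1 = "g1", r2 = "g1", r3 = "g2", r4 = "g2")
  v <- rbind(p1 = c(1, 3, 5, 7), p2 = c(4, 4, 4, 4))
  colnames(v) <- names(groups)
  m <- intensity_matrix(v, "log2")
  gm <- group_median_transform(m, groups)
  expect_equal(gm["p1", ], c(g1 = -2, g2 = 2))
  expect_equal(gm["p2", ], c(g1 = 0, g2 = 0))
  # shift invariance
  m2 <- intensity_matrix(v + 100, "log2")
  expect_equal(group_median_transform(m2, groups), gm)
  # fully missing group -> NA entry
  v3 <- rbind(p1 = c(NA, NA, 5, 7))
  colnames(v3) <- names(groups)
  gm3 <- group_median_transform(intensity_matrix(v3, "log2"), groups)
  expect_true(is.na(gm3["p1", "g1"]))
})

test_that("complete-linkage merges match a brute-force agglomeration oracle", {
  bf_complete_heights <- function(x) {
    D <- as.matrix(dist(x))
    active <- as.list(seq_len(nrow(x)))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- NULL; bh <- Inf
      for (i in 1:(length(active) - 1)) for (j in (i + 1):length(active)) {
        h <- max(D[active[[i]], active[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
      heights <- c(heights, bh)
      merged <- c(active[[best[1]]], active[[best[2]]])
      active <- active[-best]
      active[[length(active) + 1]] <- merged
    }
    heights
  }
  set.seed(8)
  for (r in 1:6) {
    x <- matrix(rnorm(10), 5, 2)
    hc <- hierarchical_cluster(x, "rows")
    expect_equal(hc$height, bf_complete_heights(x), tolerance = 1e-12)
    # permutation invariance of merge heights
    perm <- sample(5)
    expect_equal(sort(hierarchical_cluster(x[perm, ], "rows")$height),
                 sort(hc$height), tolerance = 1e-12)
  }
  # identical rows merge first at height zero
  x <- rbind(c(0, 0), c(5, 5), c(0, 0), c(9, 1))
  hc <- hierarchical_cluster(x, "rows")
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 3))
  # both axes
  two <- hierarchical_cluster(matrix(rnorm(20), 4, 5), "both")
  expect_s3_class(two$rows, "hclust")
  expect_s3_class(two$columns, "hclust")
  expect_error(hierarchical_cluster(matrix(1, 1, 3), "rows"), "fewer than 2")
  # newick export round-trips through ape
  nwk <- dendrogram_newick(two$rows)
  expect_match(nwk, "^\\(")
})
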