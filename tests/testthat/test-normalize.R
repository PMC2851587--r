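test_that("log2 transform is elementwise, missing-preserving and guarded", {
  v <- matrix(c(1024, 1, NA, 8), 2, 2)
  m <- im(v, state = "raw")
  out <- log2_transform(m)
  expect_equal(out$values, matrix(c(10, 0, NA, 3), 2, 2), ignore_attr = TRUE)
  expect_true("log2" %in% out$state)
  bad <- im(matrix(c(-1, 2, 3, 4), 2, 2), state = "raw")
  expect_error(log2_transform(bad), "non-positive")
  expect_error(log2_transform(out), "already")
})

test_that("low-intensity runs are flagged by the MAD rule", {
  set.seed(5)
  v <- matrix(rnorm(200, 16, 0.5), 20, 10)
  m <- im(v)
  med <- apply(v, 2, median)
  # shift one run far below the cohort
  v2 <- v; v2[, 3] <- v[, 3] - 10 * mad(med)
  m2 <- im(v2)
  # direct MAD oracle
  med2 <- apply(m2$values, 2, median)
  oracle <- colnames(m2$values)[med2 < median(med2) - 3 * mad(med2)]
  flags <- flag_outlier_runs(m2, k = 3)
  expect_equal(flags$run_id, oracle)
  expect_true("r3" %in% flags$run_id)

  expect_equal(nrow(flag_outlier_runs(im(matrix(5, 4, 6)), k = 3)), 0L)
  expect_equal(nrow(flag_outlier_runs(m2, k = Inf)), 0L)
  expect_error(flag_outlier_runs(im(v[, 1:3]), 3), "at least 4")
})

test_that("the reference run is the per-peptide median over matched peptides", {
  v <- matrix(c(1, 2, 9,
                4, 5, 6,
                NA, NA, 7), 3, 3, byrow = TRUE)
  ref <- build_reference_run(im(v))
  expect_equal(unname(ref$values), c(2, 5))        # third peptide excluded
  expect_equal(ref$peptides, c("p1", "p2"))

  # observed in exactly half the runs -> excluded (strict inequality)
  v2 <- rbind(c(1, 2, NA, NA), c(1, 2, 3, 4))
  ref2 <- build_reference_run(im(v2))
  expect_equal(ref2$peptides, "p2")

  expect_error(build_reference_run(im(matrix(NA_real_, 2, 2))), "no peptide")
})

test_that("calibration maps runs onto the reference scale exactly", {
  set.seed(6)
  base <- rnorm(30, 16, 2)
  v <- cbind(base, base, base, 2 * base - 3)
  colnames(v) <- paste0("r", 1:4)
  m <- im(v)
  ref <- build_reference_run(m)
  cal <- calibrate_to_reference(m, ref)
  # affine-distorted run inverted exactly
  expect_lt(max(abs(cal$matrix$values[, "r4"] - base)), 1e-10)
  # identical run untouched
  expect_equal(cal$fits$slope[1], 1, tolerance = 1e-10)
  expect_equal(cal$fits$intercept[1], 0, tolerance = 1e-10)

  # noisy run: post-calibration refit has slope 1, intercept 0 (OLS oracle)
  v2 <- cbind(base, base + rnorm(30, 0, 0.3), 0.8 * base + rnorm(30, 0, 0.1) + 2)
  colnames(v2) <- paste0("r", 1:3)
  m2 <- im(v2)
  ref2 <- build_reference_run(m2)
  cal2 <- calibrate_to_reference(m2, ref2)
  for (j in 1:3) {
    fit <- lm(cal2$matrix$values[, j] ~ ref2$values)
    expect_lt(abs(coef(fit)[2] - 1), 1e-8)
    expect_lt(abs(coef(fit)[1]), 1e-8)
  }
  # idempotence
  ref3 <- list(values = ref2$values, peptides = ref2$peptides)
  cal3 <- calibrate_to_reference(cal2$matrix, ref3)
  expect_lt(max(abs(cal3$matrix$values - cal2$matrix$values)), 1e-8)
  # missingness mask untouched
  v3 <- v2; v3[1, 2] <- NA
  cal4 <- calibrate_to_reference(im(v3), build_reference_run(im(v3)))
  expect_identical(unname(is.na(cal4$matrix$values)), unname(is.na(v3)))
})

test_that("degenerate calibrations are rejected", {
  v <- cbind(rnorm(10, 16), rnorm(10, 16), rep(3, 10))
  colnames(v) <- paste0("r", 1:3)
  m <- im(v)
  expect_error(calibrate_to_reference(m, build_reference_run(m)), "degenerate")
})

test_that("run-order drift correction removes a global line exactly", {
  n <- 20
  d <- make_seq_design(n)
  ord <- d$run_order
  # pure linear drift: local linear fit reproduces the global line
  v <- rbind(5 + 0.3 * ord, rep(2, n))
  m <- im(v, state = c("log2", "calibrated"))
  cr <- correct_run_order(m, d, span = 0.5)
  expect_lt(max(abs(cr$matrix$values[1, ] - (5 + 0.3 * mean(ord)))), 1e-6)
  # constant peptide unchanged
  expect_equal(unname(cr$matrix$values[2, ]), rep(2, n))
  # per-peptide mean preserved
  expect_lt(abs(mean(cr$matrix$values[1, ]) - mean(v[1, ])), 1e-8)
})

test_that("the lowess fit equals a per-point tricube weighted-OLS oracle", {
  set.seed(9)
  n <- 25
  d <- make_seq_design(n)
  y <- sin(d$run_order / 5) + rnorm(n, 0, 0.2)
  y[c(4, 11)] <- NA
  v <- rbind(p1 = y, p2 = y + 1)
  m <- im(v, state = c("log2", "calibrated"))
  span <- 0.5
  cr <- correct_run_order(m, d, span = span)
  obs <- which(!is.na(y))
  x <- d$run_order[obs]; yo <- y[obs]
  k <- ceiling(span * length(x))
  oracle <- sapply(seq_along(x), function(i) {
    dist <- abs(x - x[i])
    dmax <- sort(dist)[k]
    w <- ifelse(dist / dmax < 1, (1 - (dist / dmax)^3)^3, 0)
    cf <- coef(lm(yo ~ x, weights = w))
    unname(cf[1] + cf[2] * x[i])
  })
  expect_lt(max(abs(cr$fits[["p1"]]$fitted - oracle)), 1e-8)
  # missing entries stay missing, observed stay observed
  expect_identical(unname(is.na(cr$matrix$values)), unname(is.na(v)))
})

test_that("peptides with fewer than 4 observations are left uncorrected", {
  n <- 10
  d <- make_seq_design(n)
  y <- c(1, NA, 2, NA, NA, 3, NA, NA, NA, NA)
  v <- rbind(p1 = y, p2 = seq_len(n))
  m <- im(v, state = c("log2", "calibrated"))
  cr <- correct_run_order(m, d)
  expect_equal(cr$uncorrected, "p1")
  expect_equal(cr$matrix$values[1, ], v[1, ], ignore_attr = TRUE)
})

test_that("sinusoidal drift with a long period is removed (seeded)", {
  cfg <- quiet_config(drift_amplitude = 1.0, drift_shape = "sinusoidal",
                      drift_period = 0.3, noise_sd = 0.1,
                      miss_steepness = 0.5, miss_midpoint = 5, seed = 3)
  d <- generate_design(cfg)
  sim <- simulate_intensities(cfg, d)
  m <- sim$matrix; m$state <- c("log2", "calibrated")
  cr <- correct_run_order(m, d, 0.5)
  drift <- sim$truth$run_effects$drift
  cors <- apply(cr$matrix$values, 1L, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 5) return(NA_real_)
    cor(v[ok], drift[ok])
  })
  expect_lt(max(abs(cors), na.rm = TRUE), 0.2)
})

test_that("minimum-matching filter counts missing runs per group", {
  groups <- c(r1 = "g1", r2 = "g1", r3 = "g1", r4 = "g2", r5 = "g2", r6 = "g2")
  v <- rbind(p1 = c(1, 2, 3, 4, 5, 6),       # complete
             p2 = c(NA, 2, 3, NA, 5, 6),     # 1 missing in each group
             p3 = c(NA, NA, 3, 4, 5, 6))     # 2 missing in g1
  colnames(v) <- names(groups)
  m <- intensity_matrix(v, "log2")
  f1 <- filter_min_matching(m, groups, 1)
  expect_equal(rownames(f1$values), c("p1", "p2"))
  f0 <- filter_min_matching(m, groups, 0)
  expect_equal(rownames(f0$values), "p1")
  expect_equal(nrow(filter_min_matching(m, groups, 6)$values), 3L)
  expect_error(filter_min_matching(m, groups[-1], 1), "r1")
})

test_that("technical replicates collapse to a per-peptide median pseudo-run", {
  d <- make_seq_design(6)
  d$is_reference <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  d$sample_id[d$is_reference] <- "REF"
  d$run_id[d$is_reference] <- c("REFa", "REFb", "REFc")
  v <- cbind(REFa = c(1, 7, NA), s2 = c(0, 0, 0), REFb = c(2, 7, NA),
             s4 = c(1, 1, 1), REFc = c(10, 7, NA), s6 = c(2, 2, 2))
  rownames(v) <- paste0("p", 1:3)
  colnames(v)[c(2, 4, 6)] <- d$run_id[!d$is_reference]
  m <- intensity_matrix(v, "log2")
  col <- collapse_technical_replicates(m, d)
  expect_equal(ncol(col$matrix$values), 4L)
  expect_equal(unname(col$matrix$values[, "REF"]), c(2, 7, NA))
  expect_equal(sum(col$design$is_reference), 1L)
  expect_equal(col$design$run_order, 1:4)
  # pseudo-run sits where the first replicate was
  expect_equal(colnames(col$matrix$values)[1], "REF")
})
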