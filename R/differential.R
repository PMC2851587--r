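#' @title Per-peptide factorial differential expression
#' @description The fixed-effects 2x2x2 factorial model of each peptide's
#'   log2 intensity on age, sex and treatment with all interactions,
#'   sum-to-zero coding, marginal (Type III) sums of squares computed by
#'   full-vs-reduced model comparison, an overall model F-test with
#'   Benjamini-Hochberg FDR adjustment across peptides, a joint Wald F-test
#'   of all interaction terms, least-squares means, level-contrast fold
#'   changes (ed17 - ed12, F - M, E - C) and tiered pairwise t-tests.
#' @name differential
NULL

TERM_LABELS <- c("age", "sex", "treatment", "age:sex", "age:treatment",
                 "sex:treatment", "age:sex:treatment")

factorial_model_matrix <- function(design) {
  d <- data.frame(
    age = factor(design$age, AGE_LEVELS),
    sex = factor(design$sex, SEX_LEVELS),
    treatment = factor(design$treatment, TRT_LEVELS))
  mm <- stats::model.matrix(
    ~ age * sex * treatment, d,
    contrasts.arg = list(age = "contr.sum", sex = "contr.sum",
                         treatment = "contr.sum"))
  mm
}

rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit the three-way factorial model for one peptide
#'
#' Complete cases only: runs where the peptide is missing are dropped. The
#' full model is fit by least squares with sum-to-zero contrasts; the
#' marginal (Type III) SS of each term is the increase in residual SS when
#' that term's columns are deleted from the full model. The overall F tests
#' the full model against intercept-only, and the joint interaction (Wald) F
#' compares the full model to the main-effects-only model.
#'
#' @param y Named numeric vector of per-run values (names = run ids; NA =
#'   missing).
#' @param design Design table covering the runs of `y`.
#' @return A `factorial_fit` list: coefficients, cell and least-squares
#'   means, fold changes, Type III SS with per-term F/p, overall and
#'   interaction tests, residual variance/df, and `flags` (e.g.
#'   `"unestimable"`, `"zero_residual_df"`, `"degenerate"`).
#' @export
fit_factorial <- function(y, design) {
  design <- design[order(design$run_order), , drop = FALSE]
  y <- y[design$run_id]
  ok <- !is.na(y)
  d <- design[ok, , drop = FALSE]
  yy <- unname(y[ok])
  flags <- character(0)
  out <- list(n_obs = sum(ok), flags = flags)
  class(out) <- "factorial_fit"
  if (length(unique(d$age)) < 2 || length(unique(d$sex)) < 2 ||
      length(unique(d$treatment)) < 2) {
    out$flags <- "unestimable"
    return(out)
  }
  X <- factorial_model_matrix(d)
  if (qr(X)$rank < ncol(X)) {
    out$flags <- "unestimable"
    return(out)
  }
  fit <- stats::lm.fit(X, yy)
  rss_full <- sum(fit$residuals^2)
  df_res <- length(yy) - ncol(X)
  asgn <- attr(X, "assign")
  terms <- attr(stats::terms(~ age * sex * treatment), "term.labels")
  ss <- stats::setNames(numeric(length(terms)), terms)
  df_term <- stats::setNames(integer(length(terms)), terms)
  for (k in seq_along(terms)) {
    cols <- asgn != k
    ss[k] <- rss_of(X[, cols, drop = FALSE], yy) - rss_full
    df_term[k] <- sum(asgn == k)
  }
  sigma2 <- if (df_res > 0) rss_full / df_res else NA_real_
  f_term <- p_term <- stats::setNames(rep(NA_real_, length(terms)), terms)
  if (df_res > 0 && is.finite(sigma2) && sigma2 > 0) {
    f_term <- (ss / df_term) / sigma2
    p_term <- stats::pf(f_term, df_term, df_res, lower.tail = FALSE)
  } else if (df_res == 0) flags <- c(flags, "zero_residual_df")
  else flags <- c(flags, "degenerate")

  # overall model F vs intercept-only
  ss_model <- rss_of(X[, 1, drop = FALSE], yy) - rss_full
  df_model <- ncol(X) - 1L
  f_overall <- p_overall <- NA_real_
  if (df_res > 0 && is.finite(sigma2) && sigma2 > 0) {
    f_overall <- (ss_model / df_model) / sigma2
    p_overall <- stats::pf(f_overall, df_model, df_res, lower.tail = FALSE)
  } else if (df_res > 0 && sigma2 == 0) flags <- unique(c(flags, "degenerate"))

  # joint interaction Wald F: full vs main-effects-only
  main_cols <- asgn %in% 0:3
  rss_main <- rss_of(X[, main_cols, drop = FALSE], yy)
  df_int <- sum(!main_cols)
  f_int <- p_int <- NA_real_
  if (df_res > 0 && is.finite(sigma2) && sigma2 > 0) {
    f_int <- ((rss_main - rss_full) / df_int) / sigma2
    p_int <- stats::pf(f_int, df_int, df_res, lower.tail = FALSE)
  }

  # least-squares means: predictions on the full 2x2x2 grid, averaged
  grid <- expand.grid(age = AGE_LEVELS, sex = SEX_LEVELS,
                      treatment = TRT_LEVELS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$run_order <- seq_len(8); grid$run_id <- paste0("cell", 1:8)
  Xg <- factorial_model_matrix(grid)
  cell_means <- drop(Xg %*% fit$coefficients)
  names(cell_means) <- paste0(grid$age, grid$sex, grid$treatment)
  lsm <- list(
    age = tapply(cell_means, grid$age, mean),
    sex = tapply(cell_means, grid$sex, mean),
    treatment = tapply(cell_means, grid$treatment, mean))
  fc <- c(age = unname(lsm$age["ed17"] - lsm$age["ed12"]),
          sex = unname(lsm$sex["F"] - lsm$sex["M"]),
          treatment = unname(lsm$treatment["E"] - lsm$treatment["C"]))

  # exact Wald t for each level contrast (LS-mean difference)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  contrast_test <- function(factor_name, hi, lo) {
    Lhi <- colMeans(Xg[grid[[factor_name]] == hi, , drop = FALSE])
    Llo <- colMeans(Xg[grid[[factor_name]] == lo, , drop = FALSE])
    L <- Lhi - Llo
    est <- sum(L * fit$coefficients)
    if (df_res > 0 && is.finite(sigma2) && sigma2 > 0) {
      se <- sqrt(sigma2 * drop(t(L) %*% xtx_inv %*% L))
      tval <- est / se
      c(estimate = est, t = tval,
        p = 2 * stats::pt(-abs(tval), df_res))
    } else c(estimate = est, t = NA_real_, p = NA_real_)
  }
  tests <- rbind(age = contrast_test("age", "ed17", "ed12"),
                 sex = contrast_test("sex", "F", "M"),
                 treatment = contrast_test("treatment", "E", "C"))

  out$coefficients <- fit$coefficients
  out$grand_mean <- unname(fit$coefficients[1])
  out$cell_means <- cell_means
  out$ls_means <- lsm
  out$fold_changes <- fc
  out$contrast_tests <- tests
  out$ss <- ss; out$df_term <- df_term
  out$f_term <- f_term; out$p_term <- p_term
  out$sigma2 <- sigma2; out$df_residual <- df_res
  out$f_overall <- f_overall; out$p_overall <- p_overall
  out$f_interaction <- f_int; out$p_interaction <- p_int
  out$flags <- flags
  out
}

#' Significance tier for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' FDR adjustment of p-values
#'
#' Benjamini-Hochberg step-up by default; Benjamini-Yekutieli available for
#' dependence-robust control.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NA allowed and preserved).
#' @param method `"BH"` or `"BY"`.
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(pvalues, method = c("BH", "BY")) {
  method <- match.arg(method)
  finite <- pvalues[!is.na(pvalues)]
  if (any(finite < 0 | finite > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Pairwise t-test between two group means
#'
#' With a supplied (model-residual) pooled variance, `t = (mean(a) - mean(b))
#' / sqrt(s2 (1/na + 1/nb))` on the supplied df; otherwise the classical
#' pooled-variance two-sample t. Two-sided p; significance tiers at
#' 0.05/0.01/0.001.
#'
#' @param a,b Numeric vectors of group values.
#' @param pooled_variance Optional residual variance to use.
#' @param df Degrees of freedom accompanying `pooled_variance`.
#' @return list with `t`, `df`, `p`, `tier`, `flag`.
#' @export
pairwise_t <- function(a, b, pooled_variance = NULL, df = NULL) {
  na <- length(a); nb <- length(b)
  if (is.null(pooled_variance)) {
    if (na < 2 || nb < 2)
      stop("both groups need >= 2 values unless pooled_variance is supplied")
    pooled_variance <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    df <- na + nb - 2
  }
  if (is.null(df)) stop("df must accompany a supplied pooled_variance")
  diff <- mean(a) - mean(b)
  if (pooled_variance == 0) {
    if (diff == 0)
      return(list(t = 0, df = df, p = 1, tier = "", flag = ""))
    return(list(t = sign(diff) * Inf, df = df, p = NA_real_,
                tier = NA_character_, flag = "degenerate"))
  }
  tval <- diff / sqrt(pooled_variance * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tval), df)
  list(t = tval, df = df, p = p, tier = significance_tier(p), flag = "")
}

#' Factorial analysis of every peptide
#'
#' Applies [fit_factorial()] per peptide (complete cases per peptide),
#' adjusts the overall-F p-values across peptides by Benjamini-Hochberg,
#' and reports level-contrast fold changes with tiered pairwise tests using
#' each model's residual variance. Per-peptide failures are flagged, not
#' fatal.
#'
#' @param mat [intensity_matrix()] (normalized, filtered, replicates
#'   collapsed).
#' @param design Design table aligned with the matrix columns.
#' @param fdr_method Passed to [adjust_fdr()].
#' @return list with `table` (one row per peptide: FDR-adjusted overall p,
#'   fold changes and tiers, interaction p) and `fits` (the underlying
#'   `factorial_fit` objects).
#' @export
analyze_all <- function(mat, design, fdr_method = "BH") {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- mat$values
  design <- design[order(design$run_order), , drop = FALSE]
  fits <- lapply(seq_len(nrow(v)), function(p) fit_factorial(v[p, ], design))
  names(fits) <- rownames(v)
  get <- function(f, field, sub = NULL) {
    x <- f[[field]]
    if (is.null(x)) return(NA_real_)
    if (!is.null(sub)) x <- x[sub]
    unname(x)
  }
  p_overall <- vapply(fits, get, 0, "p_overall")
  tab <- data.frame(
    peptide = rownames(v),
    n_obs = vapply(fits, get, 0, "n_obs"),
    p_overall = p_overall,
    fdr_p = adjust_fdr(p_overall, fdr_method),
    fc_age = vapply(fits, function(f) get(f, "fold_changes", "age"), 0),
    fc_sex = vapply(fits, function(f) get(f, "fold_changes", "sex"), 0),
    fc_treatment = vapply(fits, function(f) get(f, "fold_changes", "treatment"), 0),
    p_age = vapply(fits, function(f)
      if (is.null(f$contrast_tests)) NA_real_ else f$contrast_tests["age", "p"], 0),
    p_sex = vapply(fits, function(f)
      if (is.null(f$contrast_tests)) NA_real_ else f$contrast_tests["sex", "p"], 0),
    p_treatment = vapply(fits, function(f)
      if (is.null(f$contrast_tests)) NA_real_ else f$contrast_tests["treatment", "p"], 0),
    p_interaction = vapply(fits, get, 0, "p_interaction"),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  tab$tier_age <- significance_tier(tab$p_age)
  tab$tier_sex <- significance_tier(tab$p_sex)
  tab$tier_treatment <- significance_tier(tab$p_treatment)
  tab$tier_interaction <- significance_tier(tab$p_interaction)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
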