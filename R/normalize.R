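#' @title Two-step run normalization
#' @description The normalization the study applied to its exported ion
#'   intensities: log2 transform, linear calibration of every run against a
#'   median reference run, then per-peptide locally-weighted (lowess)
#'   regression against run order to remove injection-sequence drift;
#'   followed by the minimum-matching missingness filter and collapsing of
#'   technical replicates. Missing values are never imputed; every step
#'   consumes and preserves the explicit missingness mask.
#' @name normalization
NULL

#' Log2-transform a raw intensity matrix
#'
#' @param mat [intensity_matrix()] in state `raw` with strictly positive
#'   observed intensities.
#' @return The matrix with `log2` applied elementwise (missing preserved).
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (has_state(mat, "log2")) stop("matrix is already log2-transformed")
  bad <- which(!is.na(mat$values) & mat$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive observed intensity at: ",
         paste(sprintf("[%s, %s]", rownames(mat$values)[bad[, 1]],
                       colnames(mat$values)[bad[, 2]]), collapse = ", "))
  mat$values <- log2(mat$values)
  advance_state(mat, "log2")
}

#' Flag low-intensity outlier runs
#'
#' Flags runs whose median observed log2 intensity lies more than `k`
#' MAD-scaled robust deviations below the cohort median of run medians.
#' Advisory only: removal is the caller's decision (see [drop_runs()]).
#'
#' @param mat [intensity_matrix()] in state `log2`.
#' @param k Robust-deviation multiplier; `Inf` flags nothing.
#' @return data.frame with columns `run_id`, `run_median`, `reason` (possibly
#'   zero rows).
#' @export
flag_outlier_runs <- function(mat, k = 3) {
  require_state(mat, "log2")
  if (ncol(mat$values) < 4L)
    stop("need at least 4 runs for robust outlier statistics")
  med_run <- apply(mat$values, 2L, stats::median, na.rm = TRUE)
  centre <- stats::median(med_run)
  if (is.infinite(k))
    return(data.frame(run_id = character(0), run_median = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  scale <- stats::mad(med_run)
  flag <- med_run < centre - k * scale
  data.frame(run_id = colnames(mat$values)[flag],
             run_median = unname(med_run[flag]),
             reason = sprintf("median intensity %.3f more than %g MAD below cohort median %.3f",
                              med_run[flag], k, centre),
             stringsAsFactors = FALSE)
}

#' Build the median reference run
#'
#' The reference (median) run holds, for every peptide matched in strictly
#' more than `min_match_frac` of all runs, the median of its observed log2
#' intensities.
#'
#' @param mat [intensity_matrix()] in state `log2`.
#' @param min_match_frac Strict lower bound on the observed-run fraction.
#' @return list with `values` (named numeric vector) and `peptides`.
#' @export
build_reference_run <- function(mat, min_match_frac = 0.5) {
  require_state(mat, "log2")
  frac <- rowMeans(!is.na(mat$values))
  keep <- frac > min_match_frac
  if (!any(keep)) stop("no peptide is matched in more than ",
                       round(100 * min_match_frac), "% of runs")
  vals <- apply(mat$values[keep, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  list(values = vals, peptides = names(vals))
}

#' Calibrate every run to the reference run
#'
#' For each run, ordinary least squares fits `observed = a + b * reference`
#' over the peptides shared with the reference run, then maps the run onto the
#' reference scale by `(v - a) / b`. After calibration, re-fitting a run
#' against the reference gives slope 1 and intercept 0 (to numerical
#' precision), and the transform is idempotent.
#'
#' @param mat [intensity_matrix()] in state `log2`.
#' @param ref Reference run from [build_reference_run()].
#' @return list with `matrix` (state `calibrated`) and `fits` (data.frame of
#'   per-run slope, intercept, shared-peptide count).
#' @export
calibrate_to_reference <- function(mat, ref) {
  require_state(mat, "log2")
  v <- mat$values
  runs <- colnames(v)
  fits <- data.frame(run_id = runs, slope = NA_real_, intercept = NA_real_,
                     n_shared = NA_integer_, stringsAsFactors = FALSE)
  for (j in seq_along(runs)) {
    y <- v[ref$peptides, j]
    ok <- !is.na(y)
    if (sum(ok) < 3L)
      stop("run ", runs[j], " shares only ", sum(ok),
           " peptides with the reference run (need >= 3)")
    x <- ref$values[ok]; yo <- y[ok]
    b <- stats::cov(yo, x) / stats::var(x)
    a <- mean(yo) - b * mean(x)
    if (!is.finite(b) || abs(b) < 1e-6)
      stop("degenerate calibration for run ", runs[j], " (slope ", b, ")")
    v[, j] <- (v[, j] - a) / b
    fits$slope[j] <- b; fits$intercept[j] <- a; fits$n_shared[j] <- sum(ok)
  }
  out <- intensity_matrix(v, state = mat$state)
  list(matrix = advance_state(out, "calibrated"), fits = fits)
}

# Tricube-weighted local linear fit of y on x evaluated at each x, using the
# nearest ceiling(span * n) observed points per evaluation point, no
# robustness iterations. Returns fitted values aligned with x.
lowess_fit <- function(x, y, span) {
  n <- length(x)
  k <- min(n, max(2L, ceiling(span * n)))
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    dmax <- sort(d, partial = k)[k]
    w <- numeric(n)
    if (dmax > 0) {
      u <- d / dmax
      w[u < 1] <- (1 - u[u < 1]^3)^3
    } else w[d == 0] <- 1
    sw <- sum(w)
    xw <- sum(w * x) / sw
    yw <- sum(w * y) / sw
    sxx <- sum(w * (x - xw)^2)
    if (sxx > 1e-12) {
      beta <- sum(w * (x - xw) * (y - yw)) / sxx
      fitted[i] <- yw + beta * (x[i] - xw)
    } else fitted[i] <- yw
  }
  fitted
}

#' Remove run-order drift per peptide
#'
#' Fits a locally-weighted linear regression (lowess: tricube weights over the
#' nearest `ceiling(span * n_obs)` observed runs per evaluation point, local
#' degree 1, no robustness iterations) of each peptide's calibrated intensity
#' on run order, and subtracts it. The mean of the fitted trend is added back
#' so each peptide keeps its native intensity level: the per-peptide mean of
#' observed values is preserved exactly.
#'
#' @param mat [intensity_matrix()] in state `calibrated`.
#' @param design Design table supplying the run order of each column.
#' @param span Fraction of a peptide's observed runs entering each local fit.
#' @return list with `matrix` (state `drift_corrected`), `fits` (per peptide:
#'   fitted drift value at each observed run, pre-correction mean), and
#'   `uncorrected` (peptides with fewer than 4 observations, left unchanged).
#' @export
correct_run_order <- function(mat, design, span = 0.5) {
  require_state(mat, "calibrated")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  design <- design[order(design$run_order), , drop = FALSE]
  v <- mat$values[, design$run_id, drop = FALSE]
  ord <- design$run_order
  fits <- vector("list", nrow(v))
  names(fits) <- rownames(v)
  uncorrected <- character(0)
  for (p in seq_len(nrow(v))) {
    obs <- which(!is.na(v[p, ]))
    if (length(obs) < 4L) {
      uncorrected <- c(uncorrected, rownames(v)[p])
      next
    }
    x <- ord[obs]; y <- v[p, obs]
    f <- lowess_fit(x, y, span)
    pre_mean <- mean(y)
    v[p, obs] <- y - f + mean(f)
    fits[[p]] <- list(run_order = x, fitted = f, pre_mean = pre_mean,
                      span = span)
  }
  out <- intensity_matrix(v, state = mat$state)
  list(matrix = advance_state(out, "drift_corrected"),
       fits = fits, uncorrected = uncorrected)
}

#' Minimum-matching missingness filter
#'
#' Retains a peptide only if every experimental group is missing it in at
#' most `max_missing_per_group` runs ("max one missing file per group").
#' Row order is preserved.
#'
#' @param mat [intensity_matrix()].
#' @param groups Named character vector run id -> group label (see
#'   [group_labels()]); must cover all matrix columns.
#' @param max_missing_per_group Allowed missing runs per group.
#' @return The filtered matrix (state `filtered`).
#' @export
filter_min_matching <- function(mat, groups, max_missing_per_group = 1) {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- mat$values
  uncovered <- setdiff(colnames(v), names(groups))
  if (length(uncovered))
    stop("groups do not cover run(s): ", paste(uncovered, collapse = ", "))
  g <- groups[colnames(v)]
  keep <- apply(v, 1L, function(row) {
    miss <- tapply(is.na(row), g, sum)
    all(miss <= max_missing_per_group)
  })
  out <- intensity_matrix(v[keep, , drop = FALSE], state = mat$state)
  advance_state(out, "filtered")
}

#' Collapse technical replicates of the reference sample
#'
#' Replaces all reference runs by a single pseudo-run holding, per peptide,
#' the median over the observed replicate values (present iff at least one
#' replicate observed it). The pseudo-run takes the column position and run
#' order of the first replicate and the reference sample id as its run id.
#'
#' @param mat [intensity_matrix()].
#' @param design Design table aligned with the matrix columns.
#' @return list with `matrix` (state `collapsed`) and `design` (reference
#'   rows collapsed to one, run order re-numbered contiguously).
#' @export
collapse_technical_replicates <- function(mat, design) {
  stopifnot(inherits(mat, "intensity_matrix"))
  design <- design[order(design$run_order), , drop = FALSE]
  refs <- design$run_id[design$is_reference]
  if (length(refs) < 1L) stop("design contains no reference runs")
  v <- mat$values[, design$run_id, drop = FALSE]
  med <- apply(v[, refs, drop = FALSE], 1L, function(r)
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE))
  first <- which(design$run_id == refs[1])
  pseudo_id <- design$sample_id[first]
  keep <- !(design$run_id %in% refs)
  design2 <- design[keep | design$run_id == refs[1], , drop = FALSE]
  i <- which(design2$run_id == refs[1])
  design2$run_id[i] <- pseudo_id
  v2 <- v[, design2$run_id[design2$run_id != pseudo_id], drop = FALSE]
  # reinsert the pseudo-run at the first replicate's position
  pos <- i
  left <- if (pos > 1) v2[, seq_len(pos - 1L), drop = FALSE] else NULL
  right <- if (pos <= ncol(v2)) v2[, pos:ncol(v2), drop = FALSE] else NULL
  v2 <- cbind(left, matrix(med, ncol = 1, dimnames = list(rownames(v), pseudo_id)),
              right)
  design2$run_order <- seq_len(nrow(design2))
  out <- intensity_matrix(v2, state = mat$state)
  list(matrix = advance_state(out, "collapsed"), design = design2)
}
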