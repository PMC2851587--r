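#' @title Synthetic study generator
#' @description Generates run designs and log2 intensity matrices with the
#'   statistical structure the analysis pipeline assumes: a randomized block
#'   design with an interspersed technical-replicate reference sample, sparse
#'   group effects dominated by age, smooth run-order drift, per-run
#'   multiplicative/additive scale distortion, and intensity-dependent (MNAR)
#'   missingness. Ground truth is returned alongside for recovery tests.
#' @name synthetic_data
NULL

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults are the `study2010` preset: the dimensions and design of the quail
#' diencephalon study (8 groups of sizes 5,5,5,4,4,4,4,5 = 36 samples, 5
#' blocks, 6 technical-replicate reference runs, 204 peptides). Effect sizes,
#' drift and missingness parameters are stated model assumptions (the source
#' study does not quantify them); see the package vignette for the rationale.
#'
#' @param group_sizes Named integer vector of samples per group
#'   (names = the 8 group labels).
#' @param n_blocks Number of randomized blocks.
#' @param reference_replicates Number of technical-replicate runs of the
#'   reference sample; the default `n_blocks + 1` places one at the start of
#'   each block plus one final run.
#' @param reference_group Group label whose factor levels the reference
#'   sample carries.
#' @param n_peptides Number of peptide ions.
#' @param baseline_mean,baseline_sd Per-peptide baseline log2 intensity
#'   distribution.
#' @param age_frac,age_mean,age_sd Fraction of peptides with an age effect
#'   and the Normal distribution of its size, expressed as the ed17 - ed12
#'   level-mean difference (log2 units).
#' @param sex_frac,sex_mean,sex_sd Ditto for sex (F - M).
#' @param trt_frac,trt_mean,trt_sd Ditto for treatment (E - C).
#' @param inter_frac,inter_sd Fraction of peptides with an age-by-treatment
#'   interaction and the sd of its (zero-mean) size.
#' @param drift_amplitude,drift_shape,drift_period Run-order drift:
#'   amplitude in log2 units and shape (`"linear"`, `"sinusoidal"` or
#'   `"spline"`); a sinusoidal drift completes `drift_period` periods over
#'   the run sequence (values < 1 give slow drift whose period exceeds the
#'   sequence); spline drift is a smooth random curve.
#' @param run_slope_sd,run_intercept_sd Per-run multiplicative (applied to the
#'   baseline-centered signal) and additive scale distortion sds.
#' @param noise_sd Residual Normal noise sd (log2 units).
#' @param miss_midpoint,miss_steepness,miss_floor Logistic
#'   missing-not-at-random model: an entry with value x is deleted with
#'   probability `floor + (1 - floor) * plogis(-(x - midpoint) * steepness)`
#'   (lower intensity, more likely missing; steepness 0 gives MCAR at rate
#'   `floor + (1 - floor)/2`).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = c(ed12MC = 5, ed12FC = 5, ed12ME = 5,
                                       ed12FE = 4, ed17MC = 4, ed17FC = 4,
                                       ed17ME = 4, ed17FE = 5),
                       n_blocks = 5,
                       reference_replicates = n_blocks + 1,
                       reference_group = "ed17FC",
                       n_peptides = 204,
                       baseline_mean = 16, baseline_sd = 2.5,
                       age_frac = 0.25, age_mean = 1.5, age_sd = 1.0,
                       sex_frac = 0.05, sex_mean = 0, sex_sd = 0.6,
                       trt_frac = 0.05, trt_mean = 0, trt_sd = 0.5,
                       inter_frac = 0.05, inter_sd = 0.5,
                       drift_amplitude = 0.5, drift_shape = "sinusoidal",
                       drift_period = 1,
                       run_slope_sd = 0.05, run_intercept_sd = 0.5,
                       noise_sd = 0.3,
                       miss_midpoint = 10, miss_steepness = 1.5,
                       miss_floor = 0.01,
                       seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_blocks = n_blocks,
              reference_replicates = reference_replicates,
              reference_group = reference_group, n_peptides = n_peptides,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              age_frac = age_frac, age_mean = age_mean, age_sd = age_sd,
              sex_frac = sex_frac, sex_mean = sex_mean, sex_sd = sex_sd,
              trt_frac = trt_frac, trt_mean = trt_mean, trt_sd = trt_sd,
              inter_frac = inter_frac, inter_sd = inter_sd,
              drift_amplitude = drift_amplitude, drift_shape = drift_shape,
              drift_period = drift_period,
              run_slope_sd = run_slope_sd, run_intercept_sd = run_intercept_sd,
              noise_sd = noise_sd, miss_midpoint = miss_midpoint,
              miss_steepness = miss_steepness, miss_floor = miss_floor,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$group_sizes < 1)) stop("group sizes must be >= 1")
  if (is.null(names(cfg$group_sizes)) || any(!nzchar(names(cfg$group_sizes))))
    stop("group_sizes must be named by group label")
  fr <- c(cfg$age_frac, cfg$sex_frac, cfg$trt_frac, cfg$inter_frac)
  if (any(fr < 0 | fr > 1)) stop("effect fractions must lie in [0, 1]")
  sds <- c(cfg$baseline_sd, cfg$age_sd, cfg$sex_sd, cfg$trt_sd, cfg$inter_sd,
           cfg$run_slope_sd, cfg$run_intercept_sd, cfg$noise_sd)
  if (any(sds < 0)) stop("all sds must be >= 0")
  if (!cfg$drift_shape %in% c("linear", "sinusoidal", "spline"))
    stop("unknown drift shape: ", cfg$drift_shape)
  if (cfg$miss_floor < 0 || cfg$miss_floor > 1)
    stop("missingness floor must lie in [0, 1]")
  invisible(cfg)
}

# Split group label like "ed12MC" back into its factor levels.
split_group_label <- function(label) {
  age <- substr(label, 1, 4)
  sex <- substr(label, 5, 5)
  trt <- substr(label, 6, 6)
  if (!age %in% AGE_LEVELS || !sex %in% SEX_LEVELS || !trt %in% TRT_LEVELS)
    stop("cannot parse group label: ", label)
  list(age = age, sex = sex, treatment = trt)
}

#' Generate a randomized block design
#'
#' Samples are randomized to blocks (as evenly as possible) and shuffled
#' within block; the technical-replicate reference sample is placed at the
#' start of each block and as the final run. Fully determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A validated design table (see [validate_design()]).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- sum(config$group_sizes)
  if (n_samples < config$n_blocks)
    stop("group sizes (", n_samples, " samples) cannot be distributed over ",
         config$n_blocks, " blocks")
  n_ref <- config$reference_replicates
  if (n_ref > config$n_blocks + 1L)
    stop("at most n_blocks + 1 reference replicates can be placed")
  local_seed(config$seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    ids <- sprintf("S%02d", seq_len(n_samples))
    shuffle <- sample.int(n_samples)
    groups <- groups[shuffle]
    # block sizes as even as possible
    sizes <- diff(round(seq(0, n_samples, length.out = config$n_blocks + 1L)))
    block_of <- rep(seq_len(config$n_blocks), sizes)
    rows <- list()
    ref <- if (n_ref > 0) split_group_label(config$reference_group) else NULL
    ref_used <- 0L
    idx <- 1L
    for (b in seq_len(config$n_blocks)) {
      # reference opens each block while replicates remain; when n_ref ==
      # n_blocks + 1 the last replicate is reserved for the final run
      if (ref_used < min(n_ref, config$n_blocks)) {
        ref_used <- ref_used + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = paste0("REF", letters[ref_used]), sample_id = "REF",
          age = ref$age, sex = ref$sex, treatment = ref$treatment,
          block = paste0("B", b), is_reference = TRUE,
          stringsAsFactors = FALSE)
      }
      in_block <- which(block_of == b)
      for (i in in_block) {
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = ids[idx], sample_id = ids[idx],
          age = split_group_label(groups[i])$age,
          sex = split_group_label(groups[i])$sex,
          treatment = split_group_label(groups[i])$treatment,
          block = paste0("B", b), is_reference = FALSE,
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    if (ref_used < n_ref) {
      ref_used <- ref_used + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = paste0("REF", letters[ref_used]), sample_id = "REF",
        age = ref$age, sex = ref$sex, treatment = ref$treatment,
        block = paste0("B", config$n_blocks), is_reference = TRUE,
        stringsAsFactors = FALSE)
    }
    design <- do.call(rbind, rows)
    design <- cbind(run_order = seq_len(nrow(design)), design)
    validate_design(design)
    design
  })
}

drift_values <- function(config, run_order) {
  n <- max(run_order)
  x <- (run_order - 1) / max(1, n - 1)
  amp <- config$drift_amplitude
  switch(config$drift_shape,
         linear = amp * (2 * x - 1),
         sinusoidal = amp * sin(2 * pi * config$drift_period * x),
         spline = {
           k <- 5
           knots <- seq(0, 1, length.out = k)
           coef <- stats::rnorm(k, 0, amp)
           stats::spline(knots, coef, xout = x)$y
         })
}

#' Simulate a log2 intensity matrix with ground truth
#'
#' Each entry is `baseline_p + group effects + slope_r * (baseline_p -
#' mean(baseline)) + intercept_r + drift(run_order_r) + Normal(0, noise_sd)`;
#' entries are then deleted with the logistic MNAR probability evaluated at
#' the realized value. Effects are half-coded (+effect/2 at the high level,
#' -effect/2 at the low level) so an effect equals the level-mean difference
#' (ed17 - ed12, F - M, E - C).
#'
#' @param config A [sim_config()].
#' @param design A design table, typically from [generate_design()].
#' @param catalog Optional [load_catalog()] result; when given, peptide ids
#'   are taken from catalog sequences (made unique) before falling back to
#'   generated ids.
#' @return list with `matrix` (an [intensity_matrix()] in state `log2`) and
#'   `truth` (per-peptide true effects, per-run scale and drift, baseline,
#'   and the realized missingness probabilities).
#' @export
simulate_intensities <- function(config, design, catalog = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_design(design)
  design <- design[order(design$run_order), , drop = FALSE]
  n_pep <- config$n_peptides
  n_run <- nrow(design)
  pep_ids <- sprintf("pep_%03d", seq_len(n_pep))
  if (!is.null(catalog)) {
    k <- min(nrow(catalog), n_pep)
    pep_ids[seq_len(k)] <- make.unique(catalog$sequence[seq_len(k)])
  }
  local_seed(config$seed + 1L, {
    baseline <- stats::rnorm(n_pep, config$baseline_mean, config$baseline_sd)
    draw_eff <- function(frac, mean, sd) {
      has <- stats::runif(n_pep) < frac
      ifelse(has, stats::rnorm(n_pep, mean, sd), 0)
    }
    eff_age <- draw_eff(config$age_frac, config$age_mean, config$age_sd)
    eff_sex <- draw_eff(config$sex_frac, config$sex_mean, config$sex_sd)
    eff_trt <- draw_eff(config$trt_frac, config$trt_mean, config$trt_sd)
    eff_at  <- draw_eff(config$inter_frac, 0, config$inter_sd)
    slope <- stats::rnorm(n_run, 0, config$run_slope_sd)
    intercept <- stats::rnorm(n_run, 0, config$run_intercept_sd)
    drift <- drift_values(config, design$run_order)
    s_age <- ifelse(design$age == "ed17", 0.5, -0.5)
    s_sex <- ifelse(design$sex == "F", 0.5, -0.5)
    s_trt <- ifelse(design$treatment == "E", 0.5, -0.5)
    base_c <- baseline - mean(baseline)
    vals <- matrix(0, n_pep, n_run, dimnames = list(pep_ids, design$run_id))
    for (r in seq_len(n_run)) {
      signal <- baseline +
        eff_age * s_age[r] + eff_sex * s_sex[r] + eff_trt * s_trt[r] +
        eff_at * (2 * s_age[r]) * s_trt[r] +
        slope[r] * base_c + intercept[r] + drift[r]
      vals[, r] <- signal
    }
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(n_pep * n_run, 0, config$noise_sd),
                            n_pep, n_run)
    p_miss <- config$miss_floor + (1 - config$miss_floor) *
      stats::plogis(-(vals - config$miss_midpoint) * config$miss_steepness)
    miss <- matrix(stats::runif(n_pep * n_run), n_pep, n_run) < p_miss
    vals[miss] <- NA_real_
    truth <- list(
      effects = data.frame(peptide = pep_ids, age = eff_age, sex = eff_sex,
                           treatment = eff_trt, age_treatment = eff_at,
                           stringsAsFactors = FALSE),
      run_effects = data.frame(run_id = design$run_id, slope = slope,
                               intercept = intercept, drift = drift,
                               stringsAsFactors = FALSE),
      baseline = stats::setNames(baseline, pep_ids),
      miss_prob = p_miss)
    list(matrix = intensity_matrix(vals, state = "log2"), truth = truth)
  })
}
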