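# Shared fixture builders; everything is generated in code.

GROUPS8 <- c("ed12MC", "ed12FC", "ed12ME", "ed12FE",
             "ed17MC", "ed17FC", "ed17ME", "ed17FE")

# Factorial design with given cell sizes (named by the 8 group labels or an
# unnamed vector of 8), no reference runs.
make_cell_design <- function(sizes) {
  if (is.null(names(sizes))) names(sizes) <- GROUPS8
  rows <- do.call(rbind, lapply(names(sizes), function(g) {
    k <- sizes[[g]]
    data.frame(age = substr(g, 1, 4), sex = substr(g, 5, 5),
               treatment = substr(g, 6, 6),
               stringsAsFactors = FALSE)[rep(1, k), , drop = FALSE]
  }))
  n <- nrow(rows)
  cbind(run_order = seq_len(n), run_id = paste0("r", seq_len(n)),
        sample_id = paste0("s", seq_len(n)), rows,
        block = "B1", is_reference = FALSE, stringsAsFactors = FALSE)
}

# Sequential-run design for drift-correction tests (one group, no refs).
make_seq_design <- function(n) {
  data.frame(run_order = seq_len(n), run_id = paste0("r", seq_len(n)),
             sample_id = paste0("s", seq_len(n)),
             age = rep(c("ed12", "ed17"), length.out = n),
             sex = rep(c("M", "F"), length.out = n),
             treatment = rep(c("C", "E"), length.out = n),
             block = "B1", is_reference = FALSE, stringsAsFactors = FALSE)
}

im <- function(values, state = "log2", peptides = NULL, runs = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- peptides %||% paste0("p", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- runs %||% paste0("r", seq_len(ncol(values)))
  intensity_matrix(values, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sim_config with all systematic structure off (no effects, drift, run scale
# distortion or missingness) unless overridden.
quiet_config <- function(...) {
  args <- list(...)
  base <- list(age_frac = 0, sex_frac = 0, trt_frac = 0, inter_frac = 0,
               drift_amplitude = 0, run_slope_sd = 0, run_intercept_sd = 0,
               noise_sd = 0, miss_floor = 0, miss_steepness = 1,
               miss_midpoint = -1e9)
  base[names(args)] <- args
  do.call(sim_config, base)
}

balanced8 <- function(n_per_cell) stats::setNames(rep(n_per_cell, 8), GROUPS8)
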