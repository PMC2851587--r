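#!/usr/bin/env Rscript
# Stage 2 — two-step normalization.
#
# Calibrates every run against the median reference run (linear regression,
# then inversion onto the reference scale), removes run-order drift with a
# per-peptide lowess (span 0.5), applies the minimum-matching filter (max one
# missing run per group) and collapses the technical replicates to their
# median pseudo-run.

suppressPackageStartupMessages(library(lfqpep))

design <- read_design("results/sim/design.tsv")
mat <- read_matrix("results/sim/matrix.tsv", design = design)
out <- "results/normalized"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

flags <- flag_outlier_runs(mat, k = 3)
if (nrow(flags)) {
  cat("flagged low-intensity runs:", paste(flags$run_id, collapse = ", "), "\n")
  dr <- drop_runs(mat, design, flags$run_id)
  mat <- dr$matrix; design <- dr$design
} else cat("no low-intensity outlier runs flagged\n")

ref <- build_reference_run(mat, min_match_frac = 0.5)
cat(sprintf("reference run built from %d peptides matched in > 50%% of runs\n",
            length(ref$peptides)))
cal <- calibrate_to_reference(mat, ref)
cat(sprintf("calibration slopes %.3f-%.3f, intercepts %.3f-%.3f\n",
            min(cal$fits$slope), max(cal$fits$slope),
            min(cal$fits$intercept), max(cal$fits$intercept)))

drift <- correct_run_order(cal$matrix, design, span = 0.5)
cat(sprintf("drift-corrected %d peptides (%d left uncorrected, < 4 obs)\n",
            nrow(drift$matrix$values) - length(drift$uncorrected),
            length(drift$uncorrected)))

filt <- filter_min_matching(drift$matrix, group_labels(design),
                            max_missing_per_group = 1)
cat(sprintf("minimum-matching filter: %d of %d peptides retained\n",
            nrow(filt$values), nrow(drift$matrix$values)))

col <- collapse_technical_replicates(filt, design)
cat(sprintf("collapsed %d reference replicates into one pseudo-run; %d runs remain\n",
            sum(design$is_reference), ncol(col$matrix$values)))

write_matrix(col$matrix, file.path(out, "matrix.tsv"))
write_design(col$design, file.path(out, "design.tsv"))
utils::write.table(cal$fits, file.path(out, "calibration.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("normalized matrix and design written to", paste0(out, "/\n"))
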