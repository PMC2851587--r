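#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Emits a randomized block design (8 groups = 2 ages x 2 sexes x 2 treatments,
# 36 samples over 5 blocks, 6 technical-replicate reference runs) and a
# 204-peptide x 42-run log2 intensity matrix with run-order drift, per-run
# scale distortion and intensity-dependent missingness, plus the ground truth
# used by later stages to judge recovery.

suppressPackageStartupMessages(library(lfqpep))

seed <- 20100318L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
design <- generate_design(cfg)
sim <- simulate_intensities(cfg, design, catalog = load_catalog())

write_design(design, file.path(out, "design.tsv"))
write_matrix(sim$matrix, file.path(out, "matrix.tsv"))
utils::write.table(sim$truth$effects, file.path(out, "truth_effects.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$run_effects, file.path(out, "truth_runs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

g <- table(group_labels(design)[design$run_id[!design$is_reference]])
cat(sprintf("simulated %d peptides x %d runs (%.1f%% missing)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            100 * mean(is.na(sim$matrix$values))))
cat(sprintf("%d unique samples, %d reference replicates; group sizes: %s\n",
            length(unique(design$sample_id)), sum(design$is_reference),
            paste(names(g), g, sep = "=", collapse = " ")))
cat(sprintf("%d/%d peptides carry a true age effect; outputs in %s/\n",
            sum(sim$truth$effects$age != 0), nrow(sim$truth$effects), out))
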