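#!/usr/bin/env Rscript
# Stage 3 — multivariate class structure.
#
# Group-median (Xclass - Xtot) transform with two-way complete-linkage
# clustering, PCA with 7-fold cross-validated Q2 and T2/DModX diagnostics,
# and a PLS-DA on the four age x treatment classes with VIP scores and
# jackknife confidence intervals.

suppressPackageStartupMessages(library(lfqpep))

design <- read_design("results/normalized/design.tsv")
mat <- read_matrix("results/normalized/matrix.tsv", design = design)
out <- "results/multivariate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gm <- group_median_transform(mat, group_labels(design))
gm_complete <- gm[stats::complete.cases(gm), , drop = FALSE]
dend <- hierarchical_cluster(gm_complete, "both")
writeLines(c(dendrogram_newick(dend$rows), dendrogram_newick(dend$columns)),
           file.path(out, "dendrograms.nwk"))
utils::write.table(data.frame(peptide = rownames(gm), gm, check.names = FALSE),
                   file.path(out, "group_medians.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

complete <- !apply(mat$values, 1L, anyNA)
X <- t(mat$values[complete, , drop = FALSE])
cat(sprintf("multivariate stage uses %d complete-case peptides over %d runs\n",
            sum(complete), nrow(X)))

pca <- fit_pca(X, n_components = 2, cv_folds = 7)
cat(sprintf("PCA: R2X(cum) = %.3f, Q2(cum) = %.3f over 2 components\n",
            pca$model$r2x_cum[2], pca$model$q2_cum[2]))
cat(sprintf("     %d/%d runs outside the 95%% Hotelling T2 limit\n",
            sum(pca$diagnostics$t2 > pca$diagnostics$t2_limit), nrow(X)))

classes <- paste0(design$age, design$treatment)[match(rownames(X), design$run_id)]
plsda <- fit_plsda(X, classes, n_components = 3, cv_folds = 7)
cat(sprintf("PLS-DA (age x treatment, %d classes): R2Y(cum) = %.3f, Q2(cum) = %.3f\n",
            length(unique(classes)), plsda$r2y_cum[3], plsda$q2_cum[3]))

vip <- jackknife_vip(X, classes, n_components = 3)
vip <- vip[order(-vip$vip), ]
utils::write.table(vip, file.path(out, "vip.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d peptides have VIP > 1; top 5:\n",
            sum(vip$vip > 1), nrow(vip)))
print(utils::head(vip[, c("variable", "vip", "lower", "upper")], 5),
      row.names = FALSE)

scores <- data.frame(run_id = rownames(X), class = classes,
                     pca$model$scores[, 1:2],
                     plsda$scores, check.names = FALSE)
names(scores)[3:7] <- c("pca_t1", "pca_t2", "pls_t1", "pls_t2", "pls_t3")
utils::write.table(scores, file.path(out, "scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("scores, VIP table, group medians and dendrograms written to",
    paste0(out, "/\n"))
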