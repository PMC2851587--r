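#' Pipeline configuration
#'
#' Validated bundle of stage parameters for [run_pipeline()]. Unknown
#' parameters are rejected.
#'
#' @param span Lowess span for run-order drift correction.
#' @param min_match_frac Strict matched-run fraction for the reference run.
#' @param max_missing_per_group Minimum-matching filter threshold.
#' @param n_components_pca,n_components_plsda Components per model.
#' @param cv_folds Cross-validation folds for Q2.
#' @param fdr_level FDR threshold used when reporting significant peptides.
#' @param outlier_k MAD multiplier for low-intensity run flagging.
#' @param drop_runs_pre Run ids removed before normalization (the
#'   degradation-outlier drop point).
#' @param drop_flagged_outliers Whether runs flagged by the low-intensity
#'   criterion are removed after calibration inspection (the second drop
#'   point).
#' @param plsda_classes Factor combination defining PLS-DA classes:
#'   `"age_treatment"` (default, 4 classes) or `"group"` (all 8).
#' @param jackknife Whether to compute jackknife confidence intervals for
#'   VIP.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(span = 0.5, min_match_frac = 0.5,
                            max_missing_per_group = 1,
                            n_components_pca = 2, n_components_plsda = 3,
                            cv_folds = 7, fdr_level = 0.05, outlier_k = 3,
                            drop_runs_pre = character(0),
                            drop_flagged_outliers = TRUE,
                            plsda_classes = "age_treatment",
                            jackknife = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$span <= 0 || cfg$span > 1) stop("span must lie in (0, 1]")
  if (cfg$min_match_frac < 0 || cfg$min_match_frac >= 1)
    stop("min_match_frac must lie in [0, 1)")
  if (cfg$max_missing_per_group < 0) stop("max_missing_per_group must be >= 0")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (!cfg$plsda_classes %in% c("age_treatment", "group"))
    stop("unknown plsda_classes: ", cfg$plsda_classes)
  structure(cfg, class = "pipeline_config")
}

write_tsv_table <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) format_cell(x))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis flow on a design/matrix pair: log2 state
#' check, pre-normalization outlier removal, linear calibration to the
#' median reference run, per-peptide run-order drift correction,
#' low-intensity outlier flagging (and optional removal), minimum-matching
#' filter, technical-replicate collapsing, then the group-median transform
#' with two-way complete-linkage clustering, PCA, PLS-DA with VIP (and
#' jackknife intervals), and the per-peptide factorial analysis. All
#' artifacts are written to `out_dir` with a JSON manifest recording
#' parameters, seed and per-stage record counts; identical config and inputs
#' give byte-identical outputs.
#'
#' The multivariate stages use the complete-case peptides (no missing entry
#' after collapsing); missing values are never imputed.
#'
#' @param config [pipeline_config()].
#' @param design Design table.
#' @param mat [intensity_matrix()] in state `log2` (or `raw`, in which case
#'   it is log2-transformed first).
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return Invisible list: final matrix and design, calibration fits, outlier
#'   flags, group medians, dendrograms, PCA and PLS-DA models, VIP table,
#'   differential table, and the manifest.
#' @export
run_pipeline <- function(config, design, mat, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "validate"
  report <- list()
  counts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  run_stage("validate", {
    validate_design(design)
    if (!setequal(colnames(mat$values), design$run_id))
      stop("matrix columns do not match design run ids")
  })
  if (!has_state(mat, "log2")) mat <- run_stage("log2", log2_transform(mat))
  counts$input <- dim(mat$values)

  if (length(config$drop_runs_pre)) {
    dr <- run_stage("drop_pre", drop_runs(mat, design, config$drop_runs_pre))
    mat <- dr$matrix; design <- dr$design
  }
  counts$after_pre_drop <- ncol(mat$values)

  flags <- run_stage("flag_outliers",
                     flag_outlier_runs(mat, k = config$outlier_k))
  if (config$drop_flagged_outliers && nrow(flags)) {
    dr <- run_stage("drop_flagged", drop_runs(mat, design, flags$run_id))
    mat <- dr$matrix; design <- dr$design
  }
  counts$after_outlier_drop <- ncol(mat$values)

  ref <- run_stage("reference_run",
                   build_reference_run(mat, config$min_match_frac))
  cal <- run_stage("calibrate", calibrate_to_reference(mat, ref))
  mat <- cal$matrix
  drift <- run_stage("drift_correction",
                     correct_run_order(mat, design, config$span))
  mat <- drift$matrix
  mat <- run_stage("filter", filter_min_matching(mat, group_labels(design),
                                                 config$max_missing_per_group))
  counts$peptides_after_filter <- nrow(mat$values)
  col <- run_stage("collapse", collapse_technical_replicates(mat, design))
  mat <- col$matrix; design <- col$design
  counts$runs_after_collapse <- ncol(mat$values)

  groups <- group_labels(design)
  gm <- run_stage("group_medians", group_median_transform(mat, groups))
  gm_complete <- gm[stats::complete.cases(gm), , drop = FALSE]
  dend <- run_stage("clustering", hierarchical_cluster(gm_complete, "both"))

  # multivariate stages on complete-case peptides, observations = runs
  complete <- !apply(mat$values, 1L, anyNA)
  X <- t(mat$values[complete, , drop = FALSE])
  counts$peptides_multivariate <- sum(complete)
  pca <- run_stage("pca", fit_pca(X, config$n_components_pca,
                                  cv_folds = config$cv_folds))
  classes <- if (config$plsda_classes == "age_treatment")
    paste0(design$age, design$treatment)[match(rownames(X), design$run_id)]
  else unname(groups[rownames(X)])
  plsda <- run_stage("plsda", fit_plsda(X, classes, config$n_components_plsda,
                                        cv_folds = config$cv_folds))
  vip <- run_stage("vip", compute_vip(plsda))
  vip_tab <- data.frame(variable = names(vip), vip = unname(vip),
                        stringsAsFactors = FALSE)
  if (config$jackknife) {
    vip_tab <- run_stage("jackknife",
                         jackknife_vip(X, classes, config$n_components_plsda,
                                       cv_folds = config$cv_folds))
  }
  diff <- run_stage("differential", analyze_all(mat, design))

  manifest <- list(
    package = "lfqpep",
    version = as.character(utils::packageVersion("lfqpep")),
    parameters = unclass(config),
    counts = counts,
    outlier_flags = flags$run_id,
    seed = config$seed)

  report <- list(matrix = mat, design = design, calibration = cal$fits,
                 outlier_flags = flags, group_medians = gm,
                 dendrograms = dend, pca = pca$model,
                 pca_diagnostics = pca$diagnostics, plsda = plsda,
                 vip = vip_tab, differential = diff$table,
                 factorial_fits = diff$fits, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(mat, file.path(out_dir, "matrix_normalized.tsv"))
    write_design(design, file.path(out_dir, "design_final.tsv"))
    write_tsv_table(cal$fits, file.path(out_dir, "calibration.tsv"))
    write_tsv_table(as.data.frame(cbind(peptide = rownames(gm),
                                        as.data.frame(gm))),
                    file.path(out_dir, "group_medians.tsv"))
    writeLines(c(dendrogram_newick(dend$rows), dendrogram_newick(dend$columns)),
               file.path(out_dir, "dendrograms.nwk"))
    sc <- as.data.frame(pca$model$scores)
    names(sc) <- paste0("t", seq_len(ncol(sc)))
    write_tsv_table(cbind(run_id = rownames(X), sc),
                    file.path(out_dir, "pca_scores.tsv"))
    sp <- as.data.frame(plsda$scores)
    names(sp) <- paste0("t", seq_len(ncol(sp)))
    write_tsv_table(cbind(run_id = rownames(X), class = classes, sp),
                    file.path(out_dir, "plsda_scores.tsv"))
    write_tsv_table(vip_tab, file.path(out_dir, "vip.tsv"))
    write_tsv_table(diff$table, file.path(out_dir, "differential.tsv"))
    model_summary <- list(
      pca = list(r2x = pca$model$r2x, r2x_cum = pca$model$r2x_cum,
                 q2 = pca$model$q2, q2_cum = pca$model$q2_cum,
                 eigenvalues = pca$model$eigenvalues,
                 t2_limit = pca$diagnostics$t2_limit,
                 dcrit = pca$diagnostics$dcrit),
      plsda = list(r2x_cum = plsda$r2x_cum, r2y = plsda$r2y,
                   r2y_cum = plsda$r2y_cum, q2 = plsda$q2,
                   q2_cum = plsda$q2_cum, eigenvalues = plsda$eigenvalues))
    jsonlite::write_json(model_summary, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
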