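#' @title Design table and intensity matrix I/O
#' @description The shared data model all pipeline stages consume: a run
#'   design (run order, sample id, the three two-level factors, block,
#'   reference-replicate flag) and a peptides-by-runs matrix of log2 ion
#'   intensities with explicit missingness (NA, serialized as a blank cell).
#' @name dataio
NULL

AGE_LEVELS <- c("ed12", "ed17")
SEX_LEVELS <- c("M", "F")
TRT_LEVELS <- c("C", "E")

#' Validate a design table
#'
#' Checks the invariants of the run design: `run_order` is a permutation of
#' 1..N, run ids are unique, every non-reference sample id appears exactly
#' once, all reference runs share one sample id, and factor levels are drawn
#' from ed12/ed17, M/F, C/E.
#'
#' @param design data.frame with columns `run_order`, `run_id`, `sample_id`,
#'   `age`, `sex`, `treatment`, `block`, `is_reference`.
#' @return `design`, invisibly, with rows ordered by `run_order`.
#' @export
validate_design <- function(design) {
  required <- c("run_order", "run_id", "sample_id", "age", "sex",
                "treatment", "block", "is_reference")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols))
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(design) == 0L) stop("no runs in design")
  errs <- character(0)
  n <- nrow(design)
  if (!setequal(design$run_order, seq_len(n)) || anyDuplicated(design$run_order))
    errs <- c(errs, "run_order is not a permutation of 1..N")
  if (anyDuplicated(design$run_id))
    errs <- c(errs, paste("duplicate run_id:",
                          paste(unique(design$run_id[duplicated(design$run_id)]),
                                collapse = ", ")))
  bad_age <- setdiff(unique(design$age), AGE_LEVELS)
  if (length(bad_age)) errs <- c(errs, paste("unknown age level:", paste(bad_age, collapse = ", ")))
  bad_sex <- setdiff(unique(design$sex), SEX_LEVELS)
  if (length(bad_sex)) errs <- c(errs, paste("unknown sex level:", paste(bad_sex, collapse = ", ")))
  bad_trt <- setdiff(unique(design$treatment), TRT_LEVELS)
  if (length(bad_trt)) errs <- c(errs, paste("unknown treatment level:", paste(bad_trt, collapse = ", ")))
  nonref <- design$sample_id[!design$is_reference]
  if (anyDuplicated(nonref))
    errs <- c(errs, paste("non-reference sample_id appears more than once:",
                          paste(unique(nonref[duplicated(nonref)]), collapse = ", ")))
  refid <- unique(design$sample_id[design$is_reference])
  if (length(refid) > 1L)
    errs <- c(errs, "reference runs do not share a single sample_id")
  if (length(refid) == 1L && refid %in% nonref)
    errs <- c(errs, "reference sample_id also appears as a non-reference sample")
  if (length(errs)) stop("invalid design:\n  ", paste(errs, collapse = "\n  "))
  invisible(design[order(design$run_order), , drop = FALSE])
}

#' Read / write a design table
#'
#' TSV dialect: tab-separated, header row, LF line endings, decimal point.
#'
#' @param path File path.
#' @return `read_design` returns a validated design data.frame ordered by run
#'   order.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "")
  if (nrow(df) == 0L) stop("no runs in design file ", path)
  df$run_order <- as.integer(df$run_order)
  df$is_reference <- toupper(df$is_reference) %in% c("TRUE", "T", "1", "YES")
  validate_design(df)
  df[order(df$run_order), , drop = FALSE]
}

#' @rdname read_design
#' @param design Design data.frame.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  df <- design[order(design$run_order), , drop = FALSE]
  df$is_reference <- ifelse(df$is_reference, "TRUE", "FALSE")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Construct an intensity matrix container
#'
#' A peptides-by-runs grid of (log2) ion intensities with explicit missing
#' entries (NA) and a record of which pipeline transforms have been applied.
#'
#' @param values Numeric matrix, peptides in rows (rownames = peptide ids),
#'   runs in columns (colnames = run ids). NA marks a missing (undetected)
#'   entry.
#' @param state Character vector of applied-state flags; grows monotonically
#'   along the pipeline (`raw` -> `log2` -> `calibrated` -> `drift_corrected`
#'   -> `filtered` -> `collapsed`).
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, state = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry peptide rownames and run colnames")
  structure(list(values = values, state = state), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d peptides x %d runs, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  cat("state:", paste(x$state, collapse = " -> "), "\n")
  invisible(x)
}

has_state <- function(mat, flag) flag %in% mat$state

advance_state <- function(mat, flag) {
  if (!has_state(mat, flag)) mat$state <- c(mat$state, flag)
  mat
}

require_state <- function(mat, flag) {
  if (!has_state(mat, flag))
    stop("matrix must be in state '", flag, "' (current: ",
         paste(mat$state, collapse = " -> "), ")")
  invisible(mat)
}

# Fixed-point serialization keeps write -> read -> write byte-identical.
format_cell <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))

#' Read / write an intensity matrix
#'
#' TSV dialect: first column `peptide`, remaining columns run ids; blank cell
#' means missing; values serialized in fixed notation with 6 decimals so that
#' write-read-write round-trips are byte-identical.
#'
#' @param path File path.
#' @param design Optional design table; when given, matrix columns are
#'   cross-validated against (and reordered to) the design's run ids.
#' @param state State flags to stamp on the returned matrix (the TSV itself
#'   carries no state).
#' @return `read_matrix` returns an [intensity_matrix()].
#' @export
read_matrix <- function(path, design = NULL, state = "log2") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = "", quote = "")
  if (names(df)[1] != "peptide") stop("first column must be 'peptide'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$peptide
  if (!is.null(design)) {
    orphan <- setdiff(colnames(vals), design$run_id)
    absent <- setdiff(design$run_id, colnames(vals))
    if (length(orphan) || length(absent))
      stop("matrix/design mismatch;",
           if (length(orphan)) paste0(" runs only in matrix: ", paste(orphan, collapse = ", ")),
           if (length(absent)) paste0(" runs only in design: ", paste(absent, collapse = ", ")))
    vals <- vals[, design$run_id[order(design$run_order)], drop = FALSE]
  }
  intensity_matrix(vals, state = state)
}

#' @rdname read_matrix
#' @param mat [intensity_matrix()] to serialize.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "intensity_matrix"))
  v <- mat$values
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("peptide", colnames(v)), collapse = "\t"), con, sep = "\n")
  body <- apply(v, 1L, function(row) paste(format_cell(row), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Drop runs from a matrix/design pair
#'
#' Removes outlier runs (by run id) from both the matrix columns and the
#' design rows; run order of the remaining runs keeps its relative ranking
#' (re-numbered contiguously so the design stays valid).
#'
#' @param mat [intensity_matrix()].
#' @param design Design table.
#' @param run_ids Character vector of run ids to remove (may be empty).
#' @return list with elements `matrix`, `design`, `dropped` (the ids),
#'   `n_runs` and `n_samples` remaining (samples counted as unique sample
#'   ids).
#' @export
drop_runs <- function(mat, design, run_ids) {
  stopifnot(inherits(mat, "intensity_matrix"))
  unknown <- setdiff(run_ids, design$run_id)
  if (length(unknown))
    stop("unknown run id(s): ", paste(unknown, collapse = ", "))
  keep <- !(design$run_id %in% run_ids)
  design2 <- design[keep, , drop = FALSE]
  design2 <- design2[order(design2$run_order), , drop = FALSE]
  design2$run_order <- seq_len(nrow(design2))
  vals <- mat$values[, design2$run_id, drop = FALSE]
  out <- intensity_matrix(vals, state = mat$state)
  list(matrix = out, design = design2, dropped = run_ids,
       n_runs = nrow(design2), n_samples = length(unique(design2$sample_id)))
}

#' Derive the eight group labels from a design
#'
#' Deterministic mapping run -> group label, concatenating age, sex and
#' treatment (e.g. `ed12MC`, `ed17FE`).
#'
#' @param design Design table.
#' @return Named character vector (names = run ids).
#' @export
group_labels <- function(design) {
  g <- paste0(design$age, design$sex, design$treatment)
  names(g) <- design$run_id
  g
}
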