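#' Parse a compact modification string
#'
#' Modifications are encoded as `kind@site` tokens joined by `;`, e.g.
#' `"phospho@6"`, `"phospho@6;phospho@10"`, `"amide@cterm"`,
#' `"pyroglu@nterm"`. Empty string means no modifications.
#'
#' @param text Single character string (possibly empty or NA).
#' @return List of [mod_spec()] objects.
#' @export
parse_mods <- function(text) {
  if (is.na(text) || !nzchar(text)) return(list())
  tokens <- strsplit(text, ";", fixed = TRUE)[[1]]
  lapply(tokens, function(tok) {
    parts <- strsplit(trimws(tok), "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed modification token: ", sQuote(tok))
    site <- if (parts[2] %in% c("nterm", "cterm")) parts[2] else {
      s <- suppressWarnings(as.integer(parts[2]))
      if (is.na(s)) stop("malformed modification site in ", sQuote(tok))
      s
    }
    mod_spec(parts[1], site)
  })
}

#' Load a peptide catalog
#'
#' Reads a tab-separated peptide catalog (one row per identified peptide ion:
#' precursor protein, peptide name, sequence, printed MH+ where available,
#' modifications, and whether the peptide was matched well enough across runs
#' to be analyzable by the multivariate/differential stages). The bundled
#' fixture transcribes the study's identification table for the embryonic
#' quail diencephalon.
#'
#' @param path Path to a catalog TSV. Defaults to the bundled fixture.
#' @return A data.frame of class `peptide_catalog` with columns `precursor`,
#'   `peptide`, `sequence`, `mh_printed` (numeric, NA where not printed),
#'   `modifications` (compact string, see [parse_mods()]), `comment`,
#'   `analyzable` (logical), and `mh_theoretical` (computed monoisotopic MH+
#'   including modifications).
#' @export
load_catalog <- function(path = system.file("extdata", "peptide_catalog.tsv",
                                            package = "lfqpep")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, quote = "")
  required <- c("precursor", "peptide", "sequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    df$mh_printed <- numeric(0); df$analyzable <- logical(0)
    df$mh_theoretical <- numeric(0)
    class(df) <- c("peptide_catalog", "data.frame")
    return(df)
  }
  errors <- character(0)
  mh_theo <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      mods <- parse_mods(if ("modifications" %in% names(df)) df$modifications[i] else "")
      monoisotopic_mh(df$sequence[i], mods)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("row ", i, ": ", conditionMessage(res)))
    } else mh_theo[i] <- res
  }
  if (length(errors))
    stop("malformed catalog row(s):\n", paste(errors, collapse = "\n"))
  df$mh_printed <- suppressWarnings(as.numeric(df$mh_printed))
  df$analyzable <- tolower(trimws(df$analyzable)) %in% c("yes", "true", "1")
  df$mh_theoretical <- mh_theo
  class(df) <- c("peptide_catalog", "data.frame")
  df
}
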