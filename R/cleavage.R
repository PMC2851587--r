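#' Predict prohormone convertase cleavage sites
#'
#' Scans a precursor sequence for the classical basic-residue processing
#' motifs of neuropeptide precursors: every dibasic pair drawn from
#' {KK, KR, RK, RR} (cleavage after the pair) and every RxnR motif — an
#' arginine, exactly n intervening residues with n in {2, 4, 6}, then a second
#' arginine (cleavage after the final R). Overlapping matches are all
#' reported. The motif pair is returned in `matched_text` so callers can
#' restrict to a subset (e.g. KR/RR only).
#'
#' @param precursor Amino-acid string (20 standard residues).
#' @return A data.frame with columns `position` (0-based index of the residue
#'   AFTER which cleavage occurs, i.e. cleavage between `position` and
#'   `position + 1` in 0-based coordinates), `motif` (`"dibasic"` or
#'   `"RxnR"`), and `matched_text`; sorted by position, then motif.
#' @examples
#' find_cleavage_sites("AAKRSGKLSFLEDEMRRAA")
#' @export
find_cleavage_sites <- function(precursor) {
  chars <- check_sequence(precursor)
  n <- length(chars)
  pos <- integer(0); motif <- character(0); text <- character(0)
  basic <- c("K", "R")
  # dibasic pairs: cleavage after the second residue of the pair
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      if (chars[i] %in% basic && chars[i + 1L] %in% basic) {
        pos <- c(pos, i + 1L)  # 1-based index of second residue = 0-based "after" position
        motif <- c(motif, "dibasic")
        text <- c(text, paste0(chars[i], chars[i + 1L]))
      }
    }
  }
  # RxnR, n in {2,4,6}: cleavage after the final R
  for (gap in c(2L, 4L, 6L)) {
    span <- gap + 2L
    if (n < span) next
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      if (chars[i] == "R" && chars[j] == "R") {
        pos <- c(pos, j)
        motif <- c(motif, "RxnR")
        text <- c(text, paste(chars[i:j], collapse = ""))
      }
    }
  }
  # 0-based position of the residue after which cleavage occurs:
  # residue index j (1-based) -> 0-based index j - 1.
  out <- data.frame(position = pos - 1L, motif = motif,
                    matched_text = text, stringsAsFactors = FALSE)
  out[order(out$position, out$motif), , drop = FALSE]
}

#' Enumerate candidate peptides between cleavage sites
#'
#' Returns the maximal substrings of a precursor lying between consecutive
#' dibasic cleavage motifs (and the sequence termini), excluding the
#' basic-residue motif characters themselves. Coordinates are 0-based,
#' half-open.
#'
#' @param precursor Amino-acid string.
#' @return data.frame with columns `sequence`, `start`, `end` (0-based,
#'   half-open); empty candidates (adjacent motifs) are dropped.
#' @examples
#' enumerate_candidate_peptides("AAKRSGKLSFLEDEMRRAA")
#' @export
enumerate_candidate_peptides <- function(precursor) {
  chars <- check_sequence(precursor)
  n <- length(chars)
  sites <- find_cleavage_sites(precursor)
  sites <- sites[sites$motif == "dibasic", , drop = FALSE]
  # mask motif residues (the dibasic pair occupies 0-based [position-1, position])
  is_motif <- rep(FALSE, n)
  for (p in sites$position) is_motif[(p:(p + 1L))] <- TRUE  # 1-based indices p, p+1
  runs <- rle(is_motif)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !runs$values
  out <- data.frame(sequence = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  for (k in which(keep)) {
    s <- starts[k]; e <- ends[k]
    out <- rbind(out, data.frame(
      sequence = paste(chars[s:e], collapse = ""),
      start = s - 1L, end = e, stringsAsFactors = FALSE))
  }
  out
}
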