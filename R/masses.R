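#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues, i.e. the
#' mass each residue contributes inside a peptide chain (free amino-acid mass
#' minus one water). Constants `MASS_WATER` and `MASS_PROTON` complete the
#' MH+ computation.
#'
#' @format Named numeric vector, one entry per one-letter residue code.
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname RESIDUE_MASSES
#' @export
MASS_WATER <- 18.010565

#' @rdname RESIDUE_MASSES
#' @export
MASS_PROTON <- 1.007276

# Canonical (Unimod) monoisotopic mass deltas for the modifications the
# identification searches allowed.
MOD_DELTAS <- c(
  phospho    = 79.96633,   # STY phosphorylation, +HPO3
  amide      = -0.98402,   # C-terminal amidation, -OH +NH2
  pyroglu    = -17.02655,  # pyroglutamate from N-terminal Q, -NH3
  oxidation  = 15.99491,   # methionine oxidation, +O
  acetyl     = 42.01057    # N-terminal acetylation, +C2H2O
)

#' Modification specification
#'
#' @param kind One of `"phospho"`, `"amide"`, `"pyroglu"`, `"oxidation"`,
#'   `"acetyl"`.
#' @param site 1-based residue index, or `"nterm"` / `"cterm"` for terminal
#'   modifications (amidation is C-terminal, pyroglutamate and acetylation
#'   N-terminal).
#'
#' @return A `mod_spec` list with elements `kind`, `site` and `mass_delta`
#'   (Da, the canonical monoisotopic delta for `kind`).
#' @export
mod_spec <- function(kind, site = NULL) {
  kind <- match.arg(kind, names(MOD_DELTAS))
  if (is.null(site)) {
    site <- switch(kind, amide = "cterm", pyroglu = "nterm",
                   acetyl = "nterm",
                   stop("modification '", kind, "' needs an explicit site"))
  }
  structure(list(kind = kind, site = site,
                 mass_delta = unname(MOD_DELTAS[kind])),
            class = "mod_spec")
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(RESIDUE_MASSES))
  if (length(bad))
    stop("invalid residue character(s) in sequence: ",
         paste(sQuote(bad), collapse = ", "))
  chars
}

#' Monoisotopic MH+ of a peptide
#'
#' Sum of residue monoisotopic masses plus one water plus one proton, plus the
#' mass deltas of any modifications. Returned at full precision; round for
#' display against low-resolution observed masses.
#'
#' @param sequence Uppercase one-letter amino-acid string (20 standard
#'   residues).
#' @param mods List of [mod_spec()] objects (may be empty).
#'
#' @return Monoisotopic MH+ in Da.
#' @examples
#' monoisotopic_mh("YGGFMRF")            # Met-enkephalin-Arg-Phe, 877.40
#' monoisotopic_mh("HKTDSFVGLM", list(mod_spec("amide")))
#' @export
monoisotopic_mh <- function(sequence, mods = list()) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  delta <- 0
  for (m in mods) {
    if (!inherits(m, "mod_spec")) stop("mods must be a list of mod_spec objects")
    if (is.numeric(m$site) && (m$site < 1 || m$site > n))
      stop("modification site ", m$site, " out of range for sequence of length ", n)
    delta <- delta + m$mass_delta
  }
  sum(RESIDUE_MASSES[chars]) + MASS_WATER + MASS_PROTON + delta
}
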