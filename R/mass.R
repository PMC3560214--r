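#' Average residue masses for the 20 canonical amino acids
#'
#' Average (isotope-abundance-weighted) monomer residue masses in Da, i.e.
#' the mass contributed by one residue inside a peptide chain (free amino
#' acid minus one water). Values follow the standard average atomic weights
#' used by common protein mass calculators. Pinned here so theoretical
#' molecular weights are stable across releases.
#'
#' @format Named numeric vector, one element per one-letter residue code.
#' @keywords internal
AA_AVERAGE_RESIDUE_MASS_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' Average mass of one water molecule (Da)
#' @keywords internal
WATER_AVERAGE_MASS_DA <- 18.01524

#' Theoretical molecular weight of a protein or peptide sequence
#'
#' Computes the average-mass molecular weight of an unmodified polypeptide:
#' the sum of average residue masses plus one water, reported in kDa.
#' Average (not monoisotopic) masses are used because the downstream use
#' case is concordance with SDS-PAGE migration, which reflects average mass.
#'
#' Sequences containing the ambiguity code `X` have no defined mass; callers
#' that tolerate `X` (e.g. gel-band analysis) must exclude such entries
#' before calling.
#'
#' @param sequence Character vector of amino-acid sequences (uppercase,
#'   canonical 20-letter alphabet).
#' @return Numeric vector of molecular weights in kDa.
#' @examples
#' compute_theoretical_mw("G")    # 0.0750672 kDa
#' compute_theoretical_mw("GG")   # 0.1321191 kDa
#' @export
compute_theoretical_mw <- function(sequence) {
  if (length(sequence) == 0L) return(numeric(0))
  stopifnot(is.character(sequence))
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) {
      stop("empty sequence: molecular weight is undefined", call. = FALSE)
    }
    letters <- strsplit(s, "", fixed = TRUE)[[1L]]
    unknown <- setdiff(unique(letters), names(AA_AVERAGE_RESIDUE_MASS_DA))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown amino-acid letter(s) in sequence: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    (sum(AA_AVERAGE_RESIDUE_MASS_DA[letters]) + WATER_AVERAGE_MASS_DA) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical molecular weights for a FASTA-derived protein table
#'
#' Vectorized convenience wrapper used by the gel-band stage: proteins whose
#' sequence contains `X` get `NA` with a warning (they are excluded from
#' molecular-weight concordance analysis) instead of an error.
#'
#' @param proteins Data frame with columns `accession` and `sequence`.
#' @return Data frame with columns `accession` and `theoretical_mw_kda`.
#' @export
theoretical_mw_table <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  has_x <- grepl("X", proteins$sequence, fixed = TRUE)
  if (any(has_x)) {
    warning(sprintf(
      "%d sequence(s) contain 'X'; molecular weight undefined, set to NA: %s",
      sum(has_x), paste(utils::head(proteins$accession[has_x], 5), collapse = ", ")))
  }
  mw <- rep(NA_real_, nrow(proteins))
  mw[!has_x] <- compute_theoretical_mw(proteins$sequence[!has_x])
  data.frame(accession = proteins$accession, theoretical_mw_kda = mw,
             stringsAsFactors = FALSE)
}
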