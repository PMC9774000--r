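#' Amino-acid code utilities and tau core constants
#'
#' @name aa-utils
#' @keywords internal
NULL

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
AA1 <- stats::setNames(names(AA3), AA3)

#' Normalize an amino-acid code to the 1-letter alphabet
#'
#' Accepts 1-letter or 3-letter codes in any case. Unknown codes error.
#'
#' @param code character vector of residue codes.
#' @return character vector of upper-case 1-letter codes.
#' @export
aa_one_letter <- function(code) {
  code <- toupper(trimws(code))
  out <- ifelse(nchar(code) == 3, unname(AA1[code]), code)
  bad <- is.na(out) | !out %in% names(AA3)
  if (any(bad)) {
    stop("unknown residue type(s): ", paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' The tau(297-391) core fragment sequence in 2N4R numbering
#'
#' The 95-residue proteolysis-resistant core of tau paired helical filaments
#' (often called dGAE), numbered 297-391 in the full-length 2N4R isoform.
#' All residue numbers in this package follow that frame, so labels such as
#' V309, C322 or E391 carry their conventional meaning.
#'
#' @return a tibble with columns `residue_number` and `residue_type`
#'   (1-letter code).
#' @export
#' @examples
#' tau_core_sequence()
tau_core_sequence <- function() {
  seq1 <- paste0(
    "IKHVPGGGSV", "QIVYKPVDLS", "KVTSKCGSLG", "NIHHKPGGGQ", "VEVKSEKLDF",
    "KDRVQSKIGS", "LDNITHVPGG", "GNKKIETHKL", "TFRENAKAKT", "DHGAE"
  )
  tibble::tibble(
    residue_number = 297:391,
    residue_type = strsplit(seq1, "")[[1]]
  )
}

#' Residue segments covered by the rigid-core assignment
#'
#' The solid-state NMR assignment of tau(297-391)+DTT filaments covers the
#' contiguous segments V309-S324, G326-I328, E338-E342, R349-N359 and
#' E372-H374, plus one PGGG stretch that could not be placed uniquely
#' (see [ambiguous_pggg_residues()]).
#'
#' @return tibble with columns `start`, `end` (inclusive, 2N4R numbering).
#' @export
assignment_segments <- function() {
  tibble::tibble(
    start = c(309L, 326L, 338L, 349L, 372L),
    end   = c(324L, 328L, 342L, 359L, 374L)
  )
}

#' Residues of the ambiguously assigned PGGG repeats
#'
#' tau(297-391) contains three PGGG motifs; the assigned one is either
#' P332-G335 or P364-G367 (or both). These residue numbers are subject to the
#' `ambiguous_policy` of [match_residues()].
#'
#' @return integer vector of 2N4R residue numbers.
#' @export
ambiguous_pggg_residues <- function() {
  c(332:335, 364:367)
}
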