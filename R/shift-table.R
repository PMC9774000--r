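#' Build and validate a chemical-shift table
#'
#' A shift table is the package's common currency for per-residue, per-atom
#' chemical shifts in ppm: one row per `(residue_number, atom_name)` with the
#' residue type as a 1-letter code. Both the observed (NMR) side and every
#' calculated (predicted-from-structure) side of the strain metrics are shift
#' tables; `source_label` records which side a table is (e.g. `"NMR"` or
#' `"Cal:7mkg"`).
#'
#' Validation enforces the physical sanity bounds (carbon shifts in
#' \[0, 250\] ppm, nitrogen in \[0, 200\] ppm, all values finite), uniqueness of
#' `(residue_number, atom_name)`, and the chemistry constraint that glycine has
#' no C-beta. The atom names `"C"` and `"CO"` are dialect synonyms for the
#' carbonyl carbon and are normalized to `"C"`.
#'
#' @param x a data frame with columns `residue_number`, `residue_type`,
#'   `atom_name`, `shift`.
#' @param source_label character scalar naming the provenance of the table.
#' @return a `shift_tbl`: a tibble with the four columns above (residue types
#'   1-letter, atoms normalized) and attribute `source_label`.
#' @export
#' @examples
#' shift_tbl(data.frame(
#'   residue_number = c(309L, 309L), residue_type = "V",
#'   atom_name = c("CA", "CB"), shift = c(61.2, 34.0)
#' ), source_label = "NMR")
shift_tbl <- function(x, source_label = "unspecified") {
  need <- c("residue_number", "residue_type", "atom_name", "shift")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("shift table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x)[need]
  out$residue_number <- as.integer(out$residue_number)
  out$residue_type <- aa_one_letter(out$residue_type)
  out$atom_name <- normalize_atom_name(out$atom_name)
  out$shift <- as.double(out$shift)
  validate_shift_tbl(out)
  out <- dplyr::arrange(out, .data$residue_number, .data$atom_name)
  attr(out, "source_label") <- source_label
  class(out) <- c("shift_tbl", class(out))
  out
}

normalize_atom_name <- function(atom_name) {
  atom_name <- toupper(trimws(atom_name))
  ifelse(atom_name == "CO", "C", atom_name)
}

validate_shift_tbl <- function(x) {
  if (any(!is.finite(x$shift))) {
    stop("non-finite chemical shift values present", call. = FALSE)
  }
  carbon <- grepl("^C", x$atom_name)
  nitrogen <- grepl("^N", x$atom_name)
  bad_c <- carbon & (x$shift < 0 | x$shift > 250)
  bad_n <- nitrogen & (x$shift < 0 | x$shift > 200)
  if (any(bad_c | bad_n)) {
    i <- which(bad_c | bad_n)[1]
    stop(sprintf("shift %g ppm for atom %s of residue %d outside sanity bounds",
                 x$shift[i], x$atom_name[i], x$residue_number[i]), call. = FALSE)
  }
  dup <- duplicated(x[c("residue_number", "atom_name")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (residue, atom) entry: residue %d atom %s",
                 x$residue_number[i], x$atom_name[i]), call. = FALSE)
  }
  gly_cb <- x$residue_type == "G" & x$atom_name == "CB"
  if (any(gly_cb)) {
    stop(sprintf("glycine residue %d carries a CB shift",
                 x$residue_number[which(gly_cb)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.shift_tbl <- function(x, ...) {
  cat(sprintf("<shift_tbl> %s: %d shifts, %d residues\n",
              source_label(x), nrow(x), dplyr::n_distinct(x$residue_number)))
  NextMethod()
}

#' Source label of a table
#'
#' @param x a `shift_tbl`, `torsion_tbl` or `secondary_shift_tbl`.
#' @return character scalar.
#' @export
source_label <- function(x) {
  attr(x, "source_label") %||% "unspecified"
}

# keep the class and attributes through dplyr verbs used internally
restore_tbl_class <- function(out, template, cls) {
  attr(out, "source_label") <- attr(template, "source_label")
  if (!inherits(out, cls)) class(out) <- c(cls, class(out))
  out
}
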