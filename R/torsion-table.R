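#' Normalize angles to the (-180, 180] degree convention
#'
#' The package reports all torsions in degrees on (-180, 180], with the trans
#' conformation mapped to +180 so that equality comparisons are unambiguous.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped into (-180, 180].
#' @export
#' @examples
#' normalize_angle(c(185, -180, 540))  # -175, 180, 180
normalize_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Minimal circular difference between two angles
#'
#' @param a,b angles in degrees.
#' @return absolute difference on the circle, in \[0, 180\].
#' @keywords internal
circular_abs_diff <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

#' Build and validate a backbone torsion table
#'
#' One row per residue with phi/psi in degrees, normalized to (-180, 180].
#' Torsion tables sit on both sides of the dihedral strain metric: the NMR
#' side from shift-derived predictions (TALOS-N tables), the calculated side
#' from structure geometry via [compute_torsions()].
#'
#' @param x data frame with columns `residue_number`, `residue_type`, `phi`,
#'   `psi`, and optionally `classification`.
#' @param source_label provenance string.
#' @return a `torsion_tbl` tibble.
#' @export
torsion_tbl <- function(x, source_label = "unspecified") {
  need <- c("residue_number", "residue_type", "phi", "psi")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("torsion table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c(need, "classification"), names(x))
  out <- tibble::as_tibble(x)[keep]
  out$residue_number <- as.integer(out$residue_number)
  out$residue_type <- aa_one_letter(out$residue_type)
  if (any(!is.finite(out$phi)) || any(!is.finite(out$psi))) {
    stop("non-finite torsion angles present", call. = FALSE)
  }
  out$phi <- normalize_angle(as.double(out$phi))
  out$psi <- normalize_angle(as.double(out$psi))
  if (anyDuplicated(out$residue_number)) {
    stop("duplicate residue_number in torsion table: ",
         out$residue_number[duplicated(out$residue_number)][1], call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$residue_number)
  attr(out, "source_label") <- source_label
  class(out) <- c("torsion_tbl", class(out))
  out
}

#' @export
print.torsion_tbl <- function(x, ...) {
  cat(sprintf("<torsion_tbl> %s: %d residues\n", source_label(x), nrow(x)))
  NextMethod()
}
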