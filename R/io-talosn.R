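#' Read a TALOS-N torsion prediction table
#'
#' TALOS-N predicts backbone phi/psi from chemical shifts; its `pred.tab`
#' output is the NMR side of the dihedral strain metric. The file carries
#' `VARS`/`FORMAT` header lines followed by one row per residue with at least
#' RESID, RESNAME, PHI, PSI and a per-residue classification (CLASS).
#'
#' Only residues whose classification is in `accept` are kept (TALOS-N labels
#' confident predictions "Strong" and "Generous"; "Warn", "Dyn", "None" and
#' "Bad" rows are prediction warnings or dynamic residues). Dropped residues
#' are recorded in the `dropped` attribute and reported via a message. Angles
#' are normalized to (-180, 180].
#'
#' @param path prediction table path.
#' @param accept classifications to retain.
#' @param offset integer added to residue numbers.
#' @param source_label label for the resulting table.
#' @return a [torsion_tbl()] with attribute `dropped` (integer residue
#'   numbers of excluded rows).
#' @export
read_talosn_torsions <- function(path, accept = c("Strong", "Generous"),
                                 offset = 0L, source_label = "NMR") {
  lines <- readLines(path, warn = FALSE)
  vars_line <- grep("^\\s*VARS\\b", lines, value = TRUE)
  if (length(vars_line) == 0) {
    stop("no VARS header line in TALOS-N table: ", path, call. = FALSE)
  }
  vars <- toupper(strsplit(trimws(vars_line[1]), "\\s+")[[1]][-1])
  need <- c("RESID", "RESNAME", "PHI", "PSI")
  if (!all(need %in% vars)) {
    stop("TALOS-N table lacks PHI/PSI columns (found: ",
         paste(vars, collapse = " "), ")", call. = FALSE)
  }
  idx <- match(need, vars)
  class_idx <- match("CLASS", vars)
  body <- lines[!grepl("^\\s*(VARS|FORMAT|REMARK|DATA)\\b", lines)]
  body <- body[nzchar(trimws(body))]
  fields <- lapply(body, function(x) strsplit(trimws(x), "\\s+")[[1]])
  nf <- lengths(fields)
  if (any(nf < max(idx, class_idx, na.rm = TRUE))) {
    stop("malformed TALOS-N data row: ", body[which.min(nf)], call. = FALSE)
  }
  resid <- as.integer(vapply(fields, `[`, "", idx[1])) + as.integer(offset)
  resname <- vapply(fields, `[`, "", idx[2])
  phi <- as.numeric(vapply(fields, `[`, "", idx[3]))
  psi <- as.numeric(vapply(fields, `[`, "", idx[4]))
  cls <- if (is.na(class_idx)) rep("Strong", length(fields)) else
    vapply(fields, `[`, "", class_idx)
  # TALOS-N writes 9999.000 for angles it does not predict
  predicted <- is.finite(phi) & is.finite(psi) & abs(phi) <= 360 & abs(psi) <= 360
  keep <- cls %in% accept & predicted
  dropped <- resid[!keep]
  if (length(dropped) > 0) {
    message(sprintf("read_talosn_torsions: dropped %d residue(s) outside accepted classes {%s}: %s",
                    length(dropped), paste(accept, collapse = ", "),
                    paste(dropped, collapse = ", ")))
  }
  out <- torsion_tbl(
    tibble::tibble(
      residue_number = resid[keep],
      residue_type = resname[keep],
      phi = phi[keep],
      psi = psi[keep],
      classification = cls[keep]
    ),
    source_label = source_label
  )
  attr(out, "dropped") <- dropped
  out
}

#' Write a torsion table in TALOS-N prediction layout
#'
#' Emits the `VARS`/`FORMAT` header and per-residue rows so synthetic torsion
#' tables exercise the TALOS-N reader.
#'
#' @param torsions a [torsion_tbl()].
#' @param path output path.
#' @param classification classification written for every row (recycled).
#' @return `path`, invisibly.
#' @export
write_talosn_torsions <- function(torsions, path, classification = "Strong") {
  stopifnot(inherits(torsions, "torsion_tbl"))
  cls <- if ("classification" %in% names(torsions) &&
             !all(is.na(torsions$classification))) {
    torsions$classification
  } else {
    rep_len(classification, nrow(torsions))
  }
  writeLines(c(
    "REMARK synthetic torsion prediction table",
    "DATA SOURCE shiftstrain",
    "",
    "VARS   RESID RESNAME PHI PSI DPHI DPSI DIST S2 COUNT CS_COUNT CLASS",
    "FORMAT %4d %s %8.3f %8.3f %8.3f %8.3f %8.3f %5.3f %2d %2d %s",
    sprintf("%4d %s %8.3f %8.3f %8.3f %8.3f %8.3f %5.3f %2d %2d %s",
            torsions$residue_number, torsions$residue_type,
            torsions$phi, torsions$psi, 5, 5, 0, 0.9, 10L, 6L, cls)
  ), path)
  invisible(path)
}
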