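#' Build a backbone structure table
#'
#' A structure table holds the backbone coordinates of one chain of a fibril
#' core: one row per atom with `residue_number`, `residue_type` (1-letter),
#' `atom_name` and Cartesian `x`, `y`, `z` in Angstrom. It is the coordinate
#' source for calculated phi/psi torsions.
#'
#' @param x data frame with the six columns above.
#' @param structure_id identifier (e.g. a PDB code).
#' @param chain_id chain the coordinates came from.
#' @return a `structure_tbl` tibble ordered by residue then atom.
#' @export
structure_tbl <- function(x, structure_id = "structure", chain_id = "A") {
  need <- c("residue_number", "residue_type", "atom_name", "x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("structure table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x)[need]
  out$residue_number <- as.integer(out$residue_number)
  out$residue_type <- aa_one_letter(out$residue_type)
  out$atom_name <- toupper(trimws(out$atom_name))
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("non-finite coordinates present", call. = FALSE)
  }
  if (anyDuplicated(out[c("residue_number", "atom_name")])) {
    stop("duplicate (residue, atom) coordinate rows", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$residue_number, .data$atom_name)
  attr(out, "structure_id") <- structure_id
  attr(out, "chain_id") <- chain_id
  class(out) <- c("structure_tbl", class(out))
  out
}

#' @export
print.structure_tbl <- function(x, ...) {
  cat(sprintf("<structure_tbl> %s chain %s: %d atoms, %d residues\n",
              attr(x, "structure_id"), attr(x, "chain_id"), nrow(x),
              dplyr::n_distinct(x$residue_number)))
  NextMethod()
}

#' Read backbone coordinates from a PDB or mmCIF file
#'
#' Extracts one chain's backbone (N, CA, C, O) from a coordinate file.
#' HETATM records and non-standard residues are dropped; where alternate
#' locations exist the highest-occupancy one is kept (ties broken by altloc
#' identifier order). The first model is used unless `model_index` says
#' otherwise.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain_id chain to extract; default `"A"`, the single-protofilament
#'   convention used for fibril cores.
#' @param model_index 1-based model number for multi-model files.
#' @param structure_id identifier for the result; defaults to the file stem.
#' @return a [structure_tbl()].
#' @export
read_structure <- function(path, chain_id = "A", model_index = 1L,
                           structure_id = NULL) {
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent|cif)$", "", basename(path),
                        ignore.case = TRUE)
  }
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = model_index > 1, verbose = FALSE)
  at <- pdb$atom
  if (model_index > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index) {
      stop("model ", model_index, " not present in ", path, call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not found in ", path,
         " (available: ", paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  at <- at[toupper(at$elety) %in% c("N", "CA", "C", "O"), , drop = FALSE]
  at <- at[at$resid %in% names(AA1), , drop = FALSE]
  # altloc policy: highest occupancy wins, ties by altloc identifier order
  alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$resno, toupper(at$elety), -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at[c("resno", "elety")]), , drop = FALSE]
  structure_tbl(
    tibble::tibble(
      residue_number = at$resno,
      residue_type = unname(AA1[at$resid]),
      atom_name = toupper(at$elety),
      x = at$x, y = at$y, z = at$z
    ),
    structure_id = structure_id, chain_id = chain_id
  )
}

#' Signed dihedral (torsion) angle of four points
#'
#' Returns the torsion about the p2-p3 axis under the IUPAC sign convention
#' (cis = 0 deg; a clockwise rotation of the far bond viewed from p2 towards
#' p3 is positive), in degrees on (-180, 180] with trans reported as +180.
#' The quadruple `(0,0,0), (1,0,0), (1,1,0), (1,1,1)` gives +90.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return torsion angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- cross3(b1, b2); c23 <- cross3(b2, b3)
  if (sqrt(sum(c12^2)) <= 1e-9 || sqrt(sum(c23^2)) <= 1e-9) {
    stop("degenerate dihedral: three consecutive points are collinear",
         call. = FALSE)
  }
  y <- sqrt(sum(b2^2)) * sum(b1 * c23)
  x <- sum(c12 * c23)
  normalize_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone phi/psi torsions of a structure
#'
#' Phi(i) is the C(i-1)-N(i)-CA(i)-C(i) torsion and psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) torsion. Residues missing a backbone atom, chain
#' termini, and residues adjacent to a chain break (peptide-bond C-N distance
#' >= `break_cutoff`) have the affected angle undefined; only residues with
#' both angles defined are emitted.
#'
#' @param model a [structure_tbl()].
#' @param break_cutoff chain-break guard on the C(i)-N(i+1) distance in
#'   Angstrom.
#' @return a [torsion_tbl()] labelled `"Cal:<structure_id>"`.
#' @export
compute_torsions <- function(model, break_cutoff = 2.5) {
  stopifnot(inherits(model, "structure_tbl"))
  res <- dplyr::distinct(model[c("residue_number", "residue_type")])
  res <- dplyr::arrange(res, .data$residue_number)
  coord <- function(resno, atom) {
    row <- model[model$residue_number == resno & model$atom_name == atom, ]
    if (nrow(row) != 1) return(NULL)
    c(row$x, row$y, row$z)
  }
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rn <- res$residue_number[i]
    N_i <- coord(rn, "N"); CA_i <- coord(rn, "CA"); C_i <- coord(rn, "C")
    if (is.null(N_i) || is.null(CA_i) || is.null(C_i)) next
    if (i > 1 && res$residue_number[i - 1] == rn - 1) {
      C_prev <- coord(rn - 1, "C")
      if (!is.null(C_prev) && sqrt(sum((N_i - C_prev)^2)) < break_cutoff) {
        phi[i] <- dihedral_angle(C_prev, N_i, CA_i, C_i)
      }
    }
    if (i < n && res$residue_number[i + 1] == rn + 1) {
      N_next <- coord(rn + 1, "N")
      if (!is.null(N_next) && sqrt(sum((N_next - C_i)^2)) < break_cutoff) {
        psi[i] <- dihedral_angle(N_i, CA_i, C_i, N_next)
      }
    }
  }
  keep <- !is.na(phi) & !is.na(psi)
  torsion_tbl(
    tibble::tibble(
      residue_number = res$residue_number[keep],
      residue_type = res$residue_type[keep],
      phi = phi[keep], psi = psi[keep]
    ),
    source_label = paste0("Cal:", attr(model, "structure_id"))
  )
}

#' Write a backbone structure as a PDB file
#'
#' Minimal ATOM-record writer used to materialize synthetic backbones in the
#' format the structure reader consumes.
#'
#' @param model a [structure_tbl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_tbl"))
  ord <- order(model$residue_number,
               match(model$atom_name, c("N", "CA", "C", "O")))
  m <- model[ord, ]
  elem <- substr(m$atom_name, 1, 1)
  rec <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(m)), m$atom_name, AA3[m$residue_type],
    attr(model, "chain_id") %||% "A", m$residue_number,
    m$x, m$y, m$z, 1, 0, elem
  )
  writeLines(c(rec, "TER", "END"), path)
  invisible(path)
}
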