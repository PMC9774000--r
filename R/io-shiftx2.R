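#' Read a ShiftX2 prediction table into a shift table
#'
#' ShiftX2 predicts chemical shifts from a PDB coordinate file; its tabular
#' output (`*.cs`, comma- or whitespace-separated with columns NUM, RES,
#' ATOMNAME, SHIFT) is the calculated side of the chemical-shift strain
#' metrics. Rows whose atom name is outside `atoms` are skipped; the number
#' skipped is recorded in the `n_skipped` attribute and reported via a
#' message.
#'
#' @param path prediction table path.
#' @param structure_id identifier of the structure the prediction came from;
#'   the table's source label becomes `"Cal:<structure_id>"`.
#' @param atoms backbone-relevant atom names to keep (CO is normalized to C).
#' @param offset integer added to residue numbers (ShiftX2 inherits the PDB's
#'   numbering, so this is usually 0).
#' @return a [shift_tbl()] with attribute `n_skipped`.
#' @export
read_shiftx2_shifts <- function(path, structure_id,
                                atoms = c("CA", "CB", "C", "N"),
                                offset = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty ShiftX2 table: ", path, call. = FALSE)
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  split_row <- function(x) {
    if (sep_comma) trimws(strsplit(x, ",")[[1]]) else
      strsplit(trimws(x), "\\s+")[[1]]
  }
  fields <- lapply(lines, split_row)
  header <- toupper(fields[[1]])
  has_header <- any(header %in% c("NUM", "RES", "ATOMNAME", "SHIFT"))
  if (has_header) {
    idx <- match(c("NUM", "RES", "ATOMNAME", "SHIFT"), header)
    if (any(is.na(idx))) {
      stop("unrecognized ShiftX2 column layout at line 1: ", lines[1],
           call. = FALSE)
    }
    fields <- fields[-1]
    line_no <- seq_along(lines)[-1]
  } else {
    idx <- 1:4
    line_no <- seq_along(lines)
  }
  nf <- lengths(fields)
  if (any(nf < max(idx))) {
    stop("unparseable ShiftX2 row at line ", line_no[which(nf < max(idx))[1]],
         call. = FALSE)
  }
  num <- vapply(fields, `[`, "", idx[1])
  res <- vapply(fields, `[`, "", idx[2])
  atom <- normalize_atom_name(vapply(fields, `[`, "", idx[3]))
  shift_chr <- vapply(fields, `[`, "", idx[4])
  shift <- suppressWarnings(as.numeric(shift_chr))
  if (any(is.na(shift))) {
    bad <- which(is.na(shift))[1]
    stop("non-numeric shift field at line ", line_no[bad], ": ",
         shift_chr[bad], call. = FALSE)
  }
  keep <- atom %in% normalize_atom_name(atoms)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("read_shiftx2_shifts: skipped %d row(s) with atoms outside {%s}",
                    n_skipped, paste(atoms, collapse = ", ")))
  }
  out <- shift_tbl(
    tibble::tibble(
      residue_number = as.integer(num[keep]) + as.integer(offset),
      residue_type = res[keep],
      atom_name = atom[keep],
      shift = shift[keep]
    ),
    source_label = paste0("Cal:", structure_id)
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a shift table in ShiftX2 output layout
#'
#' CSV with header `NUM,RES,ATOMNAME,SHIFT` — the layout emitted by ShiftX2,
#' so synthetic predicted-shift tables exercise the same reader as real ones.
#'
#' @param shifts a [shift_tbl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shiftx2_shifts <- function(shifts, path) {
  stopifnot(inherits(shifts, "shift_tbl"))
  writeLines(c(
    "NUM,RES,ATOMNAME,SHIFT",
    sprintf("%d,%s,%s,%.4f", shifts$residue_number, shifts$residue_type,
            shifts$atom_name, shifts$shift)
  ), path)
  invisible(path)
}
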