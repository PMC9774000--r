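#' Read assigned chemical shifts from an NMR-STAR v3 file
#'
#' Parses the `_Atom_chem_shift` loop of a BMRB-style NMR-STAR v3 deposition
#' into a [shift_tbl()]. Only the assigned-chemical-shift loop is read; the
#' rest of the file is ignored.
#'
#' Residue numbering: BMRB depositions carry both a sequence-relative number
#' (`Comp_index_ID`) and an author number (`Auth_seq_ID`). This package works
#' throughout in full-length 2N4R tau numbering, so the default takes the
#' author number when present and falls back to the sequence number; `offset`
#' is added afterwards to map sequence-relative depositions onto the 2N4R
#' frame (e.g. `offset = 296` for a construct whose residue 1 is I297).
#'
#' @param path NMR-STAR file path.
#' @param entity_selector optional entity id; rows of other entities are
#'   dropped when the loop carries an `Entity_ID` tag.
#' @param numbering `"auth"` (default) or `"seq"`.
#' @param offset integer added to the chosen residue number.
#' @param atoms optional character vector restricting atom names (after
#'   CO -> C normalization); `NULL` keeps every atom row.
#' @param source_label label for the resulting table.
#' @return a [shift_tbl()].
#' @export
read_nmrstar_shifts <- function(path, entity_selector = NULL,
                                numbering = c("auth", "seq"), offset = 0L,
                                atoms = NULL, source_label = "NMR") {
  numbering <- match.arg(numbering)
  lines <- readLines(path, warn = FALSE)
  loop <- find_star_loop(lines, "_Atom_chem_shift.")
  if (is.null(loop)) {
    stop("no assigned chemical shift loop (_Atom_chem_shift) found in ", path,
         call. = FALSE)
  }
  tab <- loop
  col <- function(tag) {
    hit <- paste0("_Atom_chem_shift.", tag)
    if (hit %in% names(tab)) tab[[hit]] else NULL
  }
  comp_id <- col("Comp_ID")
  atom_id <- col("Atom_ID")
  val <- col("Val")
  if (is.null(comp_id) || is.null(atom_id) || is.null(val)) {
    stop("chemical shift loop lacks Comp_ID/Atom_ID/Val tags", call. = FALSE)
  }
  seq_id <- col("Comp_index_ID") %||% col("Seq_ID")
  auth_id <- col("Auth_seq_ID")
  if (!is.null(entity_selector)) {
    ent <- col("Entity_ID") %||% col("Entity_assembly_ID")
    if (!is.null(ent)) {
      keep <- ent == as.character(entity_selector)
      tab <- lapply(tab, `[`, keep)
      comp_id <- comp_id[keep]; atom_id <- atom_id[keep]; val <- val[keep]
      seq_id <- seq_id[keep]; auth_id <- auth_id[keep]
    }
  }
  resnum <- if (numbering == "auth" && !is.null(auth_id) &&
                !all(auth_id %in% c(".", "?"))) auth_id else seq_id
  if (is.null(resnum)) {
    stop("chemical shift loop lacks residue numbering tags", call. = FALSE)
  }
  shift_num <- suppressWarnings(as.numeric(val))
  if (any(is.na(shift_num))) {
    stop("non-numeric shift value in chemical shift loop: ",
         val[which(is.na(shift_num))[1]], call. = FALSE)
  }
  out <- tibble::tibble(
    residue_number = as.integer(resnum) + as.integer(offset),
    residue_type = comp_id,
    atom_name = normalize_atom_name(atom_id),
    shift = shift_num
  )
  if (!is.null(atoms)) {
    out <- dplyr::filter(out, .data$atom_name %in% normalize_atom_name(atoms))
  }
  # identical duplicate rows are collapsed; conflicting duplicates are an error
  out <- dplyr::distinct(out)
  key <- paste(out$residue_number, out$atom_name)
  if (anyDuplicated(key)) {
    bad <- out$residue_number[duplicated(key)][1]
    stop("conflicting duplicate shift rows for residue ", bad, call. = FALSE)
  }
  shift_tbl(out, source_label = source_label)
}

# Tokenize NMR-STAR content and return the first loop whose tags start with
# `tag_prefix`, as a named list of character vectors (one per tag).
find_star_loop <- function(lines, tag_prefix) {
  lines <- sub("^\\s*#.*$", "", lines)
  n <- length(lines)
  i <- 1
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1
      tags <- character()
      while (j <= n && grepl("^\\s*_\\S+\\s*$", lines[j])) {
        tags <- c(tags, trimws(lines[j]))
        j <- j + 1
      }
      body <- character()
      while (j <= n && !grepl("^\\s*(stop_|loop_)\\s*$", lines[j]) &&
             !grepl("^\\s*save_", lines[j])) {
        body <- c(body, lines[j])
        j <- j + 1
      }
      if (length(tags) > 0 && any(startsWith(tags, tag_prefix))) {
        tokens <- unlist(lapply(body, star_tokens), use.names = FALSE)
        if (length(tokens) %% length(tags) != 0) {
          stop("malformed NMR-STAR loop: ", length(tokens),
               " values for ", length(tags), " tags", call. = FALSE)
        }
        m <- matrix(tokens, ncol = length(tags), byrow = TRUE)
        return(stats::setNames(lapply(seq_along(tags), function(k) m[, k]), tags))
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  NULL
}

# split one line into STAR tokens, honouring single/double quotes
star_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character())
  tok <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

#' Write a minimal NMR-STAR v3 assigned-chemical-shift file
#'
#' Emits just a `data_` block with an `_Atom_chem_shift` loop — enough for any
#' NMR-STAR v3 reader of assigned shifts. Used to materialize synthetic
#' assignments as deposition-format fixtures.
#'
#' @param shifts a [shift_tbl()].
#' @param path output file path.
#' @param entry_id data block name.
#' @return `path`, invisibly.
#' @export
write_nmrstar_shifts <- function(shifts, path, entry_id = "synthetic") {
  stopifnot(inherits(shifts, "shift_tbl"))
  rows <- sprintf("  %4d %4d %-4s %-4s %9.4f 1",
                  seq_len(nrow(shifts)), shifts$residue_number,
                  AA3[shifts$residue_type], shifts$atom_name, shifts$shift)
  writeLines(c(
    paste0("data_", entry_id),
    "",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Auth_seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  _Atom_chem_shift.Entity_ID",
    rows,
    "stop_",
    ""
  ), path)
  invisible(path)
}
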