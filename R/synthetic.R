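#' Define a backbone torsion program
#'
#' A torsion program is the ground truth of the synthetic world: a sequence
#' plus contiguous segments, each with fixed phi/psi and a secondary-structure
#' label. Cross-beta fibril cores are dominated by beta-strand segments with
#' short localized kinks — regions deviating from strand conformation — whose
#' placement is what distinguishes fibril strains, so decoy structures differ
#' from the truth only in where those kinks sit.
#'
#' @param segments tibble/data frame with columns `start`, `end` (inclusive
#'   residue numbers), `phi`, `psi` (degrees), `label` (one of `"strand"`,
#'   `"helix"`, `"kink"`, `"coil"`).
#' @param sequence amino-acid sequence (1-letter string or vector) covering
#'   exactly the segment span.
#' @param start_residue number of the first residue.
#' @param program_id identifier used when the program is materialized as a
#'   structure or shift table.
#' @return a `torsion_program` object.
#' @export
#' @examples
#' torsion_program(
#'   data.frame(start = c(1, 5, 8), end = c(4, 7, 12),
#'              phi = c(-135, -80, -135), psi = c(135, 0, 135),
#'              label = c("strand", "kink", "strand")),
#'   sequence = "AKVLEGSTYNQW", start_residue = 1
#' )
torsion_program <- function(segments, sequence, start_residue = 1L,
                            program_id = "truth") {
  segments <- tibble::as_tibble(segments)
  need <- c("start", "end", "phi", "psi", "label")
  if (!all(need %in% names(segments))) {
    stop("segments need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  sequence <- aa_one_letter(sequence)
  segments <- dplyr::arrange(segments, .data$start)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (!all(segments$label %in% c("strand", "helix", "kink", "coil"))) {
    stop("segment labels must be strand/helix/kink/coil", call. = FALSE)
  }
  start_residue <- as.integer(start_residue)
  end_residue <- start_residue + length(sequence) - 1L
  expected_starts <- c(start_residue,
                       segments$end[-nrow(segments)] + 1L)
  if (!identical(segments$start, expected_starts) ||
      segments$end[nrow(segments)] != end_residue ||
      any(segments$end < segments$start)) {
    stop("segments must be contiguous, non-overlapping and cover residues ",
         start_residue, "-", end_residue, call. = FALSE)
  }
  if (any(abs(segments$phi) > 180 | abs(segments$psi) > 180)) {
    stop("segment phi/psi must lie in (-180, 180]", call. = FALSE)
  }
  structure(
    list(segments = segments, sequence = sequence,
         start_residue = start_residue, program_id = program_id),
    class = "torsion_program"
  )
}

#' @export
print.torsion_program <- function(x, ...) {
  cat(sprintf("<torsion_program> %s: %d residues (%d-%d), %d segments (%d kink)\n",
              x$program_id, length(x$sequence), x$start_residue,
              x$start_residue + length(x$sequence) - 1L,
              nrow(x$segments), sum(x$segments$label == "kink")))
  print(x$segments, ...)
  invisible(x)
}

#' Per-residue expansion of a torsion program
#'
#' @param program a [torsion_program()].
#' @return tibble with one row per residue: `residue_number`, `residue_type`,
#'   `phi`, `psi`, `label`.
#' @export
program_residues <- function(program) {
  stopifnot(inherits(program, "torsion_program"))
  seg <- program$segments
  len <- seg$end - seg$start + 1L
  tibble::tibble(
    residue_number = seq(program$start_residue,
                         length.out = length(program$sequence)),
    residue_type = program$sequence,
    phi = rep(seg$phi, len),
    psi = rep(seg$psi, len),
    label = rep(seg$label, len)
  )
}

#' Torsion table of a program
#'
#' The program's phi/psi read off directly (no geometry involved), optionally
#' with Gaussian noise — the synthetic analogue of a shift-derived torsion
#' prediction for the observed side.
#'
#' @param program a [torsion_program()].
#' @param noise_sd per-angle Gaussian noise in degrees.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param source_label label for the table.
#' @return a [torsion_tbl()].
#' @export
program_torsions <- function(program, noise_sd = 0, seed = 1L,
                             source_label = program$program_id) {
  res <- program_residues(program)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(2 * nrow(res), 0, noise_sd))
    res$phi <- res$phi + noise[seq_len(nrow(res))]
    res$psi <- res$psi + noise[-seq_len(nrow(res))]
  }
  torsion_tbl(res[c("residue_number", "residue_type", "phi", "psi")],
              source_label = source_label)
}

# ideal backbone geometry (Angstrom / degrees): bond lengths fixed by the
# builder's contract, bond angles standard single-conformation values
IDEAL_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  omega = 180
)

# place atom d given a-b-c, bond length L (c-d), angle theta (b-c-d) and
# torsion chi (a-b-c-d), matching the sign convention of dihedral_angle()
place_atom <- function(a, b, c, L, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  u_bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- cross3(b - a, u_bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, u_bc)
  c + L * (-cos(th) * u_bc + sin(th) * cos(ch) * m + sin(th) * sin(ch) * n)
}

#' Build an ideal-geometry backbone realizing a torsion program
#'
#' Constructs N/CA/C coordinates residue by residue with fixed ideal bond
#' lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom), standard bond
#' angles, and a planar trans peptide (omega = 180 deg), so that the
#' program's phi/psi are realized exactly. Deterministic: the same program
#' always yields bit-identical coordinates. phi of the first residue and psi
#' of the last are not representable and are simply not constrained.
#'
#' @param program a [torsion_program()] with at least 3 residues.
#' @param structure_id identifier; defaults to the program id.
#' @param chain_id chain identifier for downstream writers.
#' @return a [structure_tbl()] with N, CA, C atoms per residue.
#' @export
generate_backbone <- function(program, structure_id = program$program_id,
                              chain_id = "A") {
  res <- program_residues(program)
  n_res <- nrow(res)
  if (n_res < 3) stop("need at least 3 residues", call. = FALSE)
  g <- IDEAL_GEOM
  coords <- matrix(NA_real_, nrow = 3 * n_res, ncol = 3)
  # residue 1: N at origin, CA on x, C in the xy-plane at the N-CA-C angle
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  coords[3, ] <- coords[2, ] + g$ca_c * c(cos(th), sin(th), 0)
  idx <- function(i, atom) (i - 1) * 3 + match(atom, c("N", "CA", "C"))
  for (i in seq_len(n_res - 1)) {
    N_i <- coords[idx(i, "N"), ]; CA_i <- coords[idx(i, "CA"), ]
    C_i <- coords[idx(i, "C"), ]
    # psi(i) places N(i+1); omega places CA(i+1); phi(i+1) places C(i+1)
    N_next <- place_atom(N_i, CA_i, C_i, g$c_n, g$ang_ca_c_n, res$psi[i])
    CA_next <- place_atom(CA_i, C_i, N_next, g$n_ca, g$ang_c_n_ca, g$omega)
    C_next <- place_atom(C_i, N_next, CA_next, g$ca_c, g$ang_n_ca_c,
                         res$phi[i + 1])
    coords[idx(i + 1, "N"), ] <- N_next
    coords[idx(i + 1, "CA"), ] <- CA_next
    coords[idx(i + 1, "C"), ] <- C_next
  }
  structure_tbl(
    tibble::tibble(
      residue_number = rep(res$residue_number, each = 3),
      residue_type = rep(res$residue_type, each = 3),
      atom_name = rep(c("N", "CA", "C"), n_res),
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    ),
    structure_id = structure_id, chain_id = chain_id
  )
}

#' Forward model from secondary structure to Calpha/Cbeta shifts
#'
#' Encodes the sign rule that links S to secondary structure: strand residues
#' get a negative Calpha and positive Cbeta secondary-shift offset (so
#' S < 0), helical residues the opposite (S > 0), kink/coil residues sit at
#' the random-coil value. Offsets are simulator parameters chosen to satisfy
#' that rule, not literature shift statistics.
#'
#' @param offsets named list mapping each label to `c(dca, dcb)` ppm offsets.
#' @param noise_sd Gaussian noise added per shift, ppm.
#' @param seed RNG seed for the noise.
#' @return a `forward_shift_model` list.
#' @export
forward_shift_model <- function(offsets = list(
                                  strand = c(dca = -1.5, dcb = 2.0),
                                  helix = c(dca = 2.6, dcb = -0.5),
                                  kink = c(dca = 0, dcb = 0),
                                  coil = c(dca = 0, dcb = 0)
                                ),
                                noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  need <- c("strand", "helix", "kink", "coil")
  if (!all(need %in% names(offsets))) {
    stop("offsets must name strand, helix, kink and coil", call. = FALSE)
  }
  if (!(offsets$strand[1] < 0 && offsets$strand[2] > 0)) {
    stop("strand offsets must satisfy dca < 0 < dcb (S < 0)", call. = FALSE)
  }
  if (!(offsets$helix[1] > 0 && offsets$helix[2] < 0)) {
    stop("helix offsets must satisfy dca > 0 > dcb (S > 0)", call. = FALSE)
  }
  structure(list(offsets = offsets, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "forward_shift_model")
}

#' Simulate a Calpha/Cbeta shift table from a torsion program
#'
#' Each residue's shifts are the random-coil reference plus the label's
#' offset plus independent Gaussian noise; glycines emit only Calpha.
#' Fully reproducible from the model's seed.
#'
#' @param program a [torsion_program()].
#' @param rc random-coil reference, see [random_coil_shifts()].
#' @param model a [forward_shift_model()].
#' @param source_label label for the table (e.g. `"NMR"` for an observed
#'   table, `"Cal:<id>"` for a zero-noise predicted one).
#' @return a [shift_tbl()].
#' @export
simulate_shift_table <- function(program, rc = random_coil_shifts(),
                                 model = forward_shift_model(),
                                 source_label = "NMR") {
  res <- program_residues(program)
  off <- do.call(rbind, model$offsets)[res$label, , drop = FALSE]
  rc_ca <- stats::setNames(rc$rc_ca, rc$residue_type)[res$residue_type]
  rc_cb <- stats::setNames(rc$rc_cb, rc$residue_type)[res$residue_type]
  n <- nrow(res)
  noise <- if (model$noise_sd > 0) {
    withr::with_seed(model$seed, stats::rnorm(2 * n, 0, model$noise_sd))
  } else {
    rep(0, 2 * n)
  }
  ca <- unname(rc_ca) + off[, 1] + noise[seq_len(n)]
  cb <- unname(rc_cb) + off[, 2] + noise[n + seq_len(n)]
  has_cb <- res$residue_type != "G"
  shift_tbl(
    tibble::tibble(
      residue_number = c(res$residue_number, res$residue_number[has_cb]),
      residue_type = c(res$residue_type, res$residue_type[has_cb]),
      atom_name = c(rep("CA", n), rep("CB", sum(has_cb))),
      shift = c(ca, cb[has_cb])
    ),
    source_label = source_label
  )
}

#' Generate decoy programs by translating the kinks
#'
#' Fibril strains share their beta-strand layout and differ in where the
#' kinks fall, so decoys are made from the truth by shifting every kink
#' segment along the sequence by a nonzero offset. Offset tuples are drawn
#' without replacement, so all decoys are distinct from the truth and from
#' each other; vacated positions inherit the flanking background segment's
#' torsions and label.
#'
#' @param truth a [torsion_program()] with at least one kink segment.
#' @param n_decoys number of decoys.
#' @param kink_shift_range maximum |offset| in residues.
#' @param seed RNG seed.
#' @param min_shift minimum |offset| (default 1).
#' @return list of [torsion_program()]s with ids `"decoy01"`, `"decoy02"`, ...
#' @export
make_decoys <- function(truth, n_decoys, kink_shift_range = 4L, seed = 1L,
                        min_shift = 1L) {
  stopifnot(inherits(truth, "torsion_program"), n_decoys >= 1,
            kink_shift_range >= min_shift, min_shift >= 1)
  res <- program_residues(truth)
  kinks <- which(truth$segments$label == "kink")
  if (length(kinks) == 0) stop("truth program has no kink segment",
                               call. = FALSE)
  seg <- truth$segments
  lo <- truth$start_residue
  hi <- lo + length(truth$sequence) - 1L
  offsets <- setdiff(seq(-kink_shift_range, kink_shift_range),
                     seq(-(min_shift - 1L), min_shift - 1L))
  grid <- expand.grid(rep(list(offsets), length(kinks)))
  valid <- apply(grid, 1, function(o) {
    s <- seg$start[kinks] + o; e <- seg$end[kinks] + o
    if (any(s < lo + 1L) || any(e > hi - 1L)) return(FALSE)
    # moved kinks must not collide with each other
    if (length(kinks) > 1) {
      ord <- order(s)
      if (any(s[ord][-1] <= e[ord][-length(e)] + 1L)) return(FALSE)
    }
    TRUE
  })
  grid <- grid[valid, , drop = FALSE]
  if (nrow(grid) < n_decoys) {
    stop("kink shift range admits only ", nrow(grid),
         " distinct decoys; asked for ", n_decoys, call. = FALSE)
  }
  pick <- withr::with_seed(seed, sample(nrow(grid), n_decoys))
  lapply(seq_len(n_decoys), function(d) {
    o <- as.integer(unlist(grid[pick[d], ]))
    per <- res
    # clear original kink positions: inherit the nearest background residue
    bg <- which(per$label != "kink")
    for (i in which(per$label == "kink")) {
      j <- bg[which.min(abs(bg - i))]
      per[i, c("phi", "psi", "label")] <- per[j, c("phi", "psi", "label")]
    }
    for (k in seq_along(kinks)) {
      s <- seg$start[kinks[k]] + o[k]; e <- seg$end[kinks[k]] + o[k]
      rows <- per$residue_number >= s & per$residue_number <= e
      per$phi[rows] <- seg$phi[kinks[k]]
      per$psi[rows] <- seg$psi[kinks[k]]
      per$label[rows] <- "kink"
    }
    residues_to_program(per, program_id = sprintf("decoy%02d", d))
  })
}

# compress a per-residue expansion back into a segment program
residues_to_program <- function(per, program_id) {
  r <- rle(paste(per$phi, per$psi, per$label))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  torsion_program(
    tibble::tibble(
      start = per$residue_number[starts],
      end = per$residue_number[ends],
      phi = per$phi[starts],
      psi = per$psi[starts],
      label = per$label[starts]
    ),
    sequence = per$residue_type,
    start_residue = per$residue_number[1],
    program_id = program_id
  )
}

#' Default synthetic ground truth for the tau(297-391) core
#'
#' A beta-strand-dominated backbone over the tau(297-391) sequence with four
#' 3-residue kinks (phi = -80, psi = 0) placed away from the ambiguous PGGG
#' repeats — a torsion-level cartoon of a fibril core fold whose identity is
#' carried by kink placement.
#'
#' @param kink_starts first residues of the kink segments.
#' @param kink_length kink length in residues.
#' @param strand phi/psi of the strand background, degrees.
#' @param kink phi/psi of the kinks, degrees.
#' @return a [torsion_program()] with id `"truth"`.
#' @export
tau_truth_program <- function(kink_starts = c(317L, 339L, 352L, 369L),
                              kink_length = 3L,
                              strand = c(phi = -135, psi = 135),
                              kink = c(phi = -80, psi = 0)) {
  sq <- tau_core_sequence()
  per <- tibble::tibble(
    residue_number = sq$residue_number,
    residue_type = sq$residue_type,
    phi = strand[["phi"]], psi = strand[["psi"]], label = "strand"
  )
  for (s in kink_starts) {
    rows <- per$residue_number >= s & per$residue_number < s + kink_length
    per$phi[rows] <- kink[["phi"]]
    per$psi[rows] <- kink[["psi"]]
    per$label[rows] <- "kink"
  }
  residues_to_program(per, program_id = "truth")
}
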