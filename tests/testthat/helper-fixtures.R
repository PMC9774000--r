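# Programmatic fixtures: random paired tables and tiny format files.

AA_NO_G <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "H", "I", "L", "K",
                     "M", "F", "P", "S", "T", "W", "Y", "V"), "G")

# paired random shift tables over a shared residue frame with random
# missingness; glycines sprinkled in to exercise the CA-only path
random_shift_pair <- function(seed, n_res = 30) {
  withr::with_seed(seed, {
    residues <- sort(sample(1:60, n_res))
    types <- sample(c(AA_NO_G, "G"), n_res, replace = TRUE,
                    prob = c(rep(1, length(AA_NO_G)), 3))
    one_side <- function(label) {
      rows <- list()
      for (i in seq_len(n_res)) {
        if (stats::runif(1) < 0.9) {
          rows[[length(rows) + 1]] <- data.frame(
            residue_number = residues[i], residue_type = types[i],
            atom_name = "CA", shift = stats::rnorm(1, 55, 4)
          )
        }
        if (types[i] != "G" && stats::runif(1) < 0.8) {
          rows[[length(rows) + 1]] <- data.frame(
            residue_number = residues[i], residue_type = types[i],
            atom_name = "CB", shift = stats::rnorm(1, 35, 5)
          )
        }
      }
      shift_tbl(do.call(rbind, rows), source_label = label)
    }
    list(nmr = one_side("NMR"), cal = one_side("Cal:test"))
  })
}

random_torsion_pair <- function(seed, n_res = 25) {
  withr::with_seed(seed, {
    residues <- sort(sample(1:60, n_res))
    types <- sample(AA_NO_G, n_res, replace = TRUE)
    one_side <- function(label, keep_p) {
      keep <- stats::runif(n_res) < keep_p
      torsion_tbl(data.frame(
        residue_number = residues[keep], residue_type = types[keep],
        phi = stats::runif(sum(keep), -179.999, 180),
        psi = stats::runif(sum(keep), -179.999, 180)
      ), source_label = label)
    }
    list(nmr = one_side("NMR", 0.9), cal = one_side("Cal:test", 0.9))
  })
}

# an all-true eligibility table for hand-built toy inputs
make_matched <- function(residues) {
  out <- tibble::tibble(
    residue_number = as.integer(residues),
    nmr_ca = TRUE, nmr_cb = TRUE, cal_ca = TRUE, cal_cb = TRUE,
    nmr_s = TRUE, cal_s = TRUE, nmr_phi_psi = TRUE, cal_phi_psi = TRUE
  )
  class(out) <- c("matched_residues", class(out))
  out
}

# shift table engineered so that secondary_shifts() yields the requested
# s_values (split evenly between delta_ca and -delta_cb), all alanines
shifts_with_s <- function(residues, s_values, label = "NMR") {
  rc <- random_coil_shifts()
  rc_a <- rc[rc$residue_type == "A", ]
  shift_tbl(data.frame(
    residue_number = rep(residues, 2),
    residue_type = "A",
    atom_name = rep(c("CA", "CB"), each = length(residues)),
    shift = c(rc_a$rc_ca + s_values / 2, rc_a$rc_cb - s_values / 2)
  ), source_label = label)
}

# hand-written three-residue PDB (two chains for the selection test)
write_tiny_pdb <- function(path, gap = FALSE) {
  n3_y <- if (gap) 10.0 else 6.7  # pushes the C(2)-N(3) bond far beyond 2.5 A
  lines <- c(
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            3, "C", "ALA", "A", 1, 2.009, 1.420, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            4, "N", "GLY", "A", 2, 1.326, 2.500, 0.0, "N"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            5, "CA", "GLY", "A", 2, 1.900, 3.850, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            6, "C", "GLY", "A", 2, 1.100, 5.100, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            7, "N", "SER", "A", 3, 1.700, n3_y + 0.26, 0.0, "N"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            8, "CA", "SER", "A", 3, 1.100, n3_y + 1.60, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            9, "C", "SER", "A", 3, 2.000, n3_y + 2.80, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            10, "N", "VAL", "B", 1, 9.0, 9.0, 9.0, "N"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            11, "CA", "VAL", "B", 1, 10.458, 9.0, 9.0, "C"),
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            12, "C", "VAL", "B", 1, 11.0, 10.4, 9.0, "C"),
    "TER", "END"
  )
  writeLines(lines, path)
  path
}

# NMR-STAR text with a glycine CB row (invariant violation fixture)
nmrstar_with_gly_cb <- function(path) {
  writeLines(c(
    "data_bad",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Auth_seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 5 GLY CA 45.2 ",
    "  2 5 GLY CB 30.1 ",
    "stop_"
  ), path)
  path
}

# a coverage-masked synthetic assignment mirroring the rigid-core segments
synthetic_assignment <- function(noise_sd = 0, seed = 11) {
  segs <- assignment_segments()
  keep <- sort(unique(c(
    unlist(Map(seq, segs$start, segs$end)), ambiguous_pggg_residues()
  )))
  tab <- simulate_shift_table(
    tau_truth_program(), random_coil_shifts(),
    forward_shift_model(noise_sd = noise_sd, seed = seed),
    source_label = "NMR"
  )
  shift_tbl(tab[tab$residue_number %in% keep, ], source_label = "NMR")
}
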