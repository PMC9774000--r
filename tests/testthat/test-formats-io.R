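test_that("NMR-STAR shift tables round-trip exactly", {
  tab <- shift_tbl(data.frame(
    residue_number = rep(5:7, each = 2),
    residue_type = rep(c("V", "K", "L"), each = 2),
    atom_name = rep(c("CA", "CB"), 3),
    shift = c(61.23, 33.01, 55.4872, 34.11, 54.9, 46.0)
  ), source_label = "NMR")
  path <- withr::local_tempfile(fileext = ".str")
  write_nmrstar_shifts(tab, path)
  back <- read_nmrstar_shifts(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$shift, tab$shift, tolerance = 1e-12)
  expect_equal(back$residue_number, tab$residue_number)
  expect_equal(back$atom_name, tab$atom_name)
})

test_that("NMR-STAR reader enforces the shift-table invariants", {
  path <- withr::local_tempfile(fileext = ".str")
  nmrstar_with_gly_cb(path)
  expect_error(read_nmrstar_shifts(path), "glycine")

  # conflicting duplicate rows are a data error naming the residue
  writeLines(c(
    "data_dup", "loop_",
    "  _Atom_chem_shift.ID", "  _Atom_chem_shift.Auth_seq_ID",
    "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 9 VAL CA 61.0", "  2 9 VAL CA 62.5", "stop_"
  ), path)
  expect_error(read_nmrstar_shifts(path), "residue 9")

  # a file without the assigned-shift loop is a format error
  writeLines(c("data_empty", "loop_", "  _Other.Tag", "  1", "stop_"), path)
  expect_error(read_nmrstar_shifts(path), "no assigned chemical shift loop")
})

test_that("a coverage-masked assignment keeps the rigid-core segments", {
  tab <- synthetic_assignment()
  path <- withr::local_tempfile(fileext = ".str")
  write_nmrstar_shifts(tab, path)
  back <- read_nmrstar_shifts(path)
  segs <- assignment_segments()
  for (k in seq_len(nrow(segs))) {
    expect_true(all(segs$start[k]:segs$end[k] %in% back$residue_number),
                label = sprintf("segment %d-%d", segs$start[k], segs$end[k]))
  }
  expect_false(308 %in% back$residue_number)
  expect_true(all(ambiguous_pggg_residues() %in% back$residue_number))
})

test_that("ShiftX2 tables round-trip and filter non-backbone atoms", {
  path <- withr::local_tempfile(fileext = ".cs")
  writeLines(c("NUM,RES,ATOMNAME,SHIFT",
               "12,V,CA,61.2345", "12,V,CB,33.8721"), path)
  tab <- read_shiftx2_shifts(path, structure_id = "toy")
  expect_equal(tab$shift, c(61.2345, 33.8721))
  expect_equal(source_label(tab), "Cal:toy")

  writeLines(c("NUM,RES,ATOMNAME,SHIFT",
               "12,V,CA,61.2", "12,V,HB,1.9", "12,V,CG1,21.0"), path)
  expect_message(tab <- read_shiftx2_shifts(path, structure_id = "toy"),
                 "skipped 2")
  expect_equal(attr(tab, "n_skipped"), 2)
  expect_equal(nrow(tab), 1)

  writeLines(c("NUM,RES,ATOMNAME,SHIFT", "12,V,CA,not_a_number"), path)
  expect_error(read_shiftx2_shifts(path, structure_id = "toy"),
               "non-numeric shift field at line 2")
})

test_that("TALOS-N reader filters classes and normalizes angles", {
  tors <- torsion_tbl(data.frame(
    residue_number = 5:7, residue_type = c("V", "K", "L"),
    phi = c(-120, -65, -135), psi = c(130, -40, 150)
  ), source_label = "NMR")
  path <- withr::local_tempfile(fileext = ".tab")
  write_talosn_torsions(tors, path)
  back <- read_talosn_torsions(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$phi, tors$phi)

  # one row of an excluded class is dropped and logged
  write_talosn_torsions(tors, path,
                        classification = c("Strong", "Warn", "Strong"))
  expect_message(back <- read_talosn_torsions(path), "dropped 1")
  expect_equal(back$residue_number, c(5L, 7L))
  expect_equal(attr(back, "dropped"), 6L)

  # angle wrap: psi written as 185 is stored as -175
  writeLines(c(
    "VARS   RESID RESNAME PHI PSI CLASS",
    "FORMAT %4d %s %8.3f %8.3f %s",
    "   5 V -120.0 185.0 Strong"
  ), path)
  back <- read_talosn_torsions(path)
  expect_equal(back$psi, -175)

  writeLines(c("VARS RESID RESNAME CS_COUNT CLASS", "  5 V 4 Strong"), path)
  expect_error(read_talosn_torsions(path), "PHI/PSI")
})

test_that("metric reports round-trip through CSV and JSON", {
  report <- rank_structures(tibble::tibble(
    structure_id = c("s1", "s2"),
    sigma_cs = c(12.5, 8.25), n_cs = c(10L, 9L),
    sigma_a = c(3L, 1L), n_a = c(10L, 9L),
    sigma_psiphi = c(400.5, 210.25), n_psiphi = c(8L, 8L),
    fold_label = c("AD", "CBD")
  ))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(report, csv)
  write_metric_report(report, js)
  expect_equal(readLines(csv)[1],
               paste("structure_id,sigma_cs_ppm,n_cs,sigma_a,n_a",
                     "sigma_psiphi_deg,n_psiphi,rank_cs,rank_a,rank_psiphi",
                     "fold_label", sep = ","))
  for (back in list(read_metric_report(csv), read_metric_report(js))) {
    expect_equal(back$structure_id, report$structure_id)
    expect_equal(back$sigma_cs, report$sigma_cs, tolerance = 1e-12)
    expect_equal(back$rank_a, report$rank_a)
    expect_equal(back$fold_label, report$fold_label)
  }
})

test_that("tied sign-disagreement rows follow the documented tie-break", {
  report <- rank_structures(tibble::tibble(
    structure_id = c("zeta", "alpha", "mid"),
    sigma_cs = c(5, 6, 7), n_cs = 3L,
    sigma_a = c(2L, 2L, 2L), n_a = 3L,
    sigma_psiphi = c(100, 100, 50), n_psiphi = 3L
  ))
  # ascending sigma_psiphi first, then structure_id lexicographic
  expect_equal(report$structure_id, c("mid", "alpha", "zeta"))
  expect_equal(report$rank_a, c(1L, 1L, 1L))
})

test_that("run configurations round-trip through YAML", {
  d <- withr::local_tempdir()
  run_simulate(d, n_decoys = 2, seed = 3)
  cfg <- compare_config(
    assignment = file.path(d, "observed_shifts.str"),
    structures_dir = file.path(d, "structures"),
    pred_shifts_dir = file.path(d, "pred_shifts"),
    talos = file.path(d, "observed_torsions.tab"),
    out_dir = file.path(d, "out"), circular = FALSE, epsilon_s = 0.05
  )
  path <- file.path(d, "config.yaml")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)
})
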