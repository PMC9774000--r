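toy_pair <- function() {
  # CA diffs 0.5 and 1.0 ppm, CB diffs 0.25 and 0.25 ppm
  nmr <- shift_tbl(data.frame(
    residue_number = c(1, 1, 2, 2), residue_type = "A",
    atom_name = c("CA", "CB", "CA", "CB"),
    shift = c(52.0, 19.0, 53.0, 20.0)
  ), "NMR")
  cal <- shift_tbl(data.frame(
    residue_number = c(1, 1, 2, 2), residue_type = "A",
    atom_name = c("CA", "CB", "CA", "CB"),
    shift = c(52.5, 19.25, 54.0, 20.25)
  ), "Cal:toy")
  list(nmr = nmr, cal = cal)
}

test_that("residue matching intersects coverage and applies atom flags", {
  mk <- function(res, label, types = NULL) {
    types <- types %||% rep("A", length(res))
    has_cb <- types != "G"
    shift_tbl(data.frame(
      residue_number = c(res, res[has_cb]),
      residue_type = c(types, types[has_cb]),
      atom_name = c(rep("CA", length(res)), rep("CB", sum(has_cb))),
      shift = c(rep(55, length(res)), rep(35, sum(has_cb)))
    ), label)
  }
  nmr <- mk(309:328, "NMR")
  cal <- mk(306:324, "Cal:x")
  m <- match_residues(nmr, cal, ambiguous_policy = "both")
  expect_equal(m$residue_number[m$nmr_ca & m$cal_ca], 309:324)

  # glycine at a matched position: CA term for the shift metric, no S term
  nmr_g <- mk(1:3, "NMR", types = c("A", "G", "A"))
  cal_g <- mk(1:3, "Cal:x", types = c("A", "G", "A"))
  mg <- match_residues(nmr_g, cal_g, ambiguous_policy = "both")
  row <- mg[mg$residue_number == 2, ]
  expect_true(row$nmr_ca && row$cal_ca)
  expect_false(row$nmr_s || row$cal_s)
  expect_equal(sigma_cs(nmr_g, cal_g, mg)$n, 3)
  expect_equal(sigma_a(secondary_shifts(nmr_g), secondary_shifts(cal_g), mg)$n, 2)
})

test_that("the ambiguous-PGGG policies include and exclude the right residues", {
  tab <- synthetic_assignment()
  m_ex <- match_residues(tab, tab, ambiguous_policy = "exclude")
  expect_false(any(ambiguous_pggg_residues() %in% m_ex$residue_number))
  m_332 <- match_residues(tab, tab, ambiguous_policy = "assign-to-332")
  expect_true(all(332:335 %in% m_332$residue_number))
  expect_false(any(364:367 %in% m_332$residue_number))
  m_364 <- match_residues(tab, tab, ambiguous_policy = "assign-to-364")
  expect_true(all(364:367 %in% m_364$residue_number))
  expect_false(any(332:335 %in% m_364$residue_number))
  m_both <- match_residues(tab, tab, ambiguous_policy = "both")
  expect_true(all(ambiguous_pggg_residues() %in% m_both$residue_number))
})

test_that("the chemical-shift metric and per-residue diagnostic match hand values", {
  p <- toy_pair()
  m <- match_residues(p$nmr, p$cal, ambiguous_policy = "both")
  cs <- sigma_cs(p$nmr, p$cal, m)
  expect_equal(cs$value, 2.0, tolerance = 1e-12)
  expect_equal(cs$n, 2)
  d <- delta_alphabeta(p$nmr, p$cal, m)
  expect_equal(d$delta_ab, c(0.75, 1.25), tolerance = 1e-12)
  # identity annihilation
  expect_equal(sigma_cs(p$nmr, p$nmr, m)$value, 0)
  expect_equal(delta_alphabeta(p$nmr, p$nmr, m)$delta_ab, c(0, 0))
})

test_that("the sign-disagreement count matches its two-branch definition", {
  nmr <- secondary_shifts(shifts_with_s(1:3, c(-1, -2, 0.5), "NMR"))
  cal <- secondary_shifts(shifts_with_s(1:3, c(1, -2, -1), "Cal:x"))
  m <- make_matched(1:3)
  sa <- sigma_a(nmr, cal, m)
  expect_equal(sa$value, 2)   # products: -1 < 0, +4 >= 0, -0.5 < 0
  expect_equal(sa$n, 3)
  # a zero S on either side is a zero product, counted as agreement
  nmr0 <- secondary_shifts(shifts_with_s(1:2, c(0, 0), "NMR"))
  cal0 <- secondary_shifts(shifts_with_s(1:2, c(-3, 3), "Cal:x"))
  expect_equal(sigma_a(nmr0, cal0, make_matched(1:2))$value, 0)
  expect_equal(sigma_a(nmr, nmr, m)$value, 0)
})

test_that("dihedral differences wrap circularly by default", {
  mk <- function(phi, psi, label) torsion_tbl(
    data.frame(residue_number = 1, residue_type = "A", phi = phi, psi = psi),
    label
  )
  m <- make_matched(1)
  a <- mk(170, 60, "NMR"); b <- mk(-170, 60, "Cal:x")
  expect_equal(sigma_psiphi(a, b, m)$value, 20, tolerance = 1e-12)
  expect_equal(sigma_psiphi(a, b, m, circular = FALSE)$value, 340,
               tolerance = 1e-12)
  expect_equal(sigma_psiphi(a, a, m)$value, 0)
})

test_that("metrics are symmetric, bounded, and shift-invariant", {
  for (seed in c(1, 2, 3)) {
    p <- random_shift_pair(seed)
    t <- random_torsion_pair(seed + 100)
    m <- match_residues(p$nmr, p$cal, t$nmr, t$cal, ambiguous_policy = "both")
    rc <- random_coil_shifts()
    pn <- secondary_shifts(p$nmr, rc); pc <- secondary_shifts(p$cal, rc)

    expect_equal(sigma_cs(p$nmr, p$cal, m)$value,
                 sigma_cs(p$cal, p$nmr, m)$value, tolerance = 1e-12)
    expect_equal(sigma_a(pn, pc, m)$value, sigma_a(pc, pn, m)$value)
    expect_equal(sigma_psiphi(t$nmr, t$cal, m)$value,
                 sigma_psiphi(t$cal, t$nmr, m)$value, tolerance = 1e-12)

    sa <- sigma_a(pn, pc, m)
    expect_gte(sa$value, 0)
    expect_lte(sa$value, sa$n)
    pp <- sigma_psiphi(t$nmr, t$cal, m)
    expect_lte(pp$value, 360 * pp$n)

    # adding a constant to all shifts of both tables leaves the metric fixed
    bump <- function(tab) {
      tab2 <- tibble::as_tibble(tab)
      tab2$shift <- tab2$shift + 3.7
      shift_tbl(tab2, source_label(tab))
    }
    expect_equal(sigma_cs(bump(p$nmr), bump(p$cal), m)$value,
                 sigma_cs(p$nmr, p$cal, m)$value, tolerance = 1e-9)
  }
})

test_that("ranking reproduces the published panel ordering logic", {
  # the published comparison table for the tau(297-391)+DTT assignment
  panel <- tibble::tibble(
    structure_id = c("7p6d", "7qjv", "7mkg", "5o3o", "7mkf", "7nrs", "7nrt",
                     "7nrx", "5o3t", "7p6e", "7p6c"),
    sigma_cs = c(65.8414, 73.6912, 62.9429, 74.1779, 71.8944, 74.7738,
                 74.9086, 83.0367, 88.8657, 97.3397, 69.0672),
    n_cs = NA_integer_,
    sigma_a = c(4L, 4L, 5L, 5L, 6L, 6L, 6L, 6L, 6L, 6L, 7L),
    n_a = NA_integer_,
    sigma_psiphi = c(3648, 3361, 2848, 3146, 2883, 2986, 2987, 2972, 3827,
                     3786, 2661),
    n_psiphi = NA_integer_,
    fold_label = c("AGD", "AD", "AD", "AD", "AD", "AD", "AD", "AD", "AD",
                   "AGD", "LNT")
  )
  rep <- rank_structures(panel)
  expect_equal(rep$structure_id[rep$rank_cs == 1], "7mkg")
  expect_equal(rep$structure_id[rep$rank_psiphi == 1], "7p6c")
  expect_setequal(rep$structure_id[rep$rank_a == 1], c("7p6d", "7qjv"))
  # sorted by sign disagreements; the tied leaders ordered by dihedral metric
  expect_equal(rep$structure_id[1:2], c("7qjv", "7p6d"))
  expect_true(all(diff(rep$sigma_a) >= 0))
  # each rank column is min-tie ranks over its metric
  expect_equal(sort(unique(rep$rank_cs)), 1:11)

  single <- rank_structures(panel[1, ])
  expect_equal(single$rank_cs, 1L)
  expect_equal(single$rank_a, 1L)
  expect_equal(single$rank_psiphi, 1L)
})

test_that("metrics agree with brute-force oracles on random paired tables", {
  rc <- random_coil_shifts()
  for (seed in 1:25) {
    p <- random_shift_pair(seed)
    t <- random_torsion_pair(seed + 1000)
    m <- match_residues(p$nmr, p$cal, t$nmr, t$cal, ambiguous_policy = "both")
    cs <- sigma_cs(p$nmr, p$cal, m)
    ocs <- oracle_sigma_cs(p$nmr, p$cal, m)
    expect_equal(cs$value, ocs$value, tolerance = 1e-9)
    expect_equal(cs$n, ocs$n)

    pn <- secondary_shifts(p$nmr, rc); pc <- secondary_shifts(p$cal, rc)
    sa <- sigma_a(pn, pc, m)
    osa <- oracle_sigma_a(pn, pc, m)
    expect_equal(sa$value, osa$value)
    expect_equal(sa$n, osa$n)

    for (circ in c(TRUE, FALSE)) {
      pp <- sigma_psiphi(t$nmr, t$cal, m, circular = circ)
      opp <- oracle_sigma_psiphi(t$nmr, t$cal, m, circular = circ)
      expect_equal(pp$value, opp$value, tolerance = 1e-9)
      expect_equal(pp$n, opp$n)
    }

    d <- delta_alphabeta(p$nmr, p$cal, m)
    od <- oracle_delta_ab(p$nmr, p$cal, m)
    expect_equal(stats::setNames(d$delta_ab, d$residue_number), od,
                 tolerance = 1e-9)
    expect_equal(sum(d$delta_ab), cs$value)  # exact algebraic identity
  }
})
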