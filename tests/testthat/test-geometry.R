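test_that("PDB reading returns exact coordinates for the requested chain", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  m <- read_structure(path, chain_id = "A")
  expect_equal(dplyr::n_distinct(m$residue_number), 3)
  expect_equal(m$x[m$residue_number == 1 & m$atom_name == "CA"], 1.458)
  expect_equal(m$residue_type[m$residue_number == 2][1], "G")

  b <- read_structure(path, chain_id = "B")
  expect_equal(unique(b$residue_number), 1L)
  expect_equal(unique(b$residue_type), "V")

  expect_error(read_structure(path, chain_id = "Z"), "available: A, B")
})

test_that("torsions are refused across a chain break", {
  ok <- withr::local_tempfile(fileext = ".pdb")
  broken <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(ok)
  write_tiny_pdb(broken, gap = TRUE)
  # 3 contiguous residues: exactly the middle one has both angles
  t_ok <- compute_torsions(read_structure(ok))
  expect_equal(nrow(t_ok), 1)
  expect_equal(t_ok$residue_number, 2L)
  # with a 5 A C-N gap before residue 3, no residue has both angles,
  # but both residues flanking the gap are still present in the model
  m_broken <- read_structure(broken)
  expect_setequal(unique(m_broken$residue_number), 1:3)
  expect_equal(nrow(compute_torsions(m_broken)), 0)
})

test_that("dihedral_angle follows the stated sign and range conventions", {
  # ideal planar trans arrangement: |angle| = 180, reported as +180
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  # reference quadruple fixes the sign convention
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               90)
  # invariant under reversing the point order (standard torsion property);
  # mirror reflection is what flips the sign
  expect_equal(dihedral_angle(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0)),
               90)
  mirror <- function(p) c(p[1], p[2], -p[3])
  expect_equal(dihedral_angle(mirror(c(0, 0, 0)), mirror(c(1, 0, 0)),
                              mirror(c(1, 1, 0)), mirror(c(1, 1, 1))),
               -90)
  # collinear degenerate input is a geometry error
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral_angle matches the acos-based oracle on random quadruples", {
  withr::with_seed(42, {
    for (i in 1:300) {
      p <- matrix(stats::rnorm(12, sd = 3), nrow = 4)
      got <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                      error = function(e) NA_real_)
      if (is.na(got)) next
      want <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("dihedral_angle is invariant under rigid motions", {
  random_rotation <- function() {
    m <- matrix(stats::rnorm(9), 3)
    qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))  # proper rotation
  }
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- matrix(stats::rnorm(12, sd = 2), nrow = 4)
      base <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                       error = function(e) NA_real_)
      if (is.na(base)) next
      q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      shift <- stats::rnorm(3, sd = 10)
      pt <- t(q %*% t(p)) + matrix(shift, 4, 3, byrow = TRUE)
      expect_equal(dihedral_angle(pt[1, ], pt[2, ], pt[3, ], pt[4, ]),
                   base, tolerance = 1e-9)
    }
  })
})

test_that("compute_torsions inverts the backbone builder", {
  strand <- torsion_program(
    data.frame(start = 1, end = 10, phi = -135, psi = 135, label = "strand"),
    sequence = "AKVLEGSTYN"
  )
  t1 <- compute_torsions(generate_backbone(strand))
  expect_equal(nrow(t1), 8)  # termini carry no complete phi/psi pair
  expect_equal(t1$phi, rep(-135, 8), tolerance = 1e-6)
  expect_equal(t1$psi, rep(135, 8), tolerance = 1e-6)

  helix <- torsion_program(
    data.frame(start = 1, end = 12, phi = -57, psi = -47, label = "helix"),
    sequence = "AKVLEGSTYNQW"
  )
  t2 <- compute_torsions(generate_backbone(helix))
  expect_equal(t2$phi, rep(-57, 10), tolerance = 1e-6)
  expect_equal(t2$psi, rep(-47, 10), tolerance = 1e-6)

  # a 3-residue model yields exactly one residue with both angles
  tiny <- torsion_program(
    data.frame(start = 1, end = 3, phi = -100, psi = 100, label = "coil"),
    sequence = "AKV"
  )
  expect_equal(nrow(compute_torsions(generate_backbone(tiny))), 1)
})

test_that("builder/torsion round-trip holds for arbitrary programs", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n_seg <- sample(2:4, 1)
      lens <- sample(3:6, n_seg, replace = TRUE)
      ends <- cumsum(lens)
      starts <- c(1, head(ends, -1) + 1)
      prog <- torsion_program(
        data.frame(
          start = starts, end = ends,
          phi = stats::runif(n_seg, -175, 175),
          psi = stats::runif(n_seg, -175, 175),
          label = sample(c("strand", "helix", "kink", "coil"), n_seg,
                         replace = TRUE)
        ),
        sequence = sample(AA_NO_G, sum(lens), replace = TRUE)
      )
      got <- compute_torsions(generate_backbone(prog))
      want <- program_residues(prog)
      j <- match(got$residue_number, want$residue_number)
      expect_equal(got$phi, want$phi[j], tolerance = 1e-6)
      expect_equal(got$psi, want$psi[j], tolerance = 1e-6)
    }
  })
})

test_that("torsions agree with an independent structural-biology library", {
  prog <- tau_truth_program()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(generate_backbone(prog), path)
  ours <- compute_torsions(read_structure(path))
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(path))
  want <- program_residues(prog)
  # bio3d tables are keyed by residue label; compare against the program
  j <- match(ours$residue_number, want$residue_number)
  expect_lt(max(abs(ours$phi - want$phi[j])), 0.1)  # PDB file is 3-decimal
  phi_ref <- ref$phi[!is.na(ref$phi)]
  expect_equal(sort(unique(round(want$phi))), sort(unique(round(phi_ref))))
})
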