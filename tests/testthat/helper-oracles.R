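# Independent brute-force oracles. These are deliberately coded on a
# different path from the package internals (explicit loops, acos-based
# torsions) and are only ever used as the expected side of a comparison.

oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# torsion via acos of the two plane normals, sign from the rotation sense
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- oracle_cross(b1, b2)
  n2 <- oracle_cross(b2, b3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  s <- sign(sum(oracle_cross(n1, n2) * b2))
  out <- if (s < 0) -ang else ang
  if (out <= -180) out <- out + 360
  if (out == -180) out <- 180
  out
}

# per-residue looped summation of the chemical-shift metric
oracle_sigma_cs <- function(nmr, cal, matched) {
  total <- 0
  n <- 0
  for (i in seq_len(nrow(matched))) {
    r <- matched$residue_number[i]
    contributed <- FALSE
    for (atom in c("CA", "CB")) {
      a <- nmr$shift[nmr$residue_number == r & nmr$atom_name == atom]
      b <- cal$shift[cal$residue_number == r & cal$atom_name == atom]
      if (length(a) == 1 && length(b) == 1) {
        total <- total + abs(b - a)
        contributed <- TRUE
      }
    }
    if (contributed) n <- n + 1
  }
  list(value = total, n = n)
}

oracle_delta_ab <- function(nmr, cal, matched) {
  out <- numeric(0)
  for (i in seq_len(nrow(matched))) {
    r <- matched$residue_number[i]
    d <- 0
    contributed <- FALSE
    for (atom in c("CA", "CB")) {
      a <- nmr$shift[nmr$residue_number == r & nmr$atom_name == atom]
      b <- cal$shift[cal$residue_number == r & cal$atom_name == atom]
      if (length(a) == 1 && length(b) == 1) {
        d <- d + abs(b - a)
        contributed <- TRUE
      }
    }
    if (contributed) out[as.character(r)] <- d
  }
  out
}

# looped sign-product count over residues with S on both sides
oracle_sigma_a <- function(nmr_prof, cal_prof, matched) {
  value <- 0
  n <- 0
  for (i in seq_len(nrow(matched))) {
    r <- matched$residue_number[i]
    sn <- nmr_prof$s_value[nmr_prof$residue_number == r]
    sc <- cal_prof$s_value[cal_prof$residue_number == r]
    if (length(sn) == 1 && length(sc) == 1 && !is.na(sn) && !is.na(sc)) {
      n <- n + 1
      if (sc * sn < 0) value <- value + 1
    }
  }
  list(value = value, n = n)
}

# looped dihedral-difference sum; circular difference spelled out
oracle_sigma_psiphi <- function(nmr_t, cal_t, matched, circular = TRUE) {
  dd <- function(a, b) {
    if (!circular) return(abs(a - b))
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  value <- 0
  n <- 0
  for (i in seq_len(nrow(matched))) {
    r <- matched$residue_number[i]
    jn <- which(nmr_t$residue_number == r)
    jc <- which(cal_t$residue_number == r)
    if (length(jn) == 1 && length(jc) == 1) {
      value <- value + dd(cal_t$phi[jc], nmr_t$phi[jn]) +
        dd(cal_t$psi[jc], nmr_t$psi[jn])
      n <- n + 1
    }
  }
  list(value = value, n = n)
}
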