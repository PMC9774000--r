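#' Match residues between the assignment and a candidate structure
#'
#' The strain metrics are sums "over every assigned residue", so each needs to
#' know, residue by residue, which quantities exist on both the observed (NMR)
#' and calculated (structure) side. `match_residues()` builds that eligibility
#' table: one row per assigned residue with presence flags for Calpha/Cbeta
#' shifts, an S value, and a phi/psi pair on each side.
#'
#' Ambiguously assigned residues — for tau(297-391) the PGGG repeats that
#' could not be placed uniquely at P332-G335 or P364-G367 — are handled by
#' `ambiguous_policy`:
#' \describe{
#'   \item{exclude}{drop every ambiguous residue from all metrics (default;
#'     the assignment cannot place them).}
#'   \item{assign-to-332}{keep the first candidate placement, drop the second.}
#'   \item{assign-to-364}{keep the second, drop the first.}
#'   \item{both}{keep all ambiguous residues.}
#' }
#'
#' @param nmr_shifts,cal_shifts [shift_tbl()]s for the two sides.
#' @param nmr_torsions,cal_torsions optional [torsion_tbl()]s.
#' @param ambiguous_policy see above.
#' @param ambiguous_residues integer residue numbers subject to the policy;
#'   defaults to [ambiguous_pggg_residues()].
#' @return a `matched_residues` tibble with logical flag columns and attribute
#'   `mask_label` describing the policy applied.
#' @export
match_residues <- function(nmr_shifts, cal_shifts,
                           nmr_torsions = NULL, cal_torsions = NULL,
                           ambiguous_policy = c("exclude", "assign-to-332",
                                                "assign-to-364", "both"),
                           ambiguous_residues = ambiguous_pggg_residues()) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(inherits(nmr_shifts, "shift_tbl"), inherits(cal_shifts, "shift_tbl"))

  residues <- sort(unique(c(
    nmr_shifts$residue_number,
    if (!is.null(nmr_torsions)) nmr_torsions$residue_number
  )))
  drop <- switch(ambiguous_policy,
    "exclude" = ambiguous_residues,
    "assign-to-332" = ambiguous_residues[ambiguous_residues >= 350],
    "assign-to-364" = ambiguous_residues[ambiguous_residues < 350],
    "both" = integer()
  )
  residues <- setdiff(residues, drop)
  if (length(residues) == 0) {
    stop("no residues left after matching; check numbering frames",
         call. = FALSE)
  }

  has_atom <- function(tab, atom) residues %in%
    tab$residue_number[tab$atom_name == atom]
  has_s <- function(tab) {
    prof <- secondary_shift_presence(tab)
    residues %in% prof
  }
  has_tors <- function(tab) {
    if (is.null(tab)) rep(FALSE, length(residues))
    else residues %in% tab$residue_number[is.finite(tab$phi) & is.finite(tab$psi)]
  }

  out <- tibble::tibble(
    residue_number = residues,
    nmr_ca = has_atom(nmr_shifts, "CA"),
    nmr_cb = has_atom(nmr_shifts, "CB"),
    cal_ca = has_atom(cal_shifts, "CA"),
    cal_cb = has_atom(cal_shifts, "CB"),
    nmr_s = has_s(nmr_shifts),
    cal_s = has_s(cal_shifts),
    nmr_phi_psi = has_tors(nmr_torsions),
    cal_phi_psi = has_tors(cal_torsions)
  )
  if (!any(out$nmr_ca & out$cal_ca) && !any(out$nmr_cb & out$cal_cb) &&
      !any(out$nmr_phi_psi & out$cal_phi_psi)) {
    stop("empty residue intersection between NMR and calculated tables",
         call. = FALSE)
  }
  attr(out, "mask_label") <- paste0("ambiguous=", ambiguous_policy)
  class(out) <- c("matched_residues", class(out))
  out
}

# residues of a shift table that will carry an s_value (CA and CB both present)
secondary_shift_presence <- function(tab) {
  ca <- tab$residue_number[tab$atom_name == "CA"]
  cb <- tab$residue_number[tab$atom_name == "CB"]
  intersect(ca, cb)
}

shift_lookup <- function(tab, atom) {
  sub <- tab[tab$atom_name == atom, ]
  stats::setNames(sub$shift, sub$residue_number)
}

# per-residue |Cal - NMR| CA and CB terms honouring eligibility flags
cs_terms <- function(nmr, cal, matched, partial = TRUE) {
  nmr_ca <- shift_lookup(nmr, "CA"); cal_ca <- shift_lookup(cal, "CA")
  nmr_cb <- shift_lookup(nmr, "CB"); cal_cb <- shift_lookup(cal, "CB")
  key <- as.character(matched$residue_number)
  ca_ok <- matched$nmr_ca & matched$cal_ca
  cb_ok <- matched$nmr_cb & matched$cal_cb
  if (!partial) {
    # strict mode: a residue contributes only with its full complement of
    # matched atoms (CA+CB, or CA alone for glycine-like CB-less residues)
    full <- ca_ok & (cb_ok | (!matched$nmr_cb & !matched$cal_cb))
    ca_ok <- ca_ok & full
    cb_ok <- cb_ok & full
  }
  ca_term <- ifelse(ca_ok, abs(cal_ca[key] - nmr_ca[key]), NA_real_)
  cb_term <- ifelse(cb_ok, abs(cal_cb[key] - nmr_cb[key]), NA_real_)
  tibble::tibble(
    residue_number = matched$residue_number,
    ca_term = unname(ca_term), cb_term = unname(cb_term)
  )
}

#' Summed absolute Calpha/Cbeta chemical-shift difference
#'
#' The chemical-shift strain metric: over every matched residue i, the sum of
#' `|dCA_cal(i) - dCA_nmr(i)| + |dCB_cal(i) - dCB_nmr(i)|` in ppm. Smaller
#' values mean the candidate structure's predicted shifts resemble the
#' measured assignment more closely.
#'
#' @param nmr,cal [shift_tbl()]s.
#' @param matched a [match_residues()] table.
#' @param partial if `TRUE` (default) a residue missing one atom on either
#'   side still contributes the other atom's term; if `FALSE` such residues
#'   are dropped entirely.
#' @return one-row tibble with `value` (ppm) and `n` (residues contributing
#'   at least one term).
#' @export
sigma_cs <- function(nmr, cal, matched, partial = TRUE) {
  terms <- cs_terms(nmr, cal, matched, partial = partial)
  contributes <- !is.na(terms$ca_term) | !is.na(terms$cb_term)
  if (!any(contributes)) {
    stop("no residues eligible for the chemical-shift metric", call. = FALSE)
  }
  # summed residue by residue, in the same order as delta_alphabeta(), so
  # the per-residue diagnostic sums to this value bit-exactly
  per_res <- dplyr::coalesce(terms$ca_term, 0) + dplyr::coalesce(terms$cb_term, 0)
  tibble::tibble(value = sum(per_res[contributes]), n = sum(contributes))
}

#' Count of secondary-shift sign disagreements
#'
#' For every residue with an S value (`delta_ca - delta_cb`) on both sides,
#' scores 1 when the signs disagree (`S_cal * S_nmr < 0`) and 0 otherwise —
#' a zero product, including exact zeros, counts as agreement. Because the
#' sign of S flags helical vs extended conformation, this metric counts the
#' residues where the candidate structure places a kink (or strand) that the
#' assignment contradicts.
#'
#' @param nmr_profile,cal_profile `secondary_shift_tbl`s from
#'   [secondary_shifts()].
#' @param matched a [match_residues()] table.
#' @param epsilon_s dead-band forwarded to [classify_sign()].
#' @return one-row tibble with `value` (disagreement count) and `n`
#'   (eligible residues).
#' @export
sigma_a <- function(nmr_profile, cal_profile, matched, epsilon_s = 0) {
  s_nmr <- stats::setNames(nmr_profile$s_value,
                           nmr_profile$residue_number)
  s_cal <- stats::setNames(cal_profile$s_value,
                           cal_profile$residue_number)
  key <- as.character(matched$residue_number)
  ok <- matched$nmr_s & matched$cal_s &
    !is.na(s_nmr[key]) & !is.na(s_cal[key])
  if (!any(ok)) {
    stop("no residues eligible for the sign-comparison metric", call. = FALSE)
  }
  sn <- s_nmr[key][ok]; sc <- s_cal[key][ok]
  if (epsilon_s > 0) {
    sn[abs(sn) < epsilon_s] <- 0
    sc[abs(sc) < epsilon_s] <- 0
  }
  tibble::tibble(value = sum(sc * sn < 0), n = sum(ok))
}

#' Summed absolute phi/psi dihedral difference
#'
#' Over every residue with a phi/psi pair on both sides, the sum of
#' `|phi_cal - phi_nmr| + |psi_cal - psi_nmr|` in degrees. By default each
#' difference is the minimal circular difference in \[0, 180\] — a 170 vs
#' -170 degree pair is a 20 degree discrepancy, not 340 — with
#' `circular = FALSE` reproducing naive absolute differences on raw values
#' for sensitivity checks.
#'
#' @param nmr_torsions,cal_torsions [torsion_tbl()]s.
#' @param matched a [match_residues()] table.
#' @param circular use minimal circular differences (default `TRUE`).
#' @return one-row tibble with `value` (degrees) and `n`.
#' @export
sigma_psiphi <- function(nmr_torsions, cal_torsions, matched, circular = TRUE) {
  key <- as.character(matched$residue_number)
  phi_n <- stats::setNames(nmr_torsions$phi, nmr_torsions$residue_number)
  psi_n <- stats::setNames(nmr_torsions$psi, nmr_torsions$residue_number)
  phi_c <- stats::setNames(cal_torsions$phi, cal_torsions$residue_number)
  psi_c <- stats::setNames(cal_torsions$psi, cal_torsions$residue_number)
  ok <- matched$nmr_phi_psi & matched$cal_phi_psi &
    !is.na(phi_n[key]) & !is.na(phi_c[key])
  if (!any(ok)) {
    stop("no residues eligible for the dihedral metric", call. = FALSE)
  }
  k <- key[ok]
  if (circular) {
    d <- circular_abs_diff(phi_c[k], phi_n[k]) +
      circular_abs_diff(psi_c[k], psi_n[k])
  } else {
    d <- abs(phi_c[k] - phi_n[k]) + abs(psi_c[k] - psi_n[k])
  }
  tibble::tibble(value = sum(d), n = sum(ok))
}

#' Per-residue Calpha/Cbeta chemical-shift difference
#'
#' The per-residue diagnostic behind the chemical-shift metric:
#' `|dCA_cal - dCA_nmr| + |dCB_cal - dCB_nmr|` for each matched residue, the
#' quantity used to color residues of a structure by local (dis)agreement
#' with the assignment. Its sum over residues equals the chemical-shift
#' metric exactly.
#'
#' @inheritParams sigma_cs
#' @return tibble with `residue_number` and `delta_ab` (ppm), one row per
#'   contributing residue.
#' @export
delta_alphabeta <- function(nmr, cal, matched, partial = TRUE) {
  terms <- cs_terms(nmr, cal, matched, partial = partial)
  contributes <- !is.na(terms$ca_term) | !is.na(terms$cb_term)
  terms <- terms[contributes, ]
  tibble::tibble(
    residue_number = terms$residue_number,
    delta_ab = dplyr::coalesce(terms$ca_term, 0) +
      dplyr::coalesce(terms$cb_term, 0)
  )
}

#' Rank candidate structures by the three strain metrics
#'
#' Takes one row per candidate structure with the metric values and attaches
#' independent rank columns (ascending; minimal value = rank 1; ties share
#' the smaller rank). The output rows are sorted the way the strain
#' comparison table is presented: ascending by the sign-disagreement count,
#' ties broken by ascending dihedral difference, then by `structure_id`.
#'
#' @param metrics data frame with columns `structure_id`, `sigma_cs`, `n_cs`,
#'   `sigma_a`, `n_a`, `sigma_psiphi`, `n_psiphi` and optionally `fold_label`.
#'   Missing metric columns are allowed and yield NA ranks.
#' @return a `metric_report` tibble with added `rank_cs`, `rank_a`,
#'   `rank_psiphi` columns, sorted as above.
#' @export
rank_structures <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  if (nrow(metrics) == 0 || !"structure_id" %in% names(metrics)) {
    stop("metrics must have >= 1 row and a structure_id column", call. = FALSE)
  }
  if (anyDuplicated(metrics$structure_id)) {
    stop("duplicate structure_id in metrics", call. = FALSE)
  }
  rk <- function(x) {
    if (is.null(x)) return(rep(NA_integer_, nrow(metrics)))
    as.integer(rank(x, ties.method = "min"))
  }
  metrics$rank_cs <- rk(metrics$sigma_cs)
  metrics$rank_a <- rk(metrics$sigma_a)
  metrics$rank_psiphi <- rk(metrics$sigma_psiphi)
  ord <- order(metrics$sigma_a %||% rep(0, nrow(metrics)),
               metrics$sigma_psiphi %||% rep(0, nrow(metrics)),
               metrics$structure_id)
  out <- metrics[ord, ]
  class(out) <- c("metric_report", class(out))
  out
}

#' Metric values under all convention variants
#'
#' The published definition of the metrics leaves three conventions open:
#' circular vs naive dihedral differencing, partial vs strict handling of
#' residues missing one of CA/CB, and the placement policy for ambiguously
#' assigned residues. This helper recomputes all three metrics under every
#' combination so a reproduction run can locate which conventions an external
#' reference used.
#'
#' @inheritParams match_residues
#' @param rc random-coil reference for the secondary-shift sides.
#' @return tibble with one row per (circular, partial, ambiguous_policy)
#'   combination and the metric values/counts.
#' @export
metric_variants <- function(nmr_shifts, cal_shifts,
                            nmr_torsions = NULL, cal_torsions = NULL,
                            rc = random_coil_shifts(),
                            ambiguous_residues = ambiguous_pggg_residues()) {
  nmr_prof <- secondary_shifts(nmr_shifts, rc)
  cal_prof <- secondary_shifts(cal_shifts, rc)
  grid <- tidyr::expand_grid(
    ambiguous_policy = c("exclude", "assign-to-332", "assign-to-364", "both"),
    circular = c(TRUE, FALSE),
    partial = c(TRUE, FALSE)
  )
  purrr::pmap_dfr(grid, function(ambiguous_policy, circular, partial) {
    m <- match_residues(nmr_shifts, cal_shifts, nmr_torsions, cal_torsions,
                        ambiguous_policy = ambiguous_policy,
                        ambiguous_residues = ambiguous_residues)
    cs <- sigma_cs(nmr_shifts, cal_shifts, m, partial = partial)
    sa <- sigma_a(nmr_prof, cal_prof, m)
    pp <- if (!is.null(nmr_torsions) && !is.null(cal_torsions)) {
      sigma_psiphi(nmr_torsions, cal_torsions, m, circular = circular)
    } else {
      tibble::tibble(value = NA_real_, n = NA_integer_)
    }
    tibble::tibble(
      ambiguous_policy = ambiguous_policy, circular = circular,
      partial = partial,
      sigma_cs = cs$value, n_cs = cs$n,
      sigma_a = sa$value, n_a = sa$n,
      sigma_psiphi = pp$value, n_psiphi = pp$n
    )
  })
}
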