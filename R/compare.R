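#' Compare an assignment against a panel of candidate structures
#'
#' The in-memory core of the pipeline: given one observed shift table (and
#' optionally observed torsions), and per-candidate predicted shift tables
#' (and optionally candidate torsions), computes the three strain metrics and
#' the per-residue diagnostic for every candidate and returns the ranked
#' report.
#'
#' @param nmr_shifts observed [shift_tbl()].
#' @param cal_shifts named list of predicted [shift_tbl()]s, one per
#'   candidate structure (names are the structure ids).
#' @param nmr_torsions optional observed [torsion_tbl()].
#' @param cal_torsions optional named list of candidate [torsion_tbl()]s;
#'   names must match `cal_shifts` where present.
#' @param rc random-coil reference.
#' @param ambiguous_policy,ambiguous_residues forwarded to
#'   [match_residues()].
#' @param circular forwarded to [sigma_psiphi()].
#' @param partial forwarded to [sigma_cs()].
#' @param epsilon_s forwarded to [sigma_a()].
#' @param fold_labels optional named character vector of fold annotations.
#' @return a `metric_report` (see [rank_structures()]) with a `delta_ab`
#'   list-column holding each candidate's per-residue table.
#' @export
compare_panel <- function(nmr_shifts, cal_shifts,
                          nmr_torsions = NULL, cal_torsions = NULL,
                          rc = random_coil_shifts(),
                          ambiguous_policy = "exclude",
                          ambiguous_residues = ambiguous_pggg_residues(),
                          circular = TRUE, partial = TRUE, epsilon_s = 0,
                          fold_labels = NULL) {
  stopifnot(inherits(nmr_shifts, "shift_tbl"), is.list(cal_shifts),
            length(cal_shifts) >= 1, !is.null(names(cal_shifts)))
  nmr_prof <- secondary_shifts(nmr_shifts, rc)
  rows <- purrr::imap_dfr(cal_shifts, function(cal, id) {
    cal_tors <- cal_torsions[[id]]
    m <- match_residues(nmr_shifts, cal, nmr_torsions, cal_tors,
                        ambiguous_policy = ambiguous_policy,
                        ambiguous_residues = ambiguous_residues)
    cs <- sigma_cs(nmr_shifts, cal, m, partial = partial)
    sa <- sigma_a(nmr_prof, secondary_shifts(cal, rc), m,
                  epsilon_s = epsilon_s)
    pp <- if (!is.null(nmr_torsions) && !is.null(cal_tors)) {
      sigma_psiphi(nmr_torsions, cal_tors, m, circular = circular)
    } else {
      tibble::tibble(value = NA_real_, n = NA_integer_)
    }
    tibble::tibble(
      structure_id = id,
      sigma_cs = cs$value, n_cs = cs$n,
      sigma_a = sa$value, n_a = sa$n,
      sigma_psiphi = pp$value, n_psiphi = pp$n,
      delta_ab = list(delta_alphabeta(nmr_shifts, cal, m, partial = partial))
    )
  })
  if (!is.null(fold_labels)) {
    rows$fold_label <- unname(fold_labels[rows$structure_id])
  }
  rank_structures(rows)
}
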