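#' Random-coil Calpha/Cbeta reference shifts
#'
#' Secondary chemical shifts are observed shifts minus the residue-type
#' random-coil reference. The packaged default is the Wishart et al. (1995,
#' J. Biomol. NMR 5, 67-81) random-coil set (DSS-referenced, ppm); glycine
#' carries only a Calpha value. Any user table with columns `residue_type`,
#' `rc_ca`, `rc_cb` can be supplied instead — different published sets shift
#' individual secondary-shift values by small per-residue-type constants, so
#' the reference is pluggable everywhere it is consumed.
#'
#' @param path CSV with columns `residue_type, rc_ca, rc_cb`; default the
#'   packaged Wishart 1995 table.
#' @return a tibble with one row per standard amino acid and attribute
#'   `provenance_label`.
#' @export
#' @examples
#' random_coil_shifts()
random_coil_shifts <- function(path = NULL) {
  provenance <- if (is.null(path)) "Wishart1995" else basename(path)
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_wishart1995.csv",
                        package = "shiftstrain", mustWork = TRUE)
  }
  rc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_type", "rc_ca", "rc_cb")
  if (!all(need %in% names(rc))) {
    stop("random-coil table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rc <- tibble::as_tibble(rc)[need]
  rc$residue_type <- aa_one_letter(rc$residue_type)
  missing_aa <- setdiff(names(AA3), rc$residue_type)
  if (length(missing_aa) > 0) {
    stop("random-coil table lacks residue type(s): ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  }
  if (any(rc$residue_type == "G" & !is.na(rc$rc_cb))) {
    stop("glycine must not carry a random-coil CB value", call. = FALSE)
  }
  vals <- c(rc$rc_ca, rc$rc_cb[!is.na(rc$rc_cb)])
  if (any(vals < 10 | vals > 75)) {
    stop("random-coil values outside the plausible 10-75 ppm range",
         call. = FALSE)
  }
  attr(rc, "provenance_label") <- provenance
  rc
}

#' Secondary chemical shifts and the S statistic
#'
#' For each residue with a Calpha and/or Cbeta shift, subtracts the
#' random-coil reference to give the secondary shifts `delta_ca` and
#' `delta_cb`, and where both exist forms `s_value = delta_ca - delta_cb`.
#' The sign of S tracks secondary structure: positive in helices, negative in
#' extended (beta-strand) conformation. Glycines have no Cbeta, hence
#' `delta_cb` and `s_value` are absent for them.
#'
#' Both the observed assignment and each structure-predicted table pass
#' through this same function with the same reference set, so the two sides
#' of the sign-comparison metric live on a common scale.
#'
#' @param shifts a [shift_tbl()].
#' @param rc random-coil reference, see [random_coil_shifts()].
#' @return a `secondary_shift_tbl`: tibble with `residue_number`,
#'   `residue_type`, `delta_ca`, `delta_cb`, `s_value` (NA where undefined),
#'   inheriting the shift table's source label.
#' @export
secondary_shifts <- function(shifts, rc = random_coil_shifts()) {
  stopifnot(inherits(shifts, "shift_tbl"))
  unknown <- setdiff(unique(shifts$residue_type), rc$residue_type)
  if (length(unknown) > 0) {
    stop("residue type(s) absent from random-coil table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  wide <- shifts |>
    dplyr::filter(.data$atom_name %in% c("CA", "CB")) |>
    tidyr::pivot_wider(
      id_cols = c("residue_number", "residue_type"),
      names_from = "atom_name", values_from = "shift"
    )
  if (!"CA" %in% names(wide)) wide$CA <- NA_real_
  if (!"CB" %in% names(wide)) wide$CB <- NA_real_
  out <- wide |>
    dplyr::left_join(rc, by = "residue_type") |>
    dplyr::mutate(
      delta_ca = .data$CA - .data$rc_ca,
      delta_cb = .data$CB - .data$rc_cb,
      s_value = .data$delta_ca - .data$delta_cb
    ) |>
    dplyr::select("residue_number", "residue_type",
                  "delta_ca", "delta_cb", "s_value") |>
    dplyr::arrange(.data$residue_number)
  attr(out, "source_label") <- source_label(shifts)
  attr(out, "rc_provenance") <- attr(rc, "provenance_label")
  class(out) <- c("secondary_shift_tbl", class(out))
  out
}

#' Classify the sign of the S statistic per residue
#'
#' Maps each residue's `s_value` to +1 (helical tendency), -1 (extended) or
#' 0. Zero is returned inside the dead-band `|s_value| < epsilon_s` and for
#' residues without an S value (glycines, missing atoms). The strict default
#' `epsilon_s = 0` matches the sign-product definition of the disagreement
#' count; a nonzero dead-band exists for sensitivity analysis only.
#'
#' @param profile a `secondary_shift_tbl` from [secondary_shifts()].
#' @param epsilon_s dead-band half-width in ppm.
#' @return tibble with `residue_number` and integer `sign`.
#' @export
classify_sign <- function(profile, epsilon_s = 0) {
  stopifnot(inherits(profile, "secondary_shift_tbl"), epsilon_s >= 0)
  s <- profile$s_value
  sgn <- ifelse(is.na(s) | abs(s) < epsilon_s, 0L, as.integer(sign(s)))
  tibble::tibble(residue_number = profile$residue_number, sign = sgn)
}
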