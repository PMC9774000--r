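#' Write a metric report to CSV or JSON
#'
#' Serializes a ranked [rank_structures()] report with the fixed column set
#' `structure_id, sigma_cs_ppm, n_cs, sigma_a, n_a, sigma_psiphi_deg,
#' n_psiphi, rank_cs, rank_a, rank_psiphi` (plus `fold_label` when present),
#' in the report's deterministic row order. The per-residue `delta_ab`
#' list-column is not part of this file; see [write_delta_ab()].
#'
#' @param report a `metric_report`.
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path,
                                format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (nrow(report) == 0) stop("empty metric report", call. = FALSE)
  out <- tibble::as_tibble(report)
  out$delta_ab <- NULL
  rename <- c(sigma_cs = "sigma_cs_ppm", sigma_psiphi = "sigma_psiphi_deg")
  names(out)[match(names(rename), names(out))] <- rename
  cols <- c("structure_id", "sigma_cs_ppm", "n_cs", "sigma_a", "n_a",
            "sigma_psiphi_deg", "n_psiphi", "rank_cs", "rank_a", "rank_psiphi")
  if ("fold_label" %in% names(out)) cols <- c(cols, "fold_label")
  out <- out[cols]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a metric report written by [write_metric_report()]
#'
#' @param path CSV or JSON report path.
#' @return a `metric_report` tibble (without the per-residue list-column).
#' @export
read_metric_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  rename <- c(sigma_cs_ppm = "sigma_cs", sigma_psiphi_deg = "sigma_psiphi")
  names(x)[match(names(rename), names(x))] <- rename
  for (col in c("n_cs", "n_a", "n_psiphi", "rank_cs", "rank_a", "rank_psiphi")) {
    if (col %in% names(x)) x[[col]] <- as.integer(x[[col]])
  }
  class(x) <- c("metric_report", class(x))
  x
}

#' Write per-residue chemical-shift differences in tidy form
#'
#' One row per (structure, residue) with the per-residue diagnostic — the
#' plot-ready analogue of coloring a structure by local agreement.
#'
#' @param report a `metric_report` carrying the `delta_ab` list-column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_delta_ab <- function(report, path) {
  if (!"delta_ab" %in% names(report)) {
    stop("report lacks the delta_ab list-column", call. = FALSE)
  }
  long <- tidyr::unnest(
    tibble::as_tibble(report)[c("structure_id", "delta_ab")],
    "delta_ab"
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
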