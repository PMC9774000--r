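#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d candidate structure(s), sorted by sign disagreements\n",
              nrow(x)))
  NextMethod()
}

#' Tidy a metric report into long form
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return tibble with one row per (structure, metric): `structure_id`,
#'   `metric` (`"sigma_cs"`, `"sigma_a"`, `"sigma_psiphi"`), `value`, `n`,
#'   `rank`.
#' @exportS3Method generics::tidy
tidy.metric_report <- function(x, ...) {
  tab <- tibble::as_tibble(x)
  purrr::map_dfr(
    c("sigma_cs" = "cs", "sigma_a" = "a", "sigma_psiphi" = "psiphi"),
    function(suffix) {
      tibble::tibble(
        structure_id = tab$structure_id,
        value = tab[[paste0("sigma_", suffix)]],
        n = tab[[paste0("n_", suffix)]],
        rank = tab[[paste0("rank_", suffix)]]
      )
    },
    .id = "metric"
  ) |>
    dplyr::relocate("structure_id") |>
    dplyr::arrange(.data$metric, .data$rank)
}

#' One-row summary of a metric report
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return tibble with the panel size and the best structure per metric.
#' @exportS3Method generics::glance
glance.metric_report <- function(x, ...) {
  best <- function(metric) x$structure_id[which.min(x[[metric]])]
  tibble::tibble(
    n_structures = nrow(x),
    best_cs = best("sigma_cs"),
    best_a = best("sigma_a"),
    best_psiphi = if (all(is.na(x$sigma_psiphi))) NA_character_ else
      best("sigma_psiphi"),
    top_id = x$structure_id[1]
  )
}

#' Plot a metric report as per-metric rankings
#'
#' One panel per strain metric, candidates ordered by the report's overall
#' ranking, the per-metric minimum highlighted.
#'
#' @param object a `metric_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metric_report <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, !is.na(.data$value))
  long$structure_id <- factor(long$structure_id,
                              levels = rev(object$structure_id))
  long <- dplyr::group_by(long, .data$metric) |>
    dplyr::mutate(best = .data$rank == 1L) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$structure_id,
                                     fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c51b8a",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "metric value (lower is better)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-residue S comparison plot
#'
#' Overlays the observed and one candidate's calculated S = d(Ca) - d(Cb)
#' secondary-shift difference along the sequence — the per-residue view of
#' what the sign-disagreement metric counts.
#'
#' @param nmr_profile,cal_profile `secondary_shift_tbl`s from
#'   [secondary_shifts()].
#' @return a ggplot object.
#' @export
plot_s_series <- function(nmr_profile, cal_profile) {
  both <- dplyr::bind_rows(
    tibble::tibble(residue_number = nmr_profile$residue_number,
                   s_value = nmr_profile$s_value,
                   side = source_label(nmr_profile)),
    tibble::tibble(residue_number = cal_profile$residue_number,
                   s_value = cal_profile$s_value,
                   side = source_label(cal_profile))
  )
  both <- dplyr::filter(both, !is.na(.data$s_value))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$residue_number,
                                     y = .data$s_value,
                                     colour = .data$side)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "residue", y = "S = ΔδCα - ΔδCβ (ppm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-residue chemical-shift difference plot
#'
#' Bar plot of the per-residue diagnostic for one candidate structure — the
#' flat-file analogue of coloring a fibril chain by local disagreement.
#'
#' @param report a `metric_report` with the `delta_ab` list-column.
#' @param structure_id candidate to show; default the report's top row.
#' @return a ggplot object.
#' @export
plot_delta_ab <- function(report, structure_id = report$structure_id[1]) {
  if (!"delta_ab" %in% names(report)) {
    stop("report lacks the delta_ab list-column", call. = FALSE)
  }
  row <- which(report$structure_id == structure_id)
  if (length(row) != 1) stop("unknown structure_id: ", structure_id,
                             call. = FALSE)
  d <- report$delta_ab[[row]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue_number,
                                  y = .data$delta_ab)) +
    ggplot2::geom_col(fill = "#2b8cbe") +
    ggplot2::labs(
      x = "residue",
      y = "Δαβ (ppm)",
      title = paste0("Per-residue Cα/Cβ shift difference: ",
                     structure_id)
    ) +
    ggplot2::theme_minimal()
}
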