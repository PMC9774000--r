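#' Assemble and validate a comparison run configuration
#'
#' A run configuration collects every input and convention of an end-to-end
#' comparison. It can be built in code or loaded from a YAML file with the
#' same field names; [run_compare()] accepts either.
#'
#' @param assignment path to the observed NMR-STAR assignment.
#' @param structures_dir directory of candidate structures (`.pdb`/`.cif`);
#'   each file's stem is its structure id.
#' @param pred_shifts_dir directory of per-structure predicted shift tables
#'   (`<id>.cs` or `<id>.csv`, ShiftX2 layout).
#' @param talos optional TALOS-N-style torsion prediction for the observed
#'   side; without it the dihedral metric is skipped.
#' @param out_dir output directory (created if needed).
#' @param chain_id chain used when reading structures.
#' @param ambiguous_policy,circular,partial,epsilon_s metric conventions, see
#'   [match_residues()], [sigma_psiphi()], [sigma_cs()], [sigma_a()].
#' @param rc_table optional path to a replacement random-coil CSV.
#' @param numbering,offset forwarded to [read_nmrstar_shifts()].
#' @param strict error (rather than warn-and-skip) on a structure without a
#'   predicted-shift file.
#' @param seed integer recorded in the manifest (the comparison itself is
#'   deterministic).
#' @return a validated `run_config` list.
#' @export
compare_config <- function(assignment, structures_dir, pred_shifts_dir,
                           talos = NULL, out_dir = tempfile("compare_"),
                           chain_id = "A", ambiguous_policy = "exclude",
                           circular = TRUE, partial = TRUE, epsilon_s = 0,
                           rc_table = NULL, numbering = "auth", offset = 0L,
                           strict = FALSE, seed = 1L) {
  cfg <- list(
    assignment = assignment, structures_dir = structures_dir,
    pred_shifts_dir = pred_shifts_dir, talos = talos, out_dir = out_dir,
    chain_id = chain_id, ambiguous_policy = ambiguous_policy,
    circular = circular, partial = partial, epsilon_s = epsilon_s,
    rc_table = rc_table, numbering = numbering, offset = as.integer(offset),
    strict = strict, seed = as.integer(seed)
  )
  for (p in c("assignment", "structures_dir", "pred_shifts_dir", "talos",
              "rc_table")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config path does not exist: ", p, " = ", cfg[[p]], call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(compare_config, cfg[!vapply(cfg, is.null, TRUE)])
}

#' Run the full assignment-vs-structures comparison
#'
#' For every candidate structure: read coordinates and compute phi/psi
#' torsions, read its predicted shift table, form secondary shifts on both
#' sides with a common random-coil reference, match residues under the
#' configured ambiguity policy, compute the three strain metrics and the
#' per-residue diagnostic, and rank. Writes `report.csv`, `report.json`,
#' `delta_ab.csv`, `s_series.csv` and `manifest.json` to the output
#' directory; identical configurations yield byte-identical outputs.
#'
#' @param config a [compare_config()] list or path to its YAML form.
#' @return the ranked `metric_report`, invisibly the same object that was
#'   written.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  rc <- if (is.null(config$rc_table)) random_coil_shifts() else
    random_coil_shifts(config$rc_table)

  nmr_shifts <- read_nmrstar_shifts(
    config$assignment, numbering = config$numbering, offset = config$offset
  )
  nmr_torsions <- if (!is.null(config$talos)) {
    read_talosn_torsions(config$talos)
  }

  struct_files <- list.files(config$structures_dir,
                             pattern = "\\.(pdb|ent|cif)$",
                             ignore.case = TRUE, full.names = TRUE)
  if (length(struct_files) == 0) {
    stop("no structure files in ", config$structures_dir, call. = FALSE)
  }
  struct_files <- sort(struct_files)
  cal_shifts <- list(); cal_torsions <- list()
  log_rows <- list()
  for (f in struct_files) {
    id <- sub("\\.(pdb|ent|cif)$", "", basename(f), ignore.case = TRUE)
    pred <- file.path(config$pred_shifts_dir, paste0(id, c(".cs", ".csv")))
    pred <- pred[file.exists(pred)][1]
    if (is.na(pred)) {
      msg <- paste0("structure ", id, " has no predicted-shift file")
      if (isTRUE(config$strict)) stop(msg, call. = FALSE)
      warning(msg, ", skipped", call. = FALSE)
      next
    }
    model <- read_structure(f, chain_id = config$chain_id, structure_id = id)
    cal_torsions[[id]] <- compute_torsions(model)
    cal_shifts[[id]] <- read_shiftx2_shifts(pred, structure_id = id)
    log_rows[[id]] <- tibble::tibble(
      structure_id = id, n_residues = dplyr::n_distinct(model$residue_number),
      n_pred_shifts = nrow(cal_shifts[[id]]),
      n_cal_torsions = nrow(cal_torsions[[id]])
    )
  }
  if (length(cal_shifts) == 0) {
    stop("no structure had a predicted-shift file", call. = FALSE)
  }

  report <- compare_panel(
    nmr_shifts, cal_shifts, nmr_torsions, cal_torsions, rc = rc,
    ambiguous_policy = config$ambiguous_policy, circular = config$circular,
    partial = config$partial, epsilon_s = config$epsilon_s
  )

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metric_report(report, file.path(config$out_dir, "report.csv"))
  write_metric_report(report, file.path(config$out_dir, "report.json"))
  write_delta_ab(report, file.path(config$out_dir, "delta_ab.csv"))
  s_series <- s_series_table(nmr_shifts, cal_shifts, rc)
  utils::write.csv(s_series, file.path(config$out_dir, "s_series.csv"),
                   row.names = FALSE, quote = FALSE)
  ambiguous <- intersect(nmr_shifts$residue_number, ambiguous_pggg_residues())
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("shiftstrain")),
    rc_provenance = attr(rc, "provenance_label"),
    n_assigned_residues = dplyr::n_distinct(nmr_shifts$residue_number),
    n_ambiguous_residues = length(unique(ambiguous)),
    structures = dplyr::bind_rows(log_rows)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}

# tidy per-residue S series for the observed side and every candidate
s_series_table <- function(nmr_shifts, cal_shifts, rc) {
  nmr_prof <- secondary_shifts(nmr_shifts, rc)
  purrr::imap_dfr(cal_shifts, function(cal, id) {
    cal_prof <- secondary_shifts(cal, rc)
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(nmr_prof), "residue_number",
                    s_nmr = "s_value"),
      dplyr::select(tibble::as_tibble(cal_prof), "residue_number",
                    s_cal = "s_value"),
      by = "residue_number"
    ) |>
      dplyr::mutate(structure_id = id, .before = 1)
  })
}

#' Simulate a complete synthetic input directory
#'
#' Materializes one ground-truth backbone plus kink-shifted decoys in every
#' format the comparison pipeline consumes: PDB coordinates per structure,
#' ShiftX2-layout predicted shift tables per structure, an NMR-STAR observed
#' assignment simulated from the truth with noise, a TALOS-N-layout observed
#' torsion table, and a YAML manifest. The directory feeds straight into
#' [run_compare()].
#'
#' @param out_dir output directory.
#' @param truth ground-truth [torsion_program()].
#' @param n_decoys number of decoy structures.
#' @param noise_sd observed-shift noise, ppm.
#' @param torsion_noise_sd observed-torsion noise, degrees.
#' @param kink_shift_range,min_shift decoy kink translation bounds.
#' @param seed RNG seed for decoy draws and noise.
#' @return the manifest list, invisibly. Side effect: files under `out_dir`.
#' @export
run_simulate <- function(out_dir, truth = tau_truth_program(), n_decoys = 9,
                         noise_sd = 0.3, torsion_noise_sd = 0,
                         kink_shift_range = 4L, min_shift = 2L, seed = 1L) {
  seed <- as.integer(seed)
  rc <- random_coil_shifts()
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(out_dir, "pred_shifts"), showWarnings = FALSE)

  decoys <- make_decoys(truth, n_decoys, kink_shift_range = kink_shift_range,
                        min_shift = min_shift, seed = seed)
  programs <- c(list(truth), decoys)
  for (p in programs) {
    id <- p$program_id
    write_pdb(generate_backbone(p, structure_id = id),
              file.path(out_dir, "structures", paste0(id, ".pdb")))
    write_shiftx2_shifts(
      simulate_shift_table(p, rc, forward_shift_model(noise_sd = 0),
                           source_label = paste0("Cal:", id)),
      file.path(out_dir, "pred_shifts", paste0(id, ".cs"))
    )
  }
  observed <- simulate_shift_table(
    truth, rc, forward_shift_model(noise_sd = noise_sd, seed = seed + 500L),
    source_label = "NMR"
  )
  write_nmrstar_shifts(observed, file.path(out_dir, "observed_shifts.str"),
                       entry_id = "synthetic_truth")
  write_talosn_torsions(
    program_torsions(truth, noise_sd = torsion_noise_sd, seed = seed + 900L,
                     source_label = "NMR"),
    file.path(out_dir, "observed_torsions.tab")
  )
  manifest <- list(
    seed = seed, n_decoys = n_decoys, noise_sd = noise_sd,
    torsion_noise_sd = torsion_noise_sd,
    kink_shift_range = kink_shift_range, min_shift = min_shift,
    truth_id = truth$program_id,
    structure_ids = vapply(programs, `[[`, "", "program_id"),
    files = c("structures/", "pred_shifts/", "observed_shifts.str",
              "observed_torsions.tab", "manifest.yaml")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
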