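# End-to-end orchestration: validate -> quantify -> fit -> report.
# Stages communicate through files (results.csv, fit.json, report.md) so
# each is independently usable; every output records the run configuration
# and seed for provenance.

#' Run the full mwPIFE analysis pipeline on a plate directory
#'
#' Reads and validates \code{layout.csv} + \code{scans.csv}, quantifies
#' control-corrected PIFE per replicate group, optionally normalizes to a
#' named reference group, fits a binding titration when the layout contains
#' one (>= 4 distinct protein amounts on a common probe), and writes
#' \code{results.csv}, \code{fit.json} and a human-readable
#' \code{report.md} into \code{out_dir}.
#'
#' @param dir Directory containing layout.csv and scans.csv.
#' @param out_dir Output directory. Default \code{file.path(dir, "results")}.
#' @param mask,stat Passed to [quantify_pife()].
#' @param normalize_to Optional replicate_group used as normalization
#'   reference (no silent default).
#' @param fit_titration Fit a quadratic-isotherm titration when the layout
#'   encodes one. Default TRUE.
#' @param probe_pmol Immobilized probe amount per well (pmol) for the
#'   titration fit; the layout stores protein amounts only. Default 2.5,
#'   the protocol loading.
#' @param n_boot Bootstrap resamples for fit CIs. Default 500.
#' @param seed Seed stamped into outputs and used for the bootstrap.
#' @return Invisibly, a list with elements \code{results} (data.frame),
#'   \code{fit} (binding_fit or NULL), \code{wells} (per-well PIFE) and
#'   \code{paths}.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "results"),
                         mask = "all_points", stat = "mean",
                         normalize_to = NULL, fit_titration = TRUE,
                         probe_pmol = 2.5, n_boot = 500, seed = 1) {
  plate <- read_plate(file.path(dir, "layout.csv"),
                      file.path(dir, "scans.csv"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  config <- list(dir = dir, mask = mask, stat = stat,
                 normalize_to = normalize_to, fit_titration = fit_titration,
                 probe_pmol = probe_pmol, n_boot = n_boot, seed = seed,
                 version = as.character(utils::packageVersion("mwpife")))

  layout <- plate$layout
  n_sample <- sum(layout$role == "sample")
  if (n_sample == 0) {
    warning("plate contains no sample wells; results are empty")
    results <- data.frame()
    wells <- data.frame()
  } else {
    results <- quantify_pife(plate, mask = mask, stat = stat)
    wells <- pife_by_well(plate, mask = mask, stat = stat)
    if (!is.null(normalize_to)) {
      results <- normalize_pife(results, normalize_to)
    }
  }

  fit <- NULL
  if (fit_titration && n_sample > 0) {
    smp <- layout[layout$role == "sample", , drop = FALSE]
    amounts <- smp$protein_pmol[!is.na(smp$protein_pmol)]
    if (length(unique(amounts)) >= 4 &&
        length(unique(smp$probe_id[!is.na(smp$protein_pmol)])) == 1) {
      per_well <- merge(wells,
                        smp[, c("well_id", "protein_pmol", "volume_ul")],
                        by = "well_id")
      per_well <- per_well[!is.na(per_well$protein_pmol), , drop = FALSE]
      curve <- titration_curve(
        P = pmol_to_nM(per_well$protein_pmol, per_well$volume_ul),
        y = per_well$pife,
        D = pmol_to_nM(probe_pmol, per_well$volume_ul[1]),
        signal_kind = "pife"
      )
      fit <- fit_binding(curve, n_boot = n_boot, seed = seed)
    }
  }

  results_path <- file.path(out_dir, "results.csv")
  utils::write.csv(results, results_path, row.names = FALSE)

  fit_path <- file.path(out_dir, "fit.json")
  fit_json <- list(config = config)
  if (!is.null(fit)) {
    fit_json$binding_fit <- list(
      converged = fit$converged, Kd_nM = fit$Kd, A = fit$A,
      baseline = fit$baseline, rss = fit$rss,
      Kd_ci = if (!is.null(fit$ci)) unname(fit$ci[, "Kd"]) else NULL,
      n_boot_ok = fit$n_boot_ok
    )
  }
  jsonlite::write_json(fit_json, fit_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  report_path <- file.path(out_dir, "report.md")
  .write_report(report_path, plate, results, fit, config)

  invisible(list(results = results, fit = fit, wells = wells,
                 paths = c(results = results_path, fit = fit_path,
                           report = report_path)))
}

.write_report <- function(path, plate, results, fit, config) {
  lines <- c(
    "# mwPIFE analysis report",
    "",
    sprintf("- wells: %d (%d sample, %d buffer_control, %d blank)",
            nrow(plate$layout), sum(plate$layout$role == "sample"),
            sum(plate$layout$role == "buffer_control"),
            sum(plate$layout$role == "blank")),
    sprintf("- mask: %s; aggregation: %s; seed: %s", config$mask,
            config$stat, config$seed),
    ""
  )
  if (nrow(results) == 0) {
    lines <- c(lines, "No sample wells: results are empty.", "")
  } else {
    lines <- c(lines, "## Control-corrected PIFE per replicate group", "",
               "| group | PIFE | sd | n | wash PIFE | control |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.4f | %s | %d | %s | %s |",
                       results$replicate_group, results$pife,
                       ifelse(is.na(results$sd), "-",
                              sprintf("%.4f", results$sd)),
                       results$n,
                       ifelse(is.na(results$wash_pife), "-",
                              sprintf("%.4f", results$wash_pife)),
                       results$control_group),
               "")
  }
  if (!is.null(fit) && fit$converged) {
    ci_txt <- if (!is.null(fit$ci)) {
      sprintf(" (95%% CI %.3g-%.3g nM, %d bootstrap refits)",
              fit$ci["lo", "Kd"], fit$ci["hi", "Kd"], fit$n_boot_ok)
    } else ""
    lines <- c(lines, "## Binding fit", "",
               sprintf("Kd = %.3g nM%s, amplitude A = %.3g, baseline = %.3g.",
                       fit$Kd, ci_txt, fit$A, fit$baseline), "")
  }
  # accounting: every layout well appears as used, control or excluded
  used <- unique(c(
    plate$layout$well_id[plate$layout$role %in% c("sample", "buffer_control")]
  ))
  excluded <- setdiff(plate$layout$well_id, used)
  if (length(excluded)) {
    lines <- c(lines, "## Excluded wells", "",
               sprintf("- %s: role '%s' (not part of PIFE quantification)",
                       excluded,
                       plate$layout$role[match(excluded,
                                               plate$layout$well_id)]),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
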