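# Generative model of an mwPIFE plate.
#
# Signal model per well and scan k (1 = pre-protein reference, 2 =
# post-incubation, 3 = post-wash):
#   E[F_k] = B * probe_pmol * (1 - bleach)^(k-1) * (1 + alpha * f(d) * theta_k)
#            * survival_k
# where B is brightness per pmol probe, f(d) the dye-distance falloff,
# theta_k the bound fraction at scan k (0 before protein; theta after
# incubation; theta * wash_retention after the wash), and survival_k the
# fraction of labelled probe still in the well (cleaved fragments are
# removed by the wash, so survival = 1 - cleavage_fraction at scan 3 only).
# Realised intensities are the expectation times mean-one multiplicative
# lognormal factors: one per well-scan (noise_cv) and one per grid point
# (point_cv) — fluorescence noise scales with signal.

#' Simulation configuration for a synthetic mwPIFE plate
#'
#' Defaults mirror the wet protocol: 2.5 pmol immobilized Cy3 probe in
#' 100 ul (25 nM), a 10 x 10 scan grid, a few percent photobleaching per
#' scan and percent-scale well-to-well reproducibility.
#'
#' @param probe_pmol Immobilized probe per well (pmol). Default 2.5.
#' @param volume_ul Well volume (ul). Default 100.
#' @param base_brightness Fluorescence counts per pmol of unbound probe.
#'   Default 4000 (arbitrary units; 1e4 counts/well at the default loading).
#' @param alpha Enhancement factor: fractional fluorescence increase of a
#'   fully bound zero-distance probe. Default 1.0 (the ~2-fold single-dye
#'   enhancement; population signals are lower because occupancy and
#'   distance dilute it).
#' @param bleach_per_scan Fraction of signal lost per scan event. Default 0.03.
#' @param noise_cv Lognormal CV of the per-well-per-scan factor. Default 0.05.
#' @param point_cv Lognormal CV of per-grid-point noise. Default 0.02.
#' @param distance_bp Dye-to-binding-site distance (bp). Default 1.
#' @param cleavage_fraction Fraction of probes cut and washed away before
#'   scan 3. Default 0.
#' @param wash_retention Fraction of bound protein surviving the wash.
#'   Default 0.
#' @param grid_size Scan matrix points per side. Default 10.
#' @param n_scans Scans per well (2, or 3 with a wash phase). Default 2.
#' @param d_half,steepness,bp_to_nm Distance-response parameters, see
#'   [distance_factor()].
#' @return List of class \code{pife_sim_config}.
#' @export
sim_config <- function(probe_pmol = 2.5, volume_ul = 100,
                       base_brightness = 4000, alpha = 1.0,
                       bleach_per_scan = 0.03, noise_cv = 0.05,
                       point_cv = 0.02, distance_bp = 1,
                       cleavage_fraction = 0, wash_retention = 0,
                       grid_size = 10, n_scans = 2,
                       d_half = 2, steepness = 4, bp_to_nm = 0.34) {
  cfg <- list(probe_pmol = probe_pmol, volume_ul = volume_ul,
              base_brightness = base_brightness, alpha = alpha,
              bleach_per_scan = bleach_per_scan, noise_cv = noise_cv,
              point_cv = point_cv, distance_bp = distance_bp,
              cleavage_fraction = cleavage_fraction,
              wash_retention = wash_retention, grid_size = grid_size,
              n_scans = n_scans, d_half = d_half, steepness = steepness,
              bp_to_nm = bp_to_nm)
  stopifnot(cfg$probe_pmol > 0, cfg$volume_ul > 0, cfg$base_brightness > 0,
            cfg$bleach_per_scan >= 0, cfg$bleach_per_scan <= 1,
            cfg$cleavage_fraction >= 0, cfg$cleavage_fraction <= 1,
            cfg$wash_retention >= 0, cfg$wash_retention <= 1,
            cfg$noise_cv >= 0, cfg$point_cv >= 0,
            cfg$grid_size >= 1, cfg$n_scans %in% 1:3)
  class(cfg) <- "pife_sim_config"
  cfg
}

#' Expected well-mean intensity at a given occupancy and scan
#'
#' @param config A \code{pife_sim_config}.
#' @param theta Bound fraction of the probe at this scan, in [0, 1]. The
#'   caller supplies the scan-appropriate occupancy (0 for the pre-protein
#'   scan; \code{theta * wash_retention} after a wash).
#' @param scan_index 1, 2 or 3.
#' @param distance_bp Dye-site distance (bp); default from config.
#' @param cleavage_fraction Cleaved fraction; applies at scan 3 only
#'   (fragments leave with the wash); default from config.
#' @return Expected mean intensity (counts).
#' @export
expected_signal <- function(config, theta, scan_index,
                            distance_bp = config$distance_bp,
                            cleavage_fraction = config$cleavage_fraction) {
  stopifnot(all(theta >= 0 & theta <= 1))
  n <- max(length(theta), length(scan_index), length(distance_bp),
           length(cleavage_fraction))
  theta <- rep_len(theta, n)
  scan_index <- rep_len(scan_index, n)
  distance_bp <- rep_len(distance_bp, n)
  cleavage_fraction <- rep_len(cleavage_fraction, n)
  df <- distance_factor(distance_bp, config$d_half, config$steepness,
                        config$bp_to_nm)
  survival <- ifelse(scan_index == 3, 1 - cleavage_fraction, 1)
  config$base_brightness * config$probe_pmol *
    (1 - config$bleach_per_scan)^(scan_index - 1) *
    (1 + config$alpha * df * theta) * survival
}

# mean-one lognormal factors with a given coefficient of variation
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# well labels A1, A2, ... row-major over as many 24-column rows as needed;
# labels are identifiers only, no physical geometry attached
.well_ids <- function(n) {
  cols <- 24
  rows <- ceiling(n / cols)
  letters2 <- c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))
  ids <- as.vector(t(outer(letters2[seq_len(rows)], seq_len(cols), paste0)))
  ids[seq_len(n)]
}

#' Simulate a plate from a condition table
#'
#' One row of \code{conditions} describes one replicate group; each group is
#' expanded to \code{n_wells} wells. Occupancy is derived from the binding
#' model ([fraction_bound()], or [solve_competition()] when a competitor
#' with finite affinity is present), or taken verbatim from a \code{theta}
#' column when the scenario encodes occupancy directly as truth.
#'
#' @param conditions data.frame; recognised columns: replicate_group
#'   (required), role ("sample"/"buffer_control", default sample),
#'   control_group, probe_id, protein_id, protein_pmol, kd_nM (probe
#'   affinity), competitor_id, competitor_excess (fold over probe),
#'   kd_comp_nM, distance_bp, cleavage_fraction, wash_retention, theta
#'   (direct occupancy truth), n_wells (default \code{n_replicates}).
#' @param config A \code{pife_sim_config}.
#' @param seed Integer seed; identical seed and inputs give a bit-identical
#'   plate.
#' @param n_replicates Default wells per group. Default 3 (three independent
#'   wells per condition, as in the assay protocol).
#' @return A validated \code{pife_plate} with attribute \code{"truth"}: the
#'   config plus the expanded per-group latent parameters.
#' @export
simulate_plate <- function(conditions, config = sim_config(), seed = NULL,
                           n_replicates = 3) {
  if (!is.null(seed)) set.seed(seed)
  cond <- as.data.frame(conditions, stringsAsFactors = FALSE)
  if (!"replicate_group" %in% names(cond)) stop("conditions need replicate_group")
  defaults <- list(role = "sample", control_group = NA_character_,
                   probe_id = "probe", protein_id = NA_character_,
                   protein_pmol = NA_real_, kd_nM = NA_real_,
                   competitor_id = NA_character_, competitor_excess = NA_real_,
                   kd_comp_nM = NA_real_, distance_bp = config$distance_bp,
                   cleavage_fraction = config$cleavage_fraction,
                   wash_retention = config$wash_retention, theta = NA_real_,
                   n_wells = n_replicates)
  for (nm in names(defaults)) {
    if (!nm %in% names(cond)) cond[[nm]] <- defaults[[nm]]
  }
  for (nm in c("distance_bp", "cleavage_fraction", "wash_retention",
               "n_wells")) {
    cond[[nm]][is.na(cond[[nm]])] <- defaults[[nm]]
  }

  D <- pmol_to_nM(config$probe_pmol, config$volume_ul)
  theta <- numeric(nrow(cond))
  for (i in seq_len(nrow(cond))) {
    if (cond$role[i] != "sample") {
      theta[i] <- 0
    } else if (!is.na(cond$theta[i])) {
      theta[i] <- cond$theta[i]
    } else if (is.na(cond$protein_pmol[i]) || is.na(cond$kd_nM[i])) {
      theta[i] <- 0
    } else {
      P <- pmol_to_nM(cond$protein_pmol[i], config$volume_ul)
      exc <- cond$competitor_excess[i]
      kdc <- cond$kd_comp_nM[i]
      if (!is.na(exc) && exc > 0 && !is.na(kdc) && is.finite(kdc)) {
        theta[i] <- solve_competition(D, exc * D, P, cond$kd_nM[i],
                                      kdc)$theta_probe
      } else {
        theta[i] <- fraction_bound(D, P, cond$kd_nM[i])
      }
    }
  }
  cond$theta_truth <- theta

  # expand groups to wells
  reps <- cond$n_wells
  widx <- rep(seq_len(nrow(cond)), reps)
  n_wells <- length(widx)
  ids <- .well_ids(n_wells)

  layout <- data.frame(
    well_id = ids,
    role = cond$role[widx],
    probe_id = cond$probe_id[widx],
    protein_id = cond$protein_id[widx],
    protein_pmol = cond$protein_pmol[widx],
    competitor_id = cond$competitor_id[widx],
    competitor_excess = cond$competitor_excess[widx],
    buffer_id = "assay_buffer",
    replicate_group = cond$replicate_group[widx],
    control_group = cond$control_group[widx],
    volume_ul = config$volume_ul,
    stringsAsFactors = FALSE
  )

  g <- config$grid_size
  ks <- seq_len(config$n_scans)
  # expected intensity per well x scan
  th_scan <- function(k) {
    th <- cond$theta_truth[widx]
    if (k == 1) th <- 0
    if (k == 3) th <- th * cond$wash_retention[widx]
    th
  }
  E <- vapply(ks, function(k) {
    expected_signal(config, th_scan(k), k,
                    distance_bp = cond$distance_bp[widx],
                    cleavage_fraction = cond$cleavage_fraction[widx])
  }, numeric(n_wells))
  E <- matrix(E, nrow = n_wells)

  ws_factor <- matrix(.rlnorm_cv(n_wells * length(ks), config$noise_cv),
                      nrow = n_wells)
  well_scan_mean <- E * ws_factor

  npt <- g * g
  total <- n_wells * length(ks) * npt
  point_factor <- .rlnorm_cv(total, config$point_cv)
  # layout of the long table: well (outer) x scan x point (inner)
  scans <- data.frame(
    well_id = rep(ids, each = length(ks) * npt),
    scan_index = rep(rep(ks, each = npt), times = n_wells),
    point_row = rep(rep(seq_len(g), each = g), times = n_wells * length(ks)),
    point_col = rep(seq_len(g), times = n_wells * length(ks) * g),
    intensity = rep(as.vector(t(well_scan_mean)), each = npt) * point_factor,
    stringsAsFactors = FALSE
  )

  plate <- pife_plate(layout, scans, validate = FALSE)
  attr(plate, "truth") <- list(config = unclass(config), seed = seed,
                               conditions = cond)
  plate
}

#' Write a simulated plate plus its truth sidecar
#'
#' Emits layout.csv and scans.csv via [write_plate()] and a truth.json
#' recording every latent parameter (config, seed, per-group occupancies)
#' so that tests can assert against the generative truth.
#'
#' @param plate A simulated \code{pife_plate} carrying a \code{truth}
#'   attribute.
#' @param dir Output directory.
#' @return Named vector of the three file paths.
#' @export
write_simulated_plate <- function(plate, dir) {
  paths <- write_plate(plate, dir)
  truth <- attr(plate, "truth")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  c(paths, truth = truth_path)
}
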