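# Scenario presets: condition grids + generative truths emulating the main
# mwPIFE experiment classes (restriction-enzyme distance/cation panels,
# sequence- and structure-specific competition, Ku titration / footprint /
# translocation). Concentrations follow the wet protocol (2.5 pmol probe in
# 100 ul = 25 nM; proteins pipetted in pmol). Where a latent quantity is not
# measured at plate scale (probe affinities, occupancy profiles), the preset
# fixes a documented truth chosen so that the simulated readout sits in the
# observed range; see the methods vignette.

.preset_names <- c("ku_titration", "bamhi_distance_panel", "bamhi_cations",
                   "xpf_competition", "sequence_competition", "ku_footprint",
                   "ku_translocation")

#' Available simulation presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() .preset_names

#' Build a scenario preset (condition grid + configuration truth)
#'
#' @param name One of [preset_names()].
#' @param n_replicates Wells per replicate group. Default 3.
#' @return List with elements \code{name}, \code{conditions} (a condition
#'   table for [simulate_plate()]) and \code{config}.
#' @export
scenario_preset <- function(name = .preset_names, n_replicates = 3) {
  name <- match.arg(name)
  D <- pmol_to_nM(2.5, 100) # 25 nM probe throughout

  if (name == "ku_titration") {
    # end-binding titration on a short duplex: truth Kd 10 nM, probe 25 nM,
    # protein 0.5-20 pmol (5-200 nM); alpha set so the plateau PIFE is 0.8
    cfg <- sim_config(distance_bp = 0, n_scans = 2)
    theta_max <- fraction_bound(D, pmol_to_nM(20, 100), 10)
    # the difference-form control correction leaves the enhancement term
    # attenuated by one scan interval of bleaching, E[PIFE] =
    # (1 - bleach) * alpha * f(d) * theta, so calibrate alpha through it
    cfg$alpha <- 0.8 / (theta_max *
                          distance_factor(0, cfg$d_half, cfg$steepness,
                                          cfg$bp_to_nm) *
                          (1 - cfg$bleach_per_scan))
    pm <- c(0.5, 1, 2, 4, 8, 16, 20)
    cond <- data.frame(
      replicate_group = c(sprintf("ku_%gpmol", pm), "buffer"),
      role = c(rep("sample", length(pm)), "buffer_control"),
      control_group = c(rep("buffer", length(pm)), NA),
      protein_id = c(rep("Ku", length(pm)), NA),
      protein_pmol = c(pm, NA),
      kd_nM = c(rep(10, length(pm)), NA),
      distance_bp = 0,
      stringsAsFactors = FALSE
    )
  } else if (name == "bamhi_distance_panel") {
    # recognition site placed 1/16/31/46 bp from the dye + a no-site probe;
    # divalent-cation binding conditions, occupancy ~0.58
    cfg <- sim_config(alpha = 1, n_scans = 2)
    dist <- c(1, 16, 31, 46)
    cond <- data.frame(
      replicate_group = c(sprintf("site_%dbp", dist), "no_site", "buffer"),
      role = c(rep("sample", 5), "buffer_control"),
      control_group = c(rep("buffer", 5), NA),
      probe_id = c(sprintf("probe_site%d", dist), "probe_nosite", "probe_nosite"),
      protein_id = c(rep("BamHI", 5), NA),
      protein_pmol = c(rep(15, 4), NA, NA), # no-site probe: no specific binding
      kd_nM = c(rep(100, 4), NA, NA),
      distance_bp = c(dist, 1, 1),
      stringsAsFactors = FALSE
    )
  } else if (name == "bamhi_cations") {
    # cation dependence with a wash phase: chelator (weak binding), Ca2+
    # (binding, no cleavage, protein washes off), Mg2+ (binding + cleavage
    # of 90% of probes, cleaved fragments lost in the wash)
    cfg <- sim_config(alpha = 1, n_scans = 3, distance_bp = 1)
    cond <- data.frame(
      replicate_group = c("edta", "ca", "mg", "buffer"),
      role = c("sample", "sample", "sample", "buffer_control"),
      control_group = c("buffer", "buffer", "buffer", NA),
      protein_id = c(rep("BamHI", 3), NA),
      protein_pmol = c(15, 15, 15, NA),
      kd_nM = c(5000, 100, 100, NA), # cation-free binding is weak
      cleavage_fraction = c(0, 0, 0.9, 0),
      wash_retention = 0,
      distance_bp = 1,
      stringsAsFactors = FALSE
    )
  } else if (name == "xpf_competition") {
    # structure-specific competition: five unlabelled DNA structures with
    # anisotropy-determined affinities {640, 810, 1320, 4750, 8650} nM at
    # 1/10/100-fold excess; probe truth Kd 200 nM, protein 25 pmol (250 nM),
    # alpha 1.5 so the uncompeted PIFE is ~0.8
    cfg <- sim_config(alpha = 1.5, distance_bp = 0, n_scans = 2)
    kd_c <- c(HP = 640, Y = 810, Y10 = 1320, ds10 = 4750, ss10 = 8650)
    exc <- c(1, 10, 100)
    grid <- expand.grid(competitor_id = names(kd_c), competitor_excess = exc,
                        stringsAsFactors = FALSE)
    grid$kd_comp_nM <- kd_c[grid$competitor_id]
    cond <- data.frame(
      replicate_group = c("no_competitor",
                          sprintf("%s_%gx", grid$competitor_id,
                                  grid$competitor_excess), "buffer"),
      role = c("sample", rep("sample", nrow(grid)), "buffer_control"),
      control_group = c("buffer", rep("buffer", nrow(grid)), NA),
      protein_id = c(rep("XPF_ERCC1", nrow(grid) + 1), NA),
      protein_pmol = c(rep(25, nrow(grid) + 1), NA),
      kd_nM = c(rep(200, nrow(grid) + 1), NA),
      competitor_id = c(NA, grid$competitor_id, NA),
      competitor_excess = c(NA, grid$competitor_excess, NA),
      kd_comp_nM = c(NA, grid$kd_comp_nM, NA),
      distance_bp = 0,
      stringsAsFactors = FALSE
    )
  } else if (name == "sequence_competition") {
    # sequence specificity: competitors identical to the probe, substituted
    # outside the site (compete equally) or inside the site / no site
    # (inert), at 1-10x excess
    cfg <- sim_config(alpha = 1, distance_bp = 1, n_scans = 2)
    comp <- data.frame(
      competitor_id = c("matched", "flank_sub", "site_mut", "no_site"),
      kd_comp_nM = c(100, 100, 1e7, 1e7),
      stringsAsFactors = FALSE
    )
    exc <- c(1, 2, 5, 10)
    grid <- merge(comp, data.frame(competitor_excess = exc))
    cond <- data.frame(
      replicate_group = c("no_competitor",
                          sprintf("%s_%gx", grid$competitor_id,
                                  grid$competitor_excess), "buffer"),
      role = c(rep("sample", nrow(grid) + 1), "buffer_control"),
      control_group = c(rep("buffer", nrow(grid) + 1), NA),
      protein_id = c(rep("BamHI", nrow(grid) + 1), NA),
      protein_pmol = c(rep(15, nrow(grid) + 1), NA),
      kd_nM = c(rep(100, nrow(grid) + 1), NA),
      competitor_id = c(NA, grid$competitor_id, NA),
      competitor_excess = c(NA, grid$competitor_excess, NA),
      kd_comp_nM = c(NA, grid$kd_comp_nM, NA),
      distance_bp = 1,
      stringsAsFactors = FALSE
    )
  } else if (name == "ku_footprint") {
    # minimal duplex length: a configured length-to-affinity truth map with
    # occupancy rising steeply between 11 and 13 bp
    cfg <- sim_config(alpha = 1, distance_bp = 0, n_scans = 2)
    len <- 10:15
    kd_map <- c(1e5, 1300, 380, 90, 88, 87) # nM, by length
    cond <- data.frame(
      replicate_group = c(sprintf("len_%dbp", len), "buffer"),
      role = c(rep("sample", length(len)), "buffer_control"),
      control_group = c(rep("buffer", length(len)), NA),
      probe_id = c(sprintf("duplex_%dbp", len), "duplex_15bp"),
      protein_id = c(rep("Ku", length(len)), NA),
      protein_pmol = c(rep(10, length(len)), NA),
      kd_nM = c(kd_map, NA),
      distance_bp = 0,
      stringsAsFactors = FALSE
    )
  } else { # ku_translocation
    # dye at the free end or 15/60 bp internal, or both ends blocked:
    # position-dependent occupancy encoded directly as a truth profile
    # decreasing with distance from the loading end
    cfg <- sim_config(alpha = 1, distance_bp = 0, n_scans = 2)
    cond <- data.frame(
      replicate_group = c("terminal", "internal_15bp", "internal_60bp",
                          "blocked_ends", "buffer"),
      role = c(rep("sample", 4), "buffer_control"),
      control_group = c(rep("buffer", 4), NA),
      protein_id = c(rep("Ku", 4), NA),
      protein_pmol = c(rep(10, 4), NA),
      theta = c(0.55, 0.30, 0.12, 0.02, NA),
      distance_bp = 0,
      stringsAsFactors = FALSE
    )
  }
  cond$n_wells <- n_replicates
  list(name = name, conditions = cond, config = cfg)
}

#' Simulate a preset plate (optionally writing files + truth sidecar)
#'
#' @inheritParams scenario_preset
#' @param seed Integer seed for reproducibility.
#' @param dir If non-NULL, write layout.csv / scans.csv / truth.json there.
#' @return The simulated \code{pife_plate} (invisibly when written to disk),
#'   with the truth attribute.
#' @export
simulate_preset <- function(name, seed = NULL, n_replicates = 3, dir = NULL) {
  preset <- scenario_preset(name, n_replicates = n_replicates)
  plate <- simulate_plate(preset$conditions, preset$config, seed = seed)
  truth <- attr(plate, "truth")
  truth$preset <- preset$name
  attr(plate, "truth") <- truth
  if (!is.null(dir)) {
    write_simulated_plate(plate, dir)
    return(invisible(plate))
  }
  plate
}
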