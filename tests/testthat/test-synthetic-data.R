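# Generative model: expectations, determinism, noise structure, presets.

test_that("expected_signal composes brightness, bleach, enhancement and survival", {
  cfg <- sim_config(base_brightness = 4000, probe_pmol = 2.5, alpha = 1,
                    bleach_per_scan = 0, distance_bp = 0)
  base <- 4000 * 2.5
  expect_equal(expected_signal(cfg, 0, 1), base)
  # fully bound population at zero distance: the ~2-fold enhancement
  df0 <- distance_factor(0, cfg$d_half, cfg$steepness, cfg$bp_to_nm)
  expect_equal(expected_signal(cfg, 1, 2), base * (1 + df0), tolerance = 1e-9)
  # cleavage survival applies at the post-wash scan only
  cfg2 <- sim_config(bleach_per_scan = 0.03, cleavage_fraction = 0.9)
  expect_equal(expected_signal(cfg2, 0, 3),
               4000 * 2.5 * 0.97^2 * 0.1, tolerance = 1e-12)
  expect_equal(expected_signal(cfg2, 0, 2), 4000 * 2.5 * 0.97,
               tolerance = 1e-12)
})

test_that("noise-free simulation reproduces expectations exactly", {
  cond <- data.frame(replicate_group = c("g", "ctrl"),
                     role = c("sample", "buffer_control"),
                     control_group = c("ctrl", NA), theta = c(0, NA),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(noise_cv = 0, point_cv = 0, n_scans = 3,
                    bleach_per_scan = 0.05, grid_size = 4)
  plate <- simulate_plate(cond, cfg, seed = 1, n_replicates = 1)
  ws <- summarize_wells(plate)
  base <- cfg$base_brightness * cfg$probe_pmol
  expect_equal(ws$F1, rep(base, 2))
  expect_equal(ws$F2, rep(base * 0.95, 2))
  expect_equal(ws$F3, rep(base * 0.95^2, 2))
  expect_equal(ws$point_cv1, c(0, 0))
})

test_that("identical seeds give bit-identical plates; different seeds differ", {
  p1 <- simulate_preset("ku_titration", seed = 42)
  p2 <- simulate_preset("ku_titration", seed = 42)
  p3 <- simulate_preset("ku_titration", seed = 43)
  expect_identical(p1$scans, p2$scans)
  expect_identical(p1$layout, p2$layout)
  expect_false(identical(p1$scans$intensity, p3$scans$intensity))
})

test_that("disabled enhancement yields PIFE statistically indistinguishable from zero", {
  cond <- data.frame(replicate_group = c("null", "ctrl"),
                     role = c("sample", "buffer_control"),
                     control_group = c("ctrl", NA), theta = c(0.9, NA),
                     n_wells = c(100, 100), stringsAsFactors = FALSE)
  cfg <- sim_config(alpha = 0, bleach_per_scan = 0.05)
  plate <- simulate_plate(cond, cfg, seed = 7)
  w <- pife_by_well(plate)
  sem <- sd(w$pife) / sqrt(nrow(w))
  expect_lt(abs(mean(w$pife)), 2 * sem + 2 * sem) # mean and control noise
})

test_that("the control pairing makes the statistic unbiased for the enhancement term", {
  # law of large numbers at bleach 0: mean quantified PIFE over many pairs
  # approaches alpha * f(d) * theta within 3 SEM
  cond <- data.frame(replicate_group = c("g", "ctrl"),
                     role = c("sample", "buffer_control"),
                     control_group = c("ctrl", NA), theta = c(0.6, NA),
                     n_wells = c(500, 500), stringsAsFactors = FALSE)
  cfg <- sim_config(alpha = 1, bleach_per_scan = 0, distance_bp = 0)
  plate <- simulate_plate(cond, cfg, seed = 19)
  w <- pife_by_well(plate)
  target <- 1 * distance_factor(0, cfg$d_half, cfg$steepness, cfg$bp_to_nm) * 0.6
  sem <- sd(w$pife) / sqrt(nrow(w))
  expect_lt(abs(mean(w$pife) - target), 3 * (sem + sem / sqrt(500)))
  # with bleaching, the enhancement term is attenuated by exactly (1 - b)
  cfg_b <- sim_config(alpha = 1, bleach_per_scan = 0.1, distance_bp = 0)
  plate_b <- simulate_plate(cond, cfg_b, seed = 20)
  wb <- pife_by_well(plate_b)
  semb <- sd(wb$pife) / sqrt(nrow(wb))
  expect_lt(abs(mean(wb$pife) - 0.9 * target), 3 * (semb + semb / sqrt(500)))
})

test_that("wash-phase PIFE of bleach-only wells is centred on zero", {
  cond <- data.frame(replicate_group = c("g", "ctrl"),
                     role = c("sample", "buffer_control"),
                     control_group = c("ctrl", NA), theta = c(0, NA),
                     n_wells = c(100, 100), stringsAsFactors = FALSE)
  for (b in c(0.02, 0.1)) {
    cfg <- sim_config(alpha = 1, bleach_per_scan = b, n_scans = 3)
    plate <- simulate_plate(cond, cfg, seed = 23 + round(100 * b))
    w <- pife_by_well(plate)
    sem <- sd(w$wash_pife) / sqrt(nrow(w))
    expect_lt(abs(mean(w$wash_pife)), 2 * sem + 2 * sem / sqrt(100))
  }
})

test_that("wash-phase PIFE decreases strictly with cleavage fraction", {
  vals <- vapply(c(0, 0.3, 0.6, 0.9), function(cl) {
    cond <- data.frame(replicate_group = c("g", "ctrl"),
                       role = c("sample", "buffer_control"),
                       control_group = c("ctrl", NA), theta = c(0.5, NA),
                       cleavage_fraction = c(cl, 0),
                       stringsAsFactors = FALSE)
    cfg <- sim_config(noise_cv = 0, point_cv = 0, n_scans = 3)
    plate <- simulate_plate(cond, cfg, seed = 3, n_replicates = 1)
    quantify_pife(plate)$wash_pife
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("presets build valid plates with the documented designs", {
  for (nm in preset_names()) {
    plate <- simulate_preset(nm, seed = 5)
    expect_true(validate_plate(plate))
    truth <- attr(plate, "truth")
    expect_equal(truth$preset, nm)
    expect_true(all(truth$conditions$theta_truth >= 0 &
                      truth$conditions$theta_truth <= 1))
  }
})

test_that("the titration preset plateaus near the configured 0.8 PIFE", {
  plate <- simulate_preset("ku_titration", seed = 31, n_replicates = 10)
  q <- quantify_pife(plate)
  top <- q$pife[q$replicate_group == "ku_20pmol"]
  expect_lt(abs(top - 0.8), 0.08)
})

test_that("the footprint preset gives monotone non-decreasing PIFE with length", {
  plate <- simulate_preset("ku_footprint", seed = 13, n_replicates = 20)
  q <- quantify_pife(plate)
  q <- q[order(as.integer(sub("len_(\\d+)bp", "\\1", q$replicate_group))), ]
  expect_true(all(diff(q$pife) > -0.03)) # monotone up to replicate noise
  expect_lt(q$pife[1], 0.05)  # 10 bp: no stable binding
  expect_gt(q$pife[6], 0.4)   # 15 bp: plateau
})
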