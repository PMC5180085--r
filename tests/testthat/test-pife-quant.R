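# The PIFE statistic: scan aggregation, control correction, replicate
# statistics, condition comparison and normalization.

test_that("aggregate_scan averages correctly under both masks", {
  expect_equal(aggregate_scan(matrix(7, 10, 10)), 7)
  expect_equal(aggregate_scan(matrix(7, 10, 10), mask = "inscribed_circle"), 7)
  expect_equal(aggregate_scan(matrix(c(1, 3, 2, 4), 2, 2)), 2.5)
  # inscribed-circle mask keeps exactly the brute-force point-in-circle set
  n_in <- oracle_circle_count(10)
  g <- matrix(1, 10, 10)
  keep <- mwpife:::.mask_keep(10, "inscribed_circle")
  expect_equal(sum(keep), n_in)
  # mean over masked points only: set excluded corners to a huge value
  g[!keep] <- 1e6
  expect_equal(aggregate_scan(g, mask = "inscribed_circle"), 1)
  expect_error(aggregate_scan(matrix(-1, 2, 2)), ">= 0")
})

test_that("relative_change and compute_pife follow the two-scan formula", {
  expect_equal(relative_change(100, 100), 0)
  expect_equal(relative_change(100, 130), 0.30)
  expect_equal(relative_change(100, 90), -0.10)
  expect_error(relative_change(0, 10), "> 0")

  s <- list(F1 = 100, F2 = 130); c0 <- list(F1 = 100, F2 = 100)
  expect_equal(compute_pife(s, c0), 0.30)
  # bleaching control shifts the corrected value up
  expect_equal(compute_pife(list(F1 = 100, F2 = 117),
                            list(F1 = 100, F2 = 90)), 0.27)
  expect_equal(compute_pife(s, s), 0)
  expect_error(compute_pife(list(F1 = 100, F2 = NA), c0), "second scan")
})

test_that("PIFE is scale-invariant and strictly increasing in the sample signal", {
  s <- list(F1 = 100, F2 = 123); ctl <- list(F1 = 110, F2 = 104)
  base <- compute_pife(s, ctl)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(compute_pife(lapply(s, `*`, k), lapply(ctl, `*`, k)), base,
                 tolerance = 1e-12)
  }
  f2 <- seq(50, 200, by = 10)
  vals <- vapply(f2, function(v) {
    compute_pife(list(F1 = 100, F2 = v), ctl)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("wash-phase PIFE reports recovery, cleavage and cancels bleaching", {
  expect_equal(compute_wash_pife(list(F1 = 100, F3 = 100),
                                 list(F1 = 100, F3 = 100)), 0)
  # cleavage-and-wash signature: near-total signal loss in the sample well
  expect_equal(compute_wash_pife(list(F1 = 100, F3 = 10),
                                 list(F1 = 100, F3 = 100)), -0.90)
  # bleaching common to both wells cancels
  expect_equal(compute_wash_pife(list(F1 = 100, F3 = 80),
                                 list(F1 = 100, F3 = 80)), 0)
  expect_error(compute_wash_pife(list(F1 = 100, F3 = NA),
                                 list(F1 = 100, F3 = 90)), "third scan")
})

test_that("replicate_stats uses the n-1 standard deviation and degenerates at n = 1", {
  st <- replicate_stats(c(0.3, 0.3, 0.3))
  expect_equal(st$mean, 0.3)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 3)
  st2 <- replicate_stats(c(0.2, 0.4))
  expect_equal(st2$sd, sqrt(((0.2 - 0.3)^2 + (0.4 - 0.3)^2) / 1))
  st1 <- replicate_stats(0.5)
  expect_equal(st1$mean, 0.5)
  expect_true(is.na(st1$sd))
  expect_error(replicate_stats(numeric(0)), "no replicate")
})

test_that("condition comparison matches a textbook Welch t evaluation", {
  expect_equal(compare_conditions(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$p, 1)
  # strong separation with tiny jitter drives p toward 0
  p_sep <- compare_conditions(c(0, 1e-6, -1e-6), c(1, 1 + 1e-6, 1 - 1e-6))$p
  expect_lt(p_sep, 1e-10)
  a <- c(0.28, 0.30, 0.32); b <- c(0.01, 0.00, -0.01)
  got <- compare_conditions(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # pooled variant reduces to the classical equal-variance test
  pooled <- compare_conditions(a, b, pooled = TRUE)
  expect_equal(pooled$df, 4)
  expect_error(compare_conditions(0.1, c(0.2, 0.3)), "replicates")
})

test_that("normalization divides means and sds by the named reference mean", {
  res <- data.frame(replicate_group = c("ref", "half", "neg"),
                    pife = c(0.30, 0.15, -0.30),
                    sd = c(0.03, 0.02, 0.06), n = 3,
                    wash_pife = NA, wash_sd = NA, control_group = "ctrl")
  out <- normalize_pife(res, "ref")
  expect_equal(out$normalized_pife, c(1, 0.5, -1))
  expect_equal(out$normalized_sd, c(0.1, 0.02 / 0.3, 0.2))
  expect_error(normalize_pife(res, "missing"), "not found")
  res$pife[1] <- 0
  expect_error(normalize_pife(res, "ref"), "zero")
})

test_that("plate-level quantification recovers per-well arithmetic exactly", {
  # noise-free two-group plate: PIFE must equal the plug-in expectation
  cond <- data.frame(
    replicate_group = c("bound", "ctrl"),
    role = c("sample", "buffer_control"),
    control_group = c("ctrl", NA),
    theta = c(0.5, NA), stringsAsFactors = FALSE
  )
  cfg <- sim_config(noise_cv = 0, point_cv = 0, alpha = 1, distance_bp = 0,
                    bleach_per_scan = 0.03)
  plate <- simulate_plate(cond, cfg, seed = 1)
  q <- quantify_pife(plate)
  df <- distance_factor(0, cfg$d_half, cfg$steepness, cfg$bp_to_nm)
  expect_equal(q$pife[q$replicate_group == "bound"],
               (1 - 0.03) * 1 * df * 0.5, tolerance = 1e-12)
  expect_equal(q$sd[q$replicate_group == "bound"], 0, tolerance = 1e-12)
  expect_equal(q$n, 3)
})
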