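# Independent oracles used to freeze expected values: brute-force bisection
# solvers for the mass-action equilibria, kept deliberately separate from the
# package's closed-form / vectorised implementations.

# free-protein bisection for single-site binding: solves
#   x + D * x / (x + Kd) = P  on  x in [0, P],  theta = x / (x + Kd)
oracle_fraction_bound <- function(D, P, Kd, iters = 200) {
  if (P == 0) return(0)
  lo <- 0; hi <- P
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + D * mid / (mid + Kd) > P) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  x / (x + Kd)
}

# free-protein bisection for probe + competitor
oracle_competition <- function(D, C, P, Kd_D, Kd_C, iters = 200) {
  if (P == 0) return(list(theta_probe = 0, theta_competitor = 0, free_P = 0))
  lo <- 0; hi <- P
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + D * mid / (mid + Kd_D) + C * mid / (mid + Kd_C) > P) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  x <- (lo + hi) / 2
  list(theta_probe = x / (x + Kd_D), theta_competitor = x / (x + Kd_C),
       free_P = x)
}

# brute-force point-in-circle enumeration for an n x n grid at unit spacing:
# points whose centres lie within the circle inscribed in the grid square
oracle_circle_count <- function(n) {
  ctr <- (n + 1) / 2
  r <- n / 2
  cnt <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - ctr)^2 + (j - ctr)^2 <= r^2) cnt <- cnt + 1
    }
  }
  cnt
}

# textbook Welch t-test: statistic, Welch-Satterthwaite df, two-sided p via
# the t CDF
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small randomized-but-valid plate for round-trip property tests
random_plate <- function(n_groups = NULL, grid_size = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_groups)) n_groups <- sample(1:4, 1)
  if (is.null(grid_size)) grid_size <- sample(2:5, 1)
  cond <- data.frame(
    replicate_group = c(sprintf("g%d", seq_len(n_groups)), "ctrl"),
    role = c(rep("sample", n_groups), "buffer_control"),
    control_group = c(rep("ctrl", n_groups), NA),
    protein_pmol = c(stats::runif(n_groups, 0.5, 20), NA),
    kd_nM = c(10^stats::runif(n_groups, 0, 3), NA),
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(grid_size = grid_size,
                    n_scans = sample(2:3, 1),
                    noise_cv = stats::runif(1, 0, 0.1))
  simulate_plate(cond, cfg, n_replicates = sample(1:3, 1))
}
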