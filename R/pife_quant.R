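# Control-corrected PIFE quantification.
#
# The statistic: each well's fluorescence change is expressed relative to its
# own first (pre-protein) scan, and the buffer-only control well's relative
# change — which carries photobleaching and buffer effects — is subtracted:
#   PIFE = (F2 - F1)/F1 [protein well] - (F2 - F1)/F1 [buffer control well].
# The optional wash-phase statistic uses the third scan relative to the first.

#' Mean intensity of a scan grid under a point mask
#'
#' @param grid Square numeric matrix of per-point intensities (counts >= 0).
#' @param mask \code{"all_points"} (default; the instrument already confines
#'   the scan matrix to the well) or \code{"inscribed_circle"} (keep points
#'   whose centres fall within the circle inscribed in the grid square,
#'   unit point spacing).
#' @param stat \code{"mean"} (default) or \code{"median"} for robustness to
#'   point-level outliers.
#' @return Scalar aggregate intensity.
#' @export
aggregate_scan <- function(grid, mask = c("all_points", "inscribed_circle"),
                           stat = c("mean", "median")) {
  mask <- match.arg(mask)
  stat <- match.arg(stat)
  if (!is.matrix(grid) || nrow(grid) != ncol(grid) || nrow(grid) < 1) {
    stop("grid must be a non-empty square matrix")
  }
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("grid intensities must be finite and >= 0")
  }
  keep <- .mask_keep(nrow(grid), mask)
  if (!any(keep)) stop("mask selects no points")
  vals <- grid[keep]
  if (stat == "mean") mean(vals) else stats::median(vals)
}

# logical matrix of points kept by a mask, for an n x n grid at unit spacing
.mask_keep <- function(n, mask) {
  if (mask == "all_points") return(matrix(TRUE, n, n))
  ctr <- (n + 1) / 2
  r <- n / 2 # circle inscribed in the grid square (side n at unit spacing)
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  d2 <= r^2
}

#' Relative signal change between two scans of the same well
#'
#' @param Fa Reference intensity (first scan), must be > 0.
#' @param Fb Later intensity.
#' @return \code{(Fb - Fa)/Fa}; negative under bleaching or signal loss.
#' @export
relative_change <- function(Fa, Fb) {
  if (any(!is.finite(Fa)) || any(Fa <= 0)) {
    stop("reference intensity Fa must be finite and > 0")
  }
  (Fb - Fa) / Fa
}

#' Per-well scan summaries
#'
#' Aggregates every scan of every well to its in-mask mean intensity and the
#' coefficient of variation across grid points.
#'
#' @inheritParams aggregate_scan
#' @param plate A \code{pife_plate}.
#' @return data.frame: well_id, F1, F2, F3 (NA when the scan is absent),
#'   point_cv1..point_cv3.
#' @export
summarize_wells <- function(plate, mask = c("all_points", "inscribed_circle"),
                            stat = c("mean", "median")) {
  mask <- match.arg(mask)
  stat <- match.arg(stat)
  sc <- plate$scans
  g <- max(sc$point_row)
  keep <- .mask_keep(g, mask)
  in_mask <- keep[cbind(sc$point_row, sc$point_col)]
  sub <- sc[in_mask, , drop = FALSE]
  key <- interaction(sub$well_id, sub$scan_index, drop = TRUE)
  agg_fun <- if (stat == "mean") mean else stats::median
  means <- tapply(sub$intensity, key, agg_fun)
  cvs <- tapply(sub$intensity, key, function(v) {
    m <- mean(v)
    if (m > 0 && length(v) > 1) stats::sd(v) / m else 0
  })
  parts <- strsplit(names(means), ".", fixed = TRUE)
  wid <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
                character(1))
  idx <- as.integer(vapply(parts, function(p) p[length(p)], character(1)))

  wells <- unique(plate$layout$well_id)
  out <- data.frame(well_id = wells, F1 = NA_real_, F2 = NA_real_,
                    F3 = NA_real_, point_cv1 = NA_real_, point_cv2 = NA_real_,
                    point_cv3 = NA_real_, stringsAsFactors = FALSE)
  for (k in 1:3) {
    sel <- idx == k
    m <- match(wid[sel], out$well_id)
    out[[paste0("F", k)]][m] <- as.numeric(means[sel])
    out[[paste0("point_cv", k)]][m] <- as.numeric(cvs[sel])
  }
  out
}

#' Control-corrected PIFE from paired well summaries
#'
#' @param sample,control Rows (or lists) with elements F1 and F2: the sample
#'   (protein) well and its paired buffer-only control.
#' @return Dimensionless PIFE fraction (0.30 means a 30\% enhancement).
#' @export
compute_pife <- function(sample, control) {
  if (is.na(sample$F2) || is.na(control$F2)) {
    stop("both wells need a second scan for PIFE")
  }
  relative_change(sample$F1, sample$F2) - relative_change(control$F1, control$F2)
}

#' Control-corrected wash-phase PIFE (third scan relative to the first)
#'
#' After the optional wash step the third scan reports dissociation (signal
#' returns to baseline) or substrate cleavage (labelled fragment washed out,
#' strongly negative values).
#'
#' @param sample,control Rows (or lists) with elements F1 and F3.
#' @return Dimensionless fraction; can approach -1 under complete cleavage.
#' @export
compute_wash_pife <- function(sample, control) {
  if (is.na(sample$F3) || is.na(control$F3)) {
    stop("both wells need a third scan for wash-phase PIFE")
  }
  relative_change(sample$F1, sample$F3) - relative_change(control$F1, control$F3)
}

#' Replicate mean, sample standard deviation and count
#'
#' @param values Numeric vector of per-well statistics (n >= 1).
#' @return List with mean, sd (n-1 denominator; NA for a single replicate)
#'   and n.
#' @export
replicate_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no replicate values")
  list(mean = mean(values),
       sd = if (n >= 2) stats::sd(values) else NA_real_,
       n = n)
}

#' Two-sample comparison of PIFE replicate groups
#'
#' Two-tailed t-test between two replicate groups. Welch (unequal variance)
#' by default — the safer choice at the typical n = 3 per group; the pooled
#' Student variant is available. Optional Holm correction is applied by the
#' caller across a set of comparisons via [stats::p.adjust()].
#'
#' @param a,b Numeric vectors of per-well PIFE values, each n >= 2.
#' @param pooled Use the pooled-variance Student test. Default FALSE (Welch).
#' @return List with t (statistic), p (two-sided p-value), df, and method.
#' @export
compare_conditions <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 replicates")
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), method = if (pooled) "student" else "welch")
}

#' Quantify control-corrected PIFE for every replicate group of a plate
#'
#' Each sample well's relative change is corrected with the mean per-scan
#' signal of its paired buffer-control group (so a multi-well control group
#' contributes one stable reference), then per-well PIFE values are averaged
#' within replicate groups.
#'
#' @inheritParams summarize_wells
#' @return data.frame: replicate_group, pife, sd, n, wash_pife, wash_sd,
#'   control_group. wash columns are NA when no third scan exists.
#' @export
quantify_pife <- function(plate, mask = c("all_points", "inscribed_circle"),
                          stat = c("mean", "median")) {
  mask <- match.arg(mask)
  stat <- match.arg(stat)
  layout <- plate$layout
  ws <- summarize_wells(plate, mask, stat)
  ws <- merge(layout[, c("well_id", "role", "replicate_group",
                         "control_group")], ws, by = "well_id", sort = FALSE)

  ctrl <- ws[ws$role == "buffer_control", , drop = FALSE]
  ctrl_mean <- function(group, col) {
    v <- ctrl[[col]][ctrl$replicate_group == group]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }

  smp <- ws[ws$role == "sample", , drop = FALSE]
  groups <- unique(smp$replicate_group)
  res <- lapply(groups, function(grp) {
    rows <- smp[smp$replicate_group == grp, , drop = FALSE]
    cg <- rows$control_group[1]
    cF <- list(F1 = ctrl_mean(cg, "F1"), F2 = ctrl_mean(cg, "F2"),
               F3 = ctrl_mean(cg, "F3"))
    pife_i <- vapply(seq_len(nrow(rows)), function(i) {
      compute_pife(rows[i, ], cF)
    }, numeric(1))
    st <- replicate_stats(pife_i)
    if (all(!is.na(rows$F3)) && !is.na(cF$F3)) {
      wash_i <- vapply(seq_len(nrow(rows)), function(i) {
        compute_wash_pife(rows[i, ], cF)
      }, numeric(1))
      wst <- replicate_stats(wash_i)
    } else {
      wst <- list(mean = NA_real_, sd = NA_real_)
    }
    data.frame(replicate_group = grp, pife = st$mean, sd = st$sd, n = st$n,
               wash_pife = wst$mean, wash_sd = wst$sd, control_group = cg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-well PIFE values (no replicate averaging)
#'
#' Convenience for bootstrap and condition-comparison workflows that need
#' the well-level values underneath [quantify_pife()].
#'
#' @inheritParams summarize_wells
#' @return data.frame: well_id, replicate_group, control_group, pife,
#'   wash_pife (NA when scan 3 absent).
#' @export
pife_by_well <- function(plate, mask = c("all_points", "inscribed_circle"),
                         stat = c("mean", "median")) {
  mask <- match.arg(mask)
  stat <- match.arg(stat)
  layout <- plate$layout
  ws <- summarize_wells(plate, mask, stat)
  ws <- merge(layout[, c("well_id", "role", "replicate_group",
                         "control_group")], ws, by = "well_id", sort = FALSE)
  ctrl <- ws[ws$role == "buffer_control", , drop = FALSE]
  smp <- ws[ws$role == "sample", , drop = FALSE]
  cmean <- function(g, col) {
    v <- ctrl[[col]][ctrl$replicate_group == g]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  out <- smp[, c("well_id", "replicate_group", "control_group")]
  out$pife <- vapply(seq_len(nrow(smp)), function(i) {
    cg <- smp$control_group[i]
    compute_pife(smp[i, ], list(F1 = cmean(cg, "F1"), F2 = cmean(cg, "F2")))
  }, numeric(1))
  out$wash_pife <- vapply(seq_len(nrow(smp)), function(i) {
    cg <- smp$control_group[i]
    c3 <- cmean(cg, "F3")
    if (is.na(smp$F3[i]) || is.na(c3)) return(NA_real_)
    compute_wash_pife(smp[i, ], list(F1 = cmean(cg, "F1"), F3 = c3))
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Normalize group PIFE values to a named reference group
#'
#' Divides each group's mean and sd by the reference group's mean. The
#' reference must be named explicitly: published "normalized PIFE" charts do
#' not define their reference, so no silent default exists.
#'
#' @param results data.frame from [quantify_pife()].
#' @param reference replicate_group to map to 1.0; its mean must be nonzero.
#' @return \code{results} with added columns normalized_pife, normalized_sd.
#' @export
normalize_pife <- function(results, reference) {
  if (!reference %in% results$replicate_group) {
    stop("reference group not found: ", reference)
  }
  ref <- results$pife[results$replicate_group == reference][1]
  if (is.na(ref) || ref == 0) stop("reference group mean is zero or missing")
  results$normalized_pife <- results$pife / ref
  results$normalized_sd <- results$sd / abs(ref)
  results
}
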