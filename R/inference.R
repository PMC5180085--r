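# Estimation of binding parameters from titration and competition series.
#
# Titrations are fit by (weighted) nonlinear least squares to the
# depletion-corrected quadratic isotherm, signal = baseline + A * theta(P);
# uncertainty comes from a case-resampling bootstrap over replicate wells,
# which preserves the small-n replicate structure of plate assays (no
# curvature-based standard errors at n = 3 per point).

#' Construct a titration curve for fitting
#'
#' @param P Total protein concentrations (nM), replicate-level (one entry
#'   per measured well).
#' @param y Measured signal per well (control-corrected PIFE fraction, or
#'   anisotropy change).
#' @param D Total probe concentration (nM).
#' @param sd Optional per-point signal standard deviations (same length as
#'   y) used as inverse-variance weights.
#' @param signal_kind "pife" (baseline fixed at 0: control-corrected data
#'   are zero at P = 0) or "anisotropy" (baseline free).
#' @return List of class \code{titration_curve}.
#' @export
titration_curve <- function(P, y, D, sd = NULL,
                            signal_kind = c("pife", "anisotropy")) {
  signal_kind <- match.arg(signal_kind)
  stopifnot(length(P) == length(y), D > 0, all(P >= 0))
  if (length(unique(P)) < 4) {
    stop("a titration needs >= 4 distinct protein concentrations")
  }
  if (!is.null(sd)) stopifnot(length(sd) == length(y), all(sd >= 0))
  structure(list(P = as.numeric(P), y = as.numeric(y), D = D, sd = sd,
                 signal_kind = signal_kind), class = "titration_curve")
}

# one weighted Levenberg-Marquardt fit from a given start; returns NULL on
# failure. nls.lm is used directly (rather than the nls wrapper) so that
# boundary solutions (Kd at its lower bound, where the Kd gradient vanishes)
# are reported with their RSS instead of erroring.
.fit_once <- function(P, y, w, D, start, fix_baseline) {
  sw <- sqrt(w)
  par0 <- if (fix_baseline) {
    c(Kd = start$Kd, A = start$A)
  } else {
    c(Kd = start$Kd, A = start$A, b0 = start$b0)
  }
  lower <- c(Kd = 1e-9, A = -Inf, b0 = -Inf)[names(par0)]
  resid_fn <- function(par) {
    b0 <- if (fix_baseline) 0 else par[["b0"]]
    sw * (y - b0 - par[["A"]] * fraction_bound(D, P, par[["Kd"]]))
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, lower = lower, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  # info 1-4: convergence by ftol/ptol/gtol; anything else is a failure
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  cf <- fit$par
  list(Kd = unname(cf[["Kd"]]), A = unname(cf[["A"]]),
       baseline = if (fix_baseline) 0 else unname(cf[["b0"]]),
       rss = fit$deviance, fit = fit)
}

# multi-start NLS: Kd0 from the half-max protein concentration, from D and
# from 10 D — guards against the shallow local optimum in the tight-binding
# regime (Kd << D), where the curve shape carries little Kd information
.fit_multistart <- function(P, y, w, D, fix_baseline) {
  ymax <- max(y)
  ymin <- min(0, min(y))
  half <- ymin + 0.5 * (ymax - ymin)
  P_half <- P[which.min(abs(y - half))]
  # include a small start for the tight-binding regime (Kd << D), where
  # half-max occurs near P = D/2 regardless of Kd
  kd_starts <- unique(pmax(c(P_half, D / 5, D, 10 * D), 1e-3))
  best <- NULL
  for (kd0 in kd_starts) {
    st <- list(Kd = kd0, A = ymax, b0 = ymin)
    f <- .fit_once(P, y, w, D, st, fix_baseline)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  best
}

#' Fit a binding titration (Kd, amplitude, baseline)
#'
#' Weighted nonlinear least squares of
#' \code{baseline + A * fraction_bound(D, P, Kd)} to replicate-level data,
#' with multi-start initialisation, followed (optionally) by a
#' case-resampling bootstrap over wells for percentile confidence
#' intervals.
#'
#' @param curve A [titration_curve()].
#' @param n_boot Bootstrap resamples (0 = none). 500+ recommended for CIs.
#' @param seed Seed making the bootstrap deterministic.
#' @param weights "auto" (1/sd^2 when sds supplied, else unweighted),
#'   "none", or a numeric vector.
#' @return Object of class \code{binding_fit}: list with Kd, A, baseline,
#'   rss, converged, n, and (when bootstrapped) ci (2 x parameters matrix
#'   of percentile 95\% bounds), se, n_boot_ok, boot_unreliable.
#' @export
fit_binding <- function(curve, n_boot = 0, seed = NULL,
                        weights = "auto") {
  stopifnot(inherits(curve, "titration_curve"))
  P <- curve$P; y <- curve$y; D <- curve$D
  fix_baseline <- curve$signal_kind == "pife"
  n_par <- if (fix_baseline) 2L else 3L
  if (length(y) <= n_par) stop("fewer points than parameters")

  if (is.numeric(weights)) {
    w <- weights
  } else if (identical(weights, "auto") && !is.null(curve$sd) &&
             all(curve$sd > 0)) {
    w <- 1 / curve$sd^2
  } else {
    w <- rep(1, length(y))
  }

  best <- .fit_multistart(P, y, w, D, fix_baseline)
  if (is.null(best)) {
    return(structure(list(converged = FALSE, Kd = NA_real_, A = NA_real_,
                          baseline = NA_real_, rss = NA_real_,
                          n = length(y), signal_kind = curve$signal_kind),
                     class = "binding_fit"))
  }
  out <- list(Kd = best$Kd, A = best$A, baseline = best$baseline,
              rss = best$rss, converged = TRUE, n = length(y), D = D,
              signal_kind = curve$signal_kind)
  class(out) <- "binding_fit"
  if (n_boot > 0) {
    bs <- bootstrap_ci(curve, n_boot = n_boot, seed = seed,
                       weights = weights)
    out$ci <- bs$ci
    out$se <- bs$se
    out$n_boot_ok <- bs$n_success
    out$boot_unreliable <- bs$unreliable
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("binding fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("binding fit: Kd = %.3g nM, A = %.3g, baseline = %.3g (RSS %.3g)\n",
              x$Kd, x$A, x$baseline, x$rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: Kd [%.3g, %.3g], A [%.3g, %.3g] (%d resamples)\n",
                x$ci["lo", "Kd"], x$ci["hi", "Kd"],
                x$ci["lo", "A"], x$ci["hi", "A"], x$n_boot_ok))
  }
  invisible(x)
}

#' Case-resampling bootstrap CIs for a titration fit
#'
#' Resamples replicate wells with replacement within each protein
#' concentration (preserving the design), refits, and reports percentile
#' 95\% intervals. Deterministic given the seed.
#'
#' With m replicates per concentration, within-group case resampling
#' underestimates sampling variance (by at least the exact factor (m-1)/m
#' for linear statistics), so plain percentile intervals undercover badly
#' at the typical m = 3. The interval keeps the percentile shape of the
#' bootstrap distribution but calibrates its width: deviations around the
#' point estimate are rescaled so the implied standard error equals the
#' delete-one-well jackknife standard error (nearly unbiased for smooth
#' estimators), with t quantiles on the design's sum(m_g - 1) replicate
#' degrees of freedom in place of normal quantiles. Both corrections
#' vanish as replication grows.
#'
#' @inheritParams fit_binding
#' @return List: ci (matrix, rows lo/hi, width-calibrated), se (jackknife
#'   standard errors), n_success (successful refits), unreliable (TRUE when
#'   fewer than 50 refits succeeded or the design has no replicate degrees
#'   of freedom).
#' @export
bootstrap_ci <- function(curve, n_boot = 500, seed = NULL, weights = "auto") {
  stopifnot(inherits(curve, "titration_curve"), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  P <- curve$P; y <- curve$y
  groups <- split(seq_along(P), P)
  fix_baseline <- curve$signal_kind == "pife"

  if (is.numeric(weights)) w_all <- weights
  else if (identical(weights, "auto") && !is.null(curve$sd) &&
           all(curve$sd > 0)) w_all <- 1 / curve$sd^2
  else w_all <- rep(1, length(y))

  base <- .fit_multistart(P, y, w_all, curve$D, fix_baseline)
  if (is.null(base)) stop("base fit did not converge; no bootstrap possible")
  start <- list(Kd = base$Kd, A = base$A, b0 = base$baseline)

  pars <- c("Kd", "A", if (!fix_baseline) "baseline")
  draws <- matrix(NA_real_, n_boot, length(pars),
                  dimnames = list(NULL, pars))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) {
      g[sample.int(length(g), length(g), replace = TRUE)]
    }), use.names = FALSE)
    f <- .fit_once(P[idx], y[idx], w_all[idx], curve$D, start, fix_baseline)
    if (is.null(f)) {
      f <- .fit_multistart(P[idx], y[idx], w_all[idx], curve$D, fix_baseline)
    }
    if (!is.null(f)) {
      draws[b, "Kd"] <- f$Kd
      draws[b, "A"] <- f$A
      if (!fix_baseline) draws[b, "baseline"] <- f$baseline
    }
  }
  ok <- stats::complete.cases(draws)
  n_success <- sum(ok)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  est <- c(Kd = base$Kd, A = base$A,
           baseline = base$baseline)[pars]

  # width calibration (see Details): delete-one-well jackknife SE
  n <- length(y)
  jk <- matrix(NA_real_, n, length(pars), dimnames = list(NULL, pars))
  for (i in seq_len(n)) {
    f <- .fit_once(P[-i], y[-i], w_all[-i], curve$D, start, fix_baseline)
    if (is.null(f)) {
      f <- .fit_multistart(P[-i], y[-i], w_all[-i], curve$D, fix_baseline)
    }
    if (!is.null(f)) {
      jk[i, "Kd"] <- f$Kd
      jk[i, "A"] <- f$A
      if (!fix_baseline) jk[i, "baseline"] <- f$baseline
    }
  }
  se_jack <- apply(jk, 2, function(v) {
    v <- v[!is.na(v)]
    sqrt((length(v) - 1) / length(v) * sum((v - mean(v))^2))
  })
  se_boot <- apply(draws[ok, , drop = FALSE], 2, stats::sd)

  m_g <- lengths(groups)
  df <- sum(pmax(m_g - 1, 0))
  tz <- if (df > 0) stats::qt(0.975, df) / stats::qnorm(0.975) else 1
  cf <- ifelse(se_boot > 0, tz * se_jack / se_boot, 1)
  ci <- rbind(lo = est + (qs[1, ] - est) * cf,
              hi = est + (qs[2, ] - est) * cf)
  list(ci = ci, se = se_jack, n_success = n_success,
       unreliable = n_success < 50 || df == 0)
}

#' Fit a competition series for the competitor's affinity and IC50
#'
#' Least-squares fit of \code{pife_max * theta_probe(Kd_C)} (occupancy from
#' [solve_competition()]) to PIFE measured at several competitor excess
#' levels, with the probe affinity \code{Kd_D} supplied (previously
#' estimated). The single free parameter is \code{Kd_C}, optimised on a log
#' scale. IC50 — the fold-excess halving the uncompeted PIFE — is read off
#' the fitted curve by root-finding.
#'
#' A flat series (suppression at the highest excess smaller than twice the
#' replicate scatter) is reported as censored: \code{Kd_C} has no point
#' estimate, only a lower bound ("weaker than testable").
#'
#' @param excess Competitor fold-excess over the probe, replicate-level.
#'   Include excess 0 rows (uncompeted PIFE) when \code{pife_max} is not
#'   supplied.
#' @param pife Measured control-corrected PIFE per well.
#' @param D,P Probe and protein totals (nM).
#' @param Kd_D Probe affinity (nM), known.
#' @param pife_max PIFE at full probe occupancy (i.e. the enhancement
#'   amplitude). Default: uncompeted mean PIFE divided by the uncompeted
#'   occupancy.
#' @param n_boot Bootstrap resamples for a Kd_C CI (0 = none).
#' @param seed Bootstrap seed.
#' @return List of class \code{competition_fit}: Kd_C, IC50, censored flag,
#'   Kd_C_lower (for censored series), rss, and optional ci.
#' @export
fit_competition <- function(excess, pife, D, P, Kd_D, pife_max = NULL,
                            n_boot = 0, seed = NULL) {
  stopifnot(length(excess) == length(pife), all(excess >= 0), D > 0, P >= 0,
            Kd_D > 0)
  theta0 <- fraction_bound(D, P, Kd_D)
  if (is.null(pife_max)) {
    if (!any(excess == 0)) {
      stop("supply pife_max or include excess == 0 (uncompeted) wells")
    }
    pife_max <- mean(pife[excess == 0]) / theta0
  }
  pos <- excess > 0
  if (length(unique(excess[pos])) < 3) {
    stop("need >= 3 nonzero excess levels")
  }
  exc <- excess[pos]; yy <- pife[pos]

  predict_pife <- function(kd_c, e = exc) {
    pife_max * solve_competition(D, e * D, P, Kd_D, kd_c)$theta_probe
  }

  # flat-series guard: no detectable suppression at the strongest challenge
  top <- max(exc)
  y_top <- yy[exc == top]
  supp <- pife_max * theta0 - mean(y_top)
  scatter <- if (length(y_top) >= 2) {
    stats::sd(y_top) / sqrt(length(y_top))
  } else {
    0.05 * pife_max * theta0
  }
  if (supp < 2 * scatter) {
    # smallest affinity that would have produced a detectable suppression
    lower <- tryCatch(stats::uniroot(function(lk) {
      (pife_max * theta0 - predict_pife(10^lk, top)) - 2 * scatter
    }, c(log10(Kd_D) - 6, log10(Kd_D) + 10))$root, error = function(e) NA)
    return(structure(list(censored = TRUE, Kd_C = NA_real_,
                          Kd_C_lower = if (is.na(lower)) NA_real_ else 10^lower,
                          IC50 = NA_real_, pife_max = pife_max),
                     class = "competition_fit"))
  }

  obj <- function(lk) sum((yy - predict_pife(10^lk))^2)
  opt <- stats::optimize(obj, c(log10(Kd_D) - 6, log10(Kd_D) + 9))
  kd_c <- 10^opt$minimum

  half <- 0.5 * pife_max * theta0
  ic50 <- tryCatch(stats::uniroot(function(le) {
    predict_pife(kd_c, 10^le) - half
  }, c(-6, 9))$root, error = function(e) NA)
  out <- list(censored = FALSE, Kd_C = kd_c,
              IC50 = if (is.na(ic50)) NA_real_ else 10^ic50,
              rss = opt$objective, pife_max = pife_max)
  class(out) <- "competition_fit"

  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    groups <- split(which(pos), exc)
    draws <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      eb <- excess[idx]; yb <- pife[idx]
      ob <- function(lk) {
        sum((yb - pife_max *
               solve_competition(D, eb * D, P, Kd_D, 10^lk)$theta_probe)^2)
      }
      draws[b] <- 10^stats::optimize(ob, c(log10(Kd_D) - 6,
                                           log10(Kd_D) + 9))$minimum
    }
    out$ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    out$n_boot_ok <- sum(!is.na(draws))
  }
  out
}

#' @export
print.competition_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("competition fit: no suppression detected; Kd_C > %.3g nM\n",
                x$Kd_C_lower))
  } else {
    cat(sprintf("competition fit: Kd_C = %.3g nM, IC50 = %.3g-fold excess\n",
                x$Kd_C, x$IC50))
  }
  invisible(x)
}
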