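# Equilibrium models linking concentrations and affinities to probe occupancy.
# All concentrations are nM internally; unit conversion happens only at I/O.

#' Convert a pipetted amount to a well concentration
#'
#' Plate protocols report amounts as pipetted (pmol in a stated well volume);
#' all equilibrium computations here run on concentrations.
#'
#' @param pmol Amount of material in the well (pmol). Vectorised.
#' @param volume_ul Well volume in microlitres. Must be > 0.
#' @return Concentration in nM (pmol/ul equals uM, so pmol/ul * 1000 = nM).
#' @examples
#' pmol_to_nM(2.5, 100) # 25 nM, a typical immobilized-probe loading
#' @export
pmol_to_nM <- function(pmol, volume_ul) {
  if (any(!is.finite(volume_ul)) || any(volume_ul <= 0)) {
    stop("volume_ul must be positive and finite")
  }
  if (any(pmol < 0, na.rm = TRUE)) stop("pmol must be >= 0")
  pmol / volume_ul * 1000
}

#' Fraction of labelled probe bound at equilibrium (quadratic isotherm)
#'
#' Single-site mass action with ligand depletion: the probe concentration is
#' allowed to be comparable to (or exceed) the dissociation constant, so the
#' hyperbolic approximation does not apply and the bound fraction is the
#' smaller root of the binding quadratic,
#' \deqn{\theta = \frac{(D+P+K_d) - \sqrt{(D+P+K_d)^2 - 4DP}}{2D}.}
#'
#' @param D Total labelled probe concentration (nM), > 0.
#' @param P Total protein concentration (nM), >= 0. Vectorised.
#' @param Kd Dissociation constant (nM), > 0.
#' @return Occupancy theta in [0, 1]: fraction of probe molecules bound.
#' @details The root is evaluated in its conjugate form
#'   \code{2*P / (S + sqrt(S^2 - 4*D*P))} with \code{S = D + P + Kd}, which
#'   avoids catastrophic cancellation when \code{S^2 >> 4*D*P} (weak binding
#'   or strong excess). The discriminant is clamped at zero against
#'   floating-point underflow; it is non-negative for all valid inputs.
#' @seealso [binding_signal()], [solve_competition()]
#' @examples
#' fraction_bound(D = 25, P = 10, Kd = 10)
#' @export
fraction_bound <- function(D, P, Kd) {
  if (any(D <= 0) || any(Kd <= 0)) stop("D and Kd must be > 0")
  if (any(P < 0)) stop("P must be >= 0")
  S <- D + P + Kd
  disc <- S^2 - 4 * D * P
  disc[disc < 0] <- 0
  theta <- 2 * P / (S + sqrt(disc))
  pmin(theta, 1)
}

#' Expected equilibrium signal for a titration
#'
#' Linear signal model on top of occupancy: \code{baseline + A * theta}.
#' With \code{baseline = 0} and \code{A} the maximum anisotropy change this
#' is the standard depletion-corrected anisotropy binding equation; with
#' \code{A} the maximum population PIFE it is the PIFE titration model.
#'
#' @param D,P,Kd As in [fraction_bound()].
#' @param A Maximum signal amplitude at full occupancy (dimensionless).
#' @param baseline Signal at zero occupancy. Default 0.
#' @return Expected signal, same length as the longest argument.
#' @export
binding_signal <- function(D, P, Kd, A, baseline = 0) {
  baseline + A * fraction_bound(D, P, Kd)
}

#' Simultaneous competition equilibrium for probe and unlabelled competitor
#'
#' Solves the three-species mass-action system in which free protein \code{x}
#' partitions between a labelled probe (total \code{D}, affinity \code{Kd_D})
#' and an unlabelled competitor (total \code{C}, affinity \code{Kd_C}):
#' \deqn{x + D\frac{x}{x+K_{dD}} + C\frac{x}{x+K_{dC}} = P.}
#' The left-hand side is strictly increasing in \code{x}, so the root on
#' \code{[0, P]} exists and is unique; it is found by monotone bisection,
#' which is robust across the full concentration range (preferred over the
#' closed-form cubic).
#'
#' @param D Total labelled probe (nM), >= 0.
#' @param C Total competitor (nM), >= 0. Vectorised.
#' @param P Total protein (nM), >= 0. Vectorised.
#' @param Kd_D,Kd_C Dissociation constants (nM), > 0.
#' @return A data.frame with columns \code{theta_probe} (probe occupancy),
#'   \code{theta_competitor}, and \code{free_P} (free protein, nM).
#' @details 120 bisection steps take the bracket to below machine precision
#'   relative to \code{P}; species totals are conserved to relative 1e-12.
#'   \code{C = 0} reduces exactly to [fraction_bound()].
#' @examples
#' solve_competition(D = 25, C = 250, P = 50, Kd_D = 10, Kd_C = 10)
#' @export
solve_competition <- function(D, C, P, Kd_D, Kd_C) {
  if (any(Kd_D <= 0) || any(Kd_C <= 0)) stop("Kd_D and Kd_C must be > 0")
  if (any(D < 0) || any(C < 0) || any(P < 0)) {
    stop("concentrations must be >= 0")
  }
  n <- max(length(D), length(C), length(P), length(Kd_D), length(Kd_C))
  D <- rep_len(D, n); C <- rep_len(C, n); P <- rep_len(P, n)
  Kd_D <- rep_len(Kd_D, n); Kd_C <- rep_len(Kd_C, n)

  lo <- rep_len(0, n)
  hi <- P
  # total protein accounted for at free-protein concentration x
  balance <- function(x) x + D * x / (x + Kd_D) + C * x / (x + Kd_C)
  for (i in seq_len(120)) {
    mid <- 0.5 * (lo + hi)
    high <- balance(mid) > P
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  x <- 0.5 * (lo + hi)
  x[P == 0] <- 0
  data.frame(
    theta_probe = ifelse(x + Kd_D > 0, x / (x + Kd_D), 0),
    theta_competitor = ifelse(x + Kd_C > 0, x / (x + Kd_C), 0),
    free_P = x
  )
}

#' Distance falloff of the fluorescence enhancement
#'
#' PIFE responds only to protein bound in the immediate vicinity of the dye
#' (sharp falloff over roughly 0-3 nm). The functional form of that falloff
#' is not calibrated by plate-scale data, so a logistic stand-in is used:
#' \deqn{f(d) = \frac{1}{1 + e^{s (d - d_{1/2})}}, \quad d = \mathrm{bp} \times 0.34\,\mathrm{nm}.}
#' Defaults put the response near 1 at <= 1 bp and below 1e-4 at >= 16 bp,
#' matching the observed pattern that binding sites 16 bp or further from the
#' dye produce no enhancement above background.
#'
#' @param distance_bp Distance between dye and protein binding site, in base
#'   pairs (>= 0; \code{Inf} allowed for "no site"). Vectorised.
#' @param d_half Distance of half-maximal enhancement (nm). Default 2.
#' @param steepness Logistic steepness (1/nm). Default 4.
#' @param bp_to_nm Helix rise per base pair (nm/bp). Default 0.34.
#' @return Multiplier in [0, 1] applied to the enhancement factor.
#' @export
distance_factor <- function(distance_bp, d_half = 2, steepness = 4,
                            bp_to_nm = 0.34) {
  if (any(distance_bp < 0, na.rm = TRUE)) stop("distance_bp must be >= 0")
  if (d_half <= 0 || steepness <= 0 || bp_to_nm <= 0) {
    stop("d_half, steepness and bp_to_nm must be > 0")
  }
  d <- distance_bp * bp_to_nm
  1 / (1 + exp(steepness * (d - d_half)))
}
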