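---
title: "Quantifying protein-nucleic acid binding from microwell PIFE plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-nucleic acid binding from microwell PIFE plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwpife)
```

## The assay and its statistic

Protein-induced fluorescence enhancement (PIFE) is the increase in
fluorescence of Cy3-family dyes when a protein binds a labelled nucleic acid
within roughly 0-3 nm of the dye, sterically blocking photoisomerization to
the dark *cis* state. In the microwell implementation this package analyses,
a biotinylated Cy3-labelled DNA probe is immobilized in a neutravidin-coated
well (typically 2.5 pmol in 100 µl, i.e. 25 nM), scanned once before protein
addition, incubated with protein to equilibrium (~30 min), and scanned
again; an optional buffer-exchange wash is followed by a third scan. Each
scan is a grid of point intensities (default 10 × 10 points within the
well).

The population-level statistic is a *paired relative change*:

$$\mathrm{PIFE} \;=\; \frac{F_2 - F_1}{F_1}\bigg|_{\text{protein well}} \;-\;
\frac{F_2 - F_1}{F_1}\bigg|_{\text{buffer-only well}},$$

where $F_k$ is the in-mask mean intensity of scan $k$. The subtracted
buffer-only control well carries photobleaching and buffer effects, so the
corrected statistic is (to first order) the bound-state enhancement diluted
by occupancy. The wash-phase variant uses $F_3$ relative to $F_1$ and
reports dissociation (values near 0) or substrate cleavage (strongly
negative values: the labelled fragment leaves with the wash).

Two properties of the difference form are worth keeping in mind:

* **Bleach attenuation of the enhancement term.** With per-scan bleaching
  fraction $b$ and population enhancement $\alpha f(d) \theta$ (enhancement
  factor × distance response × occupancy), the expectation of the corrected
  statistic is $(1-b)\,\alpha f(d)\theta$, not $\alpha f(d)\theta$: the
  subtraction cancels the additive bleach term but not its product with the
  enhancement. At the few-percent bleach rates of plate readers this is a
  2-3 % relative shrinkage, absorbed into the fitted amplitude and
  irrelevant to $K_d$ estimation.
* **Bleach-squared residual in the wash statistic.** A cleavage signal rides
  on twice-bleached signal: with cleaved fraction $c$ the expected
  wash-phase PIFE is $-c\,(1-b)^2$, not $-c$. Complete cleavage of 90 % of
  probes at $b = 0.03$ therefore reads about $-0.85$, not $-0.90$. A
  ratio-form correction would remove this residual but would not match the
  field's published difference-form definition, which this package follows.

Replicate groups (typically three wells per condition) are summarised by
mean and $n-1$ standard deviation; when a control group has several wells,
its per-scan means are pooled before correction so every sample well is
corrected with one stable reference. Group comparisons use a two-tailed
t-test — Welch by default, since at $n = 3$ per group the equal-variance
assumption buys little and costs robustness; the pooled variant is a flag.
No multiplicity correction is applied by default (raw p-values are the
field's convention); `stats::p.adjust(..., "holm")` is one call away.
Normalization to a reference condition divides group means and sds by the
named reference mean; the reference must be stated explicitly because
published "normalized PIFE" charts do not define theirs, and guessing
silently would bake an arbitrary convention into results.

### Scan aggregation

The default mask uses all grid points (`all_points`): the instrument
confines the scan matrix to the well diameter, so every point is
informative. An `inscribed_circle` mask (points whose centres fall within
the circle inscribed in the grid square) is available for instruments whose
rectangular grids overhang the well; for a 10 × 10 grid it keeps 80 of 100
points. Point-level outliers are not rejected by default; a median
aggregation flag provides robustness when needed.

## Equilibrium models

Probe and protein concentrations in these assays are commonable with the
dissociation constant (25 nM probe vs ~10 nM $K_d$ for a tight binder), so
the hyperbolic isotherm is wrong and the ligand-depletion quadratic is used
throughout. With totals $D$ (probe) and $P$ (protein),

$$\theta \;=\; \frac{(D+P+K_d) - \sqrt{(D+P+K_d)^2 - 4DP}}{2D},$$

evaluated in the conjugate form $2P/(S + \sqrt{S^2 - 4DP})$,
$S = D+P+K_d$, to avoid catastrophic cancellation when $S^2 \gg 4DP$. The
expected signal is $\mathrm{baseline} + A\,\theta$; with the anisotropy
amplitude for $A$ this is exactly the standard depletion-corrected
anisotropy binding equation.

Competition with an unlabelled species (total $C$, affinity $K_{dC}$) is
modelled as simultaneous single-site mass action. Free protein $x$ solves

$$x + D\frac{x}{x+K_{dD}} + C\frac{x}{x+K_{dC}} = P,$$

whose left side is strictly increasing, so the root is unique and found by
monotone bisection (120 steps, i.e. to machine precision; species totals
conserve to relative $10^{-12}$). Bisection is preferred over the
closed-form cubic for numerical robustness across the six-decade
concentration ranges these assays span. The model deliberately excludes
cooperativity, multi-site loading and kinetics: the assay is read at a
30-minute equilibrium endpoint.

The distance response $f(d) = 1/(1 + e^{s(d - d_{1/2})})$ with defaults
$d_{1/2} = 2$ nm, $s = 4$ nm$^{-1}$ and 0.34 nm/bp is a logistic stand-in
for the true (uncalibrated at plate scale) PIFE distance dependence. The
defaults were chosen once so that the response is essentially full at
$\leq 1$ bp and below $10^{-4}$ at $\geq 16$ bp, matching the observed
pattern that sites 16 bp or further from the dye give no enhancement above
background; all three parameters are exposed.

## Inference

`fit_binding()` fits $y = \mathrm{baseline} + A\,\theta(D, P, K_d)$ to
replicate-level points by Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`), weighted $1/\mathrm{sd}^2$ when per-point sds are
supplied. For PIFE curves the baseline is fixed at 0 — control-corrected
data are zero at $P = 0$ by construction — while anisotropy curves keep it
free; a flag overrides. Initialisation is multi-start over
$K_d^{(0)} \in \{P_{\text{half-max}},\ D/5,\ D,\ 10D\}$: in the
tight-binding regime ($K_d \ll D$, exactly the strong end-binder case) the
half-max abscissa sits near $D/2$ regardless of $K_d$ and carries little
information, so small and large starts guard against the shallow local
optimum. Boundary solutions ($K_d$ at its lower bound) are kept as
candidates with their RSS rather than erroring, and the best converged
start wins. Non-convergence across all starts is flagged and no estimates
are reported.

### Uncertainty

Per-parameter uncertainty comes from a case-resampling bootstrap over
replicate wells within each concentration — the resampling unit matches the
experiment's replication unit (independent wells), and no curvature-based
standard errors are reported because $n = 3$ per point is far from
asymptopia. Plain percentile intervals from this scheme, however,
undercover badly at $m = 3$ replicates: within-group resampling
underestimates variance by at least $(m-1)/m$, and the few informative
concentrations make the effective degrees of freedom small. The interval
therefore keeps the *shape* of the bootstrap distribution but calibrates
its *width*: percentile deviations around the point estimate are rescaled
so the implied standard error equals the delete-one-well jackknife standard
error (nearly unbiased for smooth estimators), and normal quantiles are
replaced by $t$ quantiles on the design's $\sum_g (m_g - 1)$ replicate
degrees of freedom. Both corrections vanish as replication grows;
noise-free data still collapse to zero-width intervals. Coverage at the
titration design is verified by simulation in the test suite (500
simulated experiments; required to land in the 90-99 % range). The
bootstrap is deterministic given its seed; intervals built from fewer than
50 successful refits, or from designs with no replicate degrees of
freedom, are flagged unreliable.

`fit_competition()` fits $\mathrm{PIFE}_{\max}\,\theta_{\text{probe}}(K_{dC})$
over the excess series with $K_{dC}$ as the single free parameter (log-scale
1-D optimisation), the probe affinity being supplied. IC50 is defined on
the fold-excess axis (amounts are reported as excess over probe) and read
off the fitted curve by root-finding. A flat series — suppression at the
strongest challenge below twice the replicate scatter — is censored: the
result is a lower bound on $K_{dC}$ (the weakest affinity that would have
produced detectable suppression), never a point estimate.

## The synthetic plate generator

No raw plate data are deposited for assays of this kind, so the package
ships a generative model that stands in for the wet laboratory. Its
structure is the analysis model run forwards plus noise:

$$E[F_k] = B \cdot \mathrm{pmol} \cdot (1-b)^{k-1}
\cdot \bigl(1 + \alpha f(d)\,\theta_k\bigr) \cdot s_k,$$

with brightness $B$ per pmol probe, occupancy $\theta_k$ appropriate to the
scan (0 before protein; $\theta$ after incubation; $\theta \times$
wash-retention after the wash), and survival $s_k$ = 1 − cleaved fraction
at the post-wash scan only. Realised intensities multiply this expectation
by mean-one lognormal factors: one per well-scan (default CV 5 %) and one
per grid point (default CV 2 %) — fluorescence noise scales with signal,
and no additive dark-count term is included by default. Occupancies come
from the equilibrium models above, or are set directly as truth where the
scenario encodes something the model does not cover (position-dependent
occupancy in the translocation scenario, a length-to-affinity map in the
footprint scenario). Identical seeds give bit-identical plates.

Default magnitudes follow the protocol and the literature: $\alpha = 1$
(the ~2-fold single-dye enhancement), 2.5 pmol probe in 100 µl, 3 % bleach
per scan, 10 × 10 grids. Population PIFE values of 0.3-0.8 then arise from
sub-unity occupancy and the distance factor, consistent with plate-scale
values being far below single-molecule enhancements; presets tune
*occupancy* (through concentrations and affinities), not $\alpha$, to sit
in the observed ranges. The well-to-well CV is not reported for the
instrument class, so the 5 % default is an assumption, exposed in the
configuration.

Presets cover the main experiment classes: a restriction-enzyme distance
panel (sites 1/16/31/46 bp from the dye plus a no-site probe, occupancy
~0.58 as under divalent-cation binding conditions), a cation panel with
wash phase (chelator/weak binding, Ca²⁺/binding without cleavage,
Mg²⁺/90 % cleavage), sequence- and structure-specific competition (the
latter with competitor affinities 640/810/1320/4750/8650 nM at 1/10/100×
excess and probe truth $K_d$ = 200 nM so the uncompeted PIFE is ~0.8), an
end-binder titration (truth $K_d$ = 10 nM, 0.5-20 pmol protein, $\alpha$
calibrated through the bleach attenuation so the plateau PIFE is 0.8), a
minimal-footprint series (duplex lengths 10-15 bp with a configured
affinity map rising steeply between 11 and 13 bp) and a translocation
scenario (occupancy profile decreasing with distance from the free DNA
end). Where a preset needs a latent value the source experiments never
measured — the immobilized probe's own affinity in the competition
scenario, the footprint affinity map — the preset fixes a documented truth
chosen once to put the simulated readout in the observed range; these are
generative truths for testing the pipeline, not estimates about any real
system.

### What the simulator does and does not establish

Passing tests on simulated plates show that the quantification is unbiased
under the stated noise model, that fits recover generative truths, and that
intervals are calibrated at the stated designs. They cannot establish
instrument-specific behaviour the model omits: inner-filter effects,
scan-order drift beyond what the paired control cancels, spatial structure
across the well surface, surface-immobilization departures from
solution-phase equilibrium (the immobilized probe is treated as well-mixed
at its nominal concentration — a stated limitation), or photophysics beyond
a single enhancement factor.

## Numerical and design notes

* Concentrations are nM internally; files store pipetted amounts (pmol) and
  volumes, converted at I/O, because protocols report amounts.
* The binding quadratic's discriminant is clamped at zero against
  floating-point underflow; occupancy is capped at 1.
* CSV round trips are lossless: numerics are written with 17 significant
  digits, and absent third scans are encoded by absent rows, never
  sentinel zeros.
* Degenerate inputs fail loudly and specifically: unpaired sample groups,
  non-numeric intensities (with row numbers), wells missing their
  reference scan, incomplete grids.
* Test and check problem sizes were chosen for statistical resolution at
  interactive runtimes: 1,000-point oracle grids, 100-200 simulated
  experiments for recovery studies, 500 for interval calibration, 60-100
  well pairs where a mean must resolve a few-percent effect.

## Worked example

```{r example}
plate <- simulate_preset("ku_titration", seed = 7)
quantify_pife(plate)

wells <- pife_by_well(plate)
lay <- plate$layout[plate$layout$role == "sample", ]
wells <- merge(wells, lay[, c("well_id", "protein_pmol", "volume_ul")],
               by = "well_id")
curve <- titration_curve(P = pmol_to_nM(wells$protein_pmol, wells$volume_ul),
                         y = wells$pife, D = pmol_to_nM(2.5, 100))
fit_binding(curve, n_boot = 500, seed = 1)
```

The generative truth behind this plate is $K_d = 10$ nM; the wide interval
is the honest consequence of estimating a tight binder ($K_d < D$) from
three wells per concentration.
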