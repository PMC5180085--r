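# mwpife

Analysis of **microwell protein-induced fluorescence enhancement (mwPIFE)**
assays: a plate-reader method for steady-state quantification of
protein-nucleic acid binding without protein labelling. Cy3-family dyes
fluoresce more brightly when a protein binds the labelled nucleic acid
within ~0-3 nm of the dye (blocking photoisomerization to the dark *cis*
state); measured over a population of immobilized probes in a microwell,
that enhancement reports occupancy — and hence affinity, specificity,
cleavage and translocation — from nothing more than two or three
fluorescence scans per well.

The package is for biochemists and assay developers who run (or plan) such
plates: it reads and validates plate layouts and multi-scan well data,
computes the control-corrected PIFE statistic with replicate statistics and
condition comparisons, fits equilibrium binding models for dissociation
constants, and ships a generative plate simulator so every pipeline stage
is testable without laboratory data.

## The statistic and the models

Each well's signal change is taken relative to its own pre-protein scan and
corrected with a paired buffer-only control well (which carries
photobleaching and buffer effects):

    PIFE = (F2 - F1)/F1 [protein well] - (F2 - F1)/F1 [buffer control]

An optional post-wash third scan gives the wash-phase statistic
(F3 relative to F1), separating dissociation (≈ 0) from substrate cleavage
(strongly negative).

Because probe concentrations (~25 nM) are comparable to the dissociation
constants of interest, titrations are fit with the ligand-depletion
quadratic isotherm rather than the hyperbola:

    theta = ((D + P + Kd) - sqrt((D + P + Kd)^2 - 4 D P)) / (2 D)
    signal = baseline + A * theta

with case-resampling bootstrap confidence intervals over replicate wells
(width-calibrated for small replicate counts; see the methods vignette).
Competition series are modelled by simultaneous mass action — free protein
solves `x + D x/(x+Kd_D) + C x/(x+Kd_C) = P`, found by monotone bisection —
yielding competitor affinities and fold-excess IC50s.

## Worked example

Simulate an end-binder titration plate (generative truth: Kd = 10 nM,
25 nM probe, 0.5-20 pmol protein, plateau PIFE 0.8, three wells per
concentration), quantify it, and fit the isotherm:

```r
library(mwpife)

plate <- simulate_preset("ku_titration", seed = 7)
quantify_pife(plate)
#>   replicate_group      pife         sd n wash_pife wash_sd control_group
#> 1      ku_0.5pmol 0.1358727 0.07969140 3        NA      NA        buffer
#> 2        ku_1pmol 0.2375860 0.02860888 3        NA      NA        buffer
#> 3        ku_2pmol 0.3563400 0.08320871 3        NA      NA        buffer
#> 4        ku_4pmol 0.4211394 0.08750177 3        NA      NA        buffer
#> 5        ku_8pmol 0.5767970 0.02999972 3        NA      NA        buffer
#> 6       ku_16pmol 0.8219096 0.12559674 3        NA      NA        buffer
#> 7       ku_20pmol 0.6820653 0.07853324 3        NA      NA        buffer

wells <- pife_by_well(plate)
lay <- plate$layout[plate$layout$role == "sample", ]
wells <- merge(wells, lay[, c("well_id", "protein_pmol", "volume_ul")],
               by = "well_id")
curve <- titration_curve(P = pmol_to_nM(wells$protein_pmol, wells$volume_ul),
                         y = wells$pife, D = pmol_to_nM(2.5, 100))
fit_binding(curve, n_boot = 500, seed = 1)
#> binding fit: Kd = 16.9 nM, A = 0.807, baseline = 0 (RSS 0.175)
#>   bootstrap 95% CI: Kd [3.26, 34.4], A [0.652, 1.01] (500 resamples)
```

The per-group `pife` column is the control-corrected fractional enhancement
(0.58 means a 58 % signal increase beyond the buffer control): it rises
with protein amount and plateaus near the configured 0.8. The fitted Kd of
16.9 nM against a generative truth of 10 nM — with a CI spanning 3-34 nM —
is the honest resolution of a tight binder (Kd < probe concentration) from
three wells per point; the interval covers the truth.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on simulated plates
and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_plates.R` | one plate per scenario preset (+ truth sidecars) |
| `02_quantify_pife.R` | PIFE per replicate group; distance / footprint / translocation patterns |
| `03_fit_titration.R` | quadratic-isotherm Kd fit with bootstrap CI |
| `04_competition.R` | competitor affinities, IC50s, suppression ranking |
| `05_wash_phase.R` | wash-phase statistics: dissociation vs cleavage |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_plates.R`.

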