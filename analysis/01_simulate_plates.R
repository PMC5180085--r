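#!/usr/bin/env Rscript
# Simulate one plate per scenario preset and write layout/scans/truth files
# under results/plates/<preset>/. These plates are the inputs for every
# downstream analysis step.

suppressPackageStartupMessages(library(mwpife))

seed0 <- 20160
out_root <- file.path("results", "plates")

for (i in seq_along(preset_names())) {
  nm <- preset_names()[i]
  dir <- file.path(out_root, nm)
  plate <- simulate_preset(nm, seed = seed0 + i, dir = dir)
  cat(sprintf("%-22s %3d wells, %d scans -> %s\n", nm, nrow(plate$layout),
              length(unique(plate$scans$scan_index)), dir))
}
cat("done: plates written with per-plate truth.json sidecars\n")
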