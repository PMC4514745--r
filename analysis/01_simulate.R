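#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Generates the synthetic two-slice landscape (static terrain + dynamic
# climate-like gradients with a known 15-km northward drift) and the
# presence-only occurrence records for the four synthetic species, and
# writes everything under results/run/ for the downstream stages.

library(sdmshift)

out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_config(seed = 1)
scen <- do.call(synthetic_scenario, c(cfg$scenario, list(seed = cfg$seed)))
landscape <- make_landscape(scen)
species <- default_species(landscape)
occ <- simulate_occurrences(landscape, species,
                            n_per_species = cfg$n_per_species,
                            seed = cfg$seed + 11L)

write_stack(landscape$t0, out)
write_stack(landscape$t1, out)
write_occurrences(occ, file.path(out, "occurrences.csv"))
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

message(sprintf("landscape: %d layers x 2 slices on a %g x %g km grid",
                length(landscape$t0$layers), scen$extent_km[1],
                scen$extent_km[2]))
message(sprintf("occurrences: %d records for %d species (drift = %g km north)",
                nrow(occ), length(species), scen$drift_km))
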