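#!/usr/bin/env Rscript
# Stage 3 — lattice projection and RIO surfaces.
#
# Applies each fitted model to the regular 5-km lattice for both time
# slices and smooths the predictions to continuous 1-km relative-index-of-
# occurrence (RIO) surfaces with inverse-distance weighting.

library(sdmshift)

out <- "results/run"
cfg <- read_config(file.path(out, "config.yaml"))
p <- cfg$params
stack_t0 <- read_stack(out, "t0_")
stack_t1 <- read_stack(out, "t1_")
models <- readRDS(file.path(out, "models.rds"))

mask <- make_mask(cfg$scenario$extent_km, res = cfg$scenario$resolution_km)
lattice <- build_lattice(mask, p$lattice_km)
lattice <- attach_timeslice(lattice, stack_t0, stack_t1)
message(sprintf("lattice: %d points at %g km spacing",
                nrow(lattice$points), p$lattice_km))

for (sp in names(models)) {
  for (slice in c("t0", "t1")) {
    vals <- predict_rio(models[[sp]], lattice, slice)
    surf <- smooth_idw(lattice$points, vals, mask,
                       resolution_km = p$idw$resolution_km,
                       power = p$idw$power, n_neighbors = p$idw$neighbors)
    write_asc(surf, file.path(out, sprintf("rio_%s_%s.asc", sp, slice)))
  }
  message(sprintf("%s: RIO surfaces written for both slices", sp))
}
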