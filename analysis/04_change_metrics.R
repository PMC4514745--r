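#!/usr/bin/env Rscript
# Stage 4 — binary ranges, change partitions and shift metrics.
#
# Thresholds every RIO surface at 0.5, partitions each species' change
# into loss / gain / persistence / absent, and computes the per-species
# shift metrics (areas, percent change, median latitude / elevation /
# coast-distance shifts and their per-decade rates over 9 decades).

library(sdmshift)

out <- "results/run"
cfg <- read_config(file.path(out, "config.yaml"))
p <- cfg$params
stack_t0 <- read_stack(out, "t0_")
elev <- grid_at_resolution(stack_t0$layers[[p$elevation_layer]],
                           p$idw$resolution_km)
coast <- grid_at_resolution(stack_t0$layers[[p$coast_layer]],
                            p$idw$resolution_km)

species <- sub("^rio_(.*)_t0\\.asc$", "\\1",
               list.files(out, pattern = "^rio_.*_t0\\.asc$"))
metrics <- list()
for (sp in species) {
  b0 <- binarize(rio_surface(read_asc(file.path(out,
                                                sprintf("rio_%s_t0.asc", sp))),
                             sp, "t0"), p$threshold)
  b1 <- binarize(rio_surface(read_asc(file.path(out,
                                                sprintf("rio_%s_t1.asc", sp))),
                             sp, "t1"), p$threshold)
  cm <- change_partition(b0, b1)
  write_asc(cm$grid, file.path(out, sprintf("change_%s.asc", sp)))
  metrics[[sp]] <- shift_metrics(b0, b1, elev, coast, decades = p$decades)
  message(sprintf("%s: area %g -> %g km2, median latitude shift %+g km",
                  sp, metrics[[sp]]$area_t0_km2, metrics[[sp]]$area_t1_km2,
                  metrics[[sp]]$d_latitude_km))
}
write_change_metrics(do.call(rbind, metrics),
                     file.path(out, "shift_metrics.csv"))
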