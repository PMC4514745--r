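#!/usr/bin/env Rscript
# Stage 5 — stacked richness and mean-RIO composites.
#
# Sums the binary ranges into per-slice richness maps, builds the
# delta-richness and delta-mean-RIO composites with their histograms, and
# ranks the environmental drivers of delta-richness with a tree-ensemble
# regression at the lattice scale.

library(sdmshift)

out <- "results/run"
cfg <- read_config(file.path(out, "config.yaml"))
p <- cfg$params
stack_t0 <- read_stack(out, "t0_")
stack_t1 <- read_stack(out, "t1_")

species <- sub("^rio_(.*)_t0\\.asc$", "\\1",
               list.files(out, pattern = "^rio_.*_t0\\.asc$"))
load_slice <- function(slice) {
  rios <- lapply(species, function(sp)
    rio_surface(read_asc(file.path(out, sprintf("rio_%s_%s.asc", sp, slice))),
                sp, slice))
  list(rios = rios,
       bins = lapply(rios, binarize, threshold = p$threshold))
}
s0 <- load_slice("t0"); s1 <- load_slice("t1")

comp <- delta_maps(s0$bins, s1$bins, s0$rios, s1$rios)
for (nm in c("delta_bio", "delta_rio", "mean_rio_t0", "mean_rio_t1"))
  write_asc(comp[[nm]], file.path(out, paste0(nm, ".asc")))
write_asc(comp$richness_t0$grid, file.path(out, "richness_t0.asc"))
write_asc(comp$richness_t1$grid, file.path(out, "richness_t1.asc"))

hists <- rbind(cbind(map = "richness_t0", richness_histogram(comp$richness_t0)),
               cbind(map = "richness_t1", richness_histogram(comp$richness_t1)),
               cbind(map = "delta_bio", richness_histogram(comp$delta_bio)))
write.csv(hists, file.path(out, "richness_histograms.csv"), row.names = FALSE)

message(sprintf("richness range t0: %d-%d, t1: %d-%d; delta-bio range %d..%d",
                min(comp$richness_t0$grid$values),
                max(comp$richness_t0$grid$values),
                min(comp$richness_t1$grid$values),
                max(comp$richness_t1$grid$values),
                min(comp$delta_bio$values), max(comp$delta_bio$values)))
message(sprintf("area with >= %d species at t1: %g km2", length(species),
                hotspot_area(comp$richness_t1, length(species))))

mask <- make_mask(cfg$scenario$extent_km, res = cfg$scenario$resolution_km)
lattice <- attach_timeslice(build_lattice(mask, p$lattice_km),
                            stack_t0, stack_t1)
drivers <- suppressWarnings(
  rank_composite_drivers(comp$delta_bio, lattice, seed = cfg$seed + 41L))
write.csv(drivers, file.path(out, "composite_drivers.csv"), row.names = FALSE)
message("top delta-richness driver: ", drivers$layer[1])
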