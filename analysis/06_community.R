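#!/usr/bin/env Rscript
# Stage 6 — community assemblage structure.
#
# Samples random points across the study area, correlates the species'
# RIO surfaces at those points, classifies pairs at the +/-0.25
# thresholds, clusters species into assemblages for both slices, and
# reports species whose assemblage membership changes between slices.

library(sdmshift)

out <- "results/run"
cfg <- read_config(file.path(out, "config.yaml"))
p <- cfg$params

species <- sub("^rio_(.*)_t0\\.asc$", "\\1",
               list.files(out, pattern = "^rio_.*_t0\\.asc$"))
mask <- make_mask(cfg$scenario$extent_km, res = cfg$scenario$resolution_km)
pts <- sample_points(mask, n = min(p$corr$n_points,
                                   sum(!is.na(mask$values)) * 10),
                     seed = cfg$seed + 37L)

assignments <- list()
for (slice in c("t0", "t1")) {
  rios <- lapply(species, function(sp)
    rio_surface(read_asc(file.path(out, sprintf("rio_%s_%s.asc", sp, slice))),
                sp, slice))
  corr <- correlation_matrix(pts, rios)
  write_correlation(corr, file.path(out, sprintf("correlation_%s.csv", slice)))
  pairs <- classify_pairs(corr, pos = p$corr$pos, neg = p$corr$neg)
  write.csv(pairs, file.path(out, sprintf("pair_classes_%s.csv", slice)),
            row.names = FALSE)
  asg <- cluster_species(corr, n_groups = p$n_groups, time_slice = slice)
  assignments[[slice]] <- asg
  write_newick(asg, file.path(out, sprintf("community_%s.nwk", slice)))
  write_assignment(asg, file.path(out, sprintf("community_%s.csv", slice)))
  message(sprintf("%s: %d co-occurring / %d exclusive / %d neutral pairs",
                  slice, sum(pairs$class == "co_occurring"),
                  sum(pairs$class == "exclusive"),
                  sum(pairs$class == "neutral")))
}

moved <- compare_memberships(assignments$t0, assignments$t1)
if (nrow(moved) == 0) {
  message("no species changed assemblage membership between slices")
} else {
  message("membership changes:")
  print(moved)
}
write.csv(moved, file.path(out, "membership_changes.csv"), row.names = FALSE)
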