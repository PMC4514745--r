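#!/usr/bin/env Rscript
# Stage 2 — occurrence filtering and envelope-model fitting.
#
# Reads the stage-1 artifacts, thins the records (one per species within
# 1 km), builds target-group pseudo-absences, fits one 500-tree ensemble
# per species and evaluates each out of bag. Writes the thinned records,
# the evaluation table, the importance rankings, and the fitted models.

library(sdmshift)

out <- "results/run"
cfg <- read_config(file.path(out, "config.yaml"))
p <- cfg$params
stack_t0 <- read_stack(out, "t0_")
occ <- read_occurrences(file.path(out, "occurrences.csv"), mode = "planar")

occ <- filter_precision(occ, p$precision_decimals)
thinned <- spatial_thin(occ, p$thin_radius_km)
write_occurrences(thinned, file.path(out, "occurrences_thinned.csv"))
message(sprintf("thinning: %d -> %d records", nrow(occ), nrow(thinned)))

models <- list(); evaluations <- list(); importance <- list()
for (sp in unique(thinned$species_id)) {
  pres <- thinned[thinned$species_id == sp, ]
  pa <- build_pseudo_absences(thinned, sp, p$pa_radius_km)
  train <- assemble_training(sp, pres, pa, stack_t0)
  models[[sp]] <- fit_envelope(train, n_trees = p$n_trees,
                               seed = cfg$seed + 23L + length(models))
  evaluations[[sp]] <- evaluate_oob(models[[sp]], train, p$threshold)
  importance[[sp]] <- cbind(species_id = sp,
                            rank_importance(models[[sp]]))
  message(sprintf("%s: %d presences / %d pseudo-absences, OOB AUC %.3f",
                  sp, train$n_presence, train$n_absence,
                  evaluations[[sp]]$auc))
}

write_evaluation_table(evaluations, file.path(out, "model_evaluation.csv"))
write.csv(do.call(rbind, importance),
          file.path(out, "variable_importance.csv"), row.names = FALSE)
saveRDS(models, file.path(out, "models.rds"))
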