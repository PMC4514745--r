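#!/usr/bin/env Rscript
# Stage 7 — aggregate the published per-species change table.
#
# Feeds the published range-change metrics for the 17 Alaskan small
# mammals through the same community-aggregation routines used for the
# synthetic pipeline, reproducing the per-community means and the
# cross-community summary statistics, and converting shifts to
# per-decade rates over the 9 decades between the modelled periods.

library(sdmshift)

dir.create("results", showWarnings = FALSE)
pub <- published_change_metrics()
cols <- c("area_t0_km2", "area_t1_km2", "net_change_km2", "pct_change",
          "d_latitude_km", "d_coast_km", "d_elevation_m")
agg <- community_aggregate(pub, cols = cols,
                           unions = list(
                             declining = c("cold-climate", "interior",
                                           "northern"),
                             expanding = c("continental", "southern")))
write.csv(agg$groups, "results/community_means.csv", row.names = FALSE)
write.csv(agg$unions, "results/community_union_means.csv", row.names = FALSE)

message("per-community means:")
print(agg$groups[, c("community", "n", "pct_change", "d_latitude_km",
                     "d_coast_km", "d_elevation_m")], digits = 3)
message("declining (cold-climate + interior + northern) communities: ",
        sprintf("%.1f%% mean area change, %+.0f km mean latitude shift",
                agg$unions$pct_change[1], agg$unions$d_latitude_km[1]))
message("expanding (continental + southern) communities: ",
        sprintf("%.1f%% mean area change", agg$unions$pct_change[2]))

rates <- add_decadal_rates(pub, decades = 9)
write.csv(rates, "results/published_with_rates.csv", row.names = FALSE)
lemming <- rates[rates$species_id == "Dicrostonyx groenlandicus", ]
message(sprintf("collared lemming: %+g km latitude shift = %.1f km/decade",
                lemming$d_latitude_km, lemming$rate_latitude_km_decade))
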