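#' Threshold a RIO surface into a binary range map
#'
#' Cells with RIO >= `threshold` are classified presence (1), cells below
#' are absence (0); no-data cells stay no-data.
#'
#' @param rio a [rio_surface] (or bare [sdm_grid]) of RIO values.
#' @param threshold symmetric decision threshold, default 0.5.
#' @return object of class `binary_range`: fields `grid` (0/1/NA),
#'   `species_id`, `time_slice`, `pixel_area_km2`.
#' @export
binarize <- function(rio, threshold = 0.5) {
  g <- as_grid(rio)
  m <- ifelse(g$values >= threshold, 1, 0)
  structure(list(grid = sdm_grid(m, g$xmin, g$ymin, g$res),
                 species_id = if (is.null(rio$species_id)) "" else rio$species_id,
                 time_slice = if (is.null(rio$time_slice)) "" else rio$time_slice,
                 pixel_area_km2 = g$res^2),
            class = "binary_range")
}

#' Partition change between two binary ranges
#'
#' Cellwise categories: loss (1 to 0), gain (0 to 1), persistence (1 to 1),
#' absent (0 to 0); no-data preserved. Categories partition the unmasked
#' study area.
#'
#' @param b_t0,b_t1 aligned [binarize] ranges of one species.
#' @return object of class `change_map`: `grid` holds integer codes with a
#'   `legend` field (0 absent, 1 loss, 2 gain, 3 persistence).
#' @export
change_partition <- function(b_t0, b_t1) {
  stop_if_misaligned(b_t0$grid, b_t1$grid, "binary ranges")
  a <- b_t0$grid$values
  b <- b_t1$grid$values
  m <- matrix(NA_real_, nrow(a), ncol(a))
  m[which(a == 0 & b == 0)] <- 0
  m[which(a == 1 & b == 0)] <- 1
  m[which(a == 0 & b == 1)] <- 2
  m[which(a == 1 & b == 1)] <- 3
  structure(list(grid = sdm_grid(m, b_t0$grid$xmin, b_t0$grid$ymin,
                                 b_t0$grid$res),
                 species_id = b_t0$species_id,
                 legend = c(absent = 0, loss = 1, gain = 2, persistence = 3),
                 pixel_area_km2 = b_t0$pixel_area_km2),
            class = "change_map")
}

#' Count change-map categories
#'
#' @param cm a [change_partition] map.
#' @return named vector of cell counts per category.
#' @export
change_counts <- function(cm) {
  v <- cm$grid$values
  vapply(cm$legend, function(code) sum(v == code, na.rm = TRUE), numeric(1))
}

grid_northing <- function(grid, idx) {
  ij <- arrayInd(idx, dim(grid$values))
  grid$ymin + (ij[, 1] - 0.5) * grid$res
}

#' Range-shift metrics between two time slices
#'
#' Areas (km^2), loss/gain/persistence areas, net change, the two percent-
#' change formulations (net change over the first-slice area, and turnover
#' — changed pixels over the second-slice area), and shifts in the median
#' latitude (pixel-centre northing, km), median elevation (m) and median
#' coast distance (km) of presence pixels. Deltas are second slice minus
#' first, so negative latitude/coast/elevation deltas mean southerly,
#' coastward and downslope movement. Decadal rates divide each delta by
#' `decades` (9 for a 2010-to-2100 projection). An empty presence set in
#' either slice leaves the affected metrics undefined (NA), never zero.
#'
#' @param b_t0,b_t1 aligned [binarize] ranges of one species.
#' @param elevation,coast_distance aligned [sdm_grid]s of terrain (m) and
#'   distance to coast (km).
#' @param decades number of decades separating the slices.
#' @param community optional community label carried into the output.
#' @return one-row data.frame (class `shift_metrics`).
#' @export
shift_metrics <- function(b_t0, b_t1, elevation, coast_distance,
                          decades = 9, community = NA_character_) {
  g0 <- b_t0$grid; g1 <- b_t1$grid
  stop_if_misaligned(g0, g1, "binary ranges")
  stop_if_misaligned(g0, as_grid(elevation), "range and elevation grids")
  stop_if_misaligned(g0, as_grid(coast_distance), "range and coast grids")
  px <- b_t0$pixel_area_km2
  p0 <- which(g0$values == 1)
  p1 <- which(g1$values == 1)
  n_loss <- sum(g0$values == 1 & g1$values == 0, na.rm = TRUE)
  n_gain <- sum(g0$values == 0 & g1$values == 1, na.rm = TRUE)
  n_pers <- sum(g0$values == 1 & g1$values == 1, na.rm = TRUE)
  area0 <- length(p0) * px
  area1 <- length(p1) * px
  defined <- length(p0) > 0 && length(p1) > 0
  med <- function(idx, grid) if (length(idx)) stats::median(grid$values[idx]) else NA_real_
  elev <- as_grid(elevation); coast <- as_grid(coast_distance)
  d_lat <- if (defined)
    stats::median(grid_northing(g1, p1)) - stats::median(grid_northing(g0, p0))
  else NA_real_
  d_elev <- if (defined) med(p1, elev) - med(p0, elev) else NA_real_
  d_coast <- if (defined) med(p1, coast) - med(p0, coast) else NA_real_
  if (!defined)
    warning(sprintf("shift_metrics('%s'): empty presence set; shift metrics undefined",
                    b_t0$species_id))
  out <- data.frame(
    species_id = b_t0$species_id, community = community,
    area_t0_km2 = area0, area_t1_km2 = area1,
    loss_km2 = n_loss * px, gain_km2 = n_gain * px,
    persistence_km2 = n_pers * px,
    net_change_km2 = area1 - area0,
    pct_change_net = if (area0 > 0) 100 * (area1 - area0) / area0 else NA_real_,
    pct_change_turnover = if (area1 > 0) 100 * (n_loss + n_gain) * px / area1 else NA_real_,
    d_latitude_km = d_lat, d_coast_km = d_coast, d_elevation_m = d_elev,
    decades = decades,
    stringsAsFactors = FALSE)
  out <- add_decadal_rates(out, decades)
  class(out) <- c("shift_metrics", class(out))
  out
}

#' Add per-decade rate columns to a shift-metrics table
#'
#' Rates are the deltas divided by the number of decades between slices
#' (exactly; e.g. a -25 km latitude delta over 9 decades is -2.8 km/decade).
#'
#' @param metrics data.frame with `d_latitude_km`, `d_coast_km`,
#'   `d_elevation_m` columns.
#' @param decades number of decades separating the slices.
#' @return the table with `rate_latitude_km_decade`, `rate_coast_km_decade`
#'   and `rate_elevation_m_decade` columns.
#' @export
add_decadal_rates <- function(metrics, decades = 9) {
  metrics$rate_latitude_km_decade <- metrics$d_latitude_km / decades
  metrics$rate_coast_km_decade <- metrics$d_coast_km / decades
  metrics$rate_elevation_m_decade <- metrics$d_elevation_m / decades
  metrics
}

#' Aggregate shift metrics by community
#'
#' Unweighted arithmetic means of each numeric metric per community, plus
#' means over any named unions of communities. A species without a
#' community assignment is an error. `exclude` drops named species before
#' averaging (useful for sensitivity checks on a single outlier species).
#'
#' @param metrics data.frame with `species_id`, `community` and numeric
#'   metric columns (one row per species), e.g. rbind-ed [shift_metrics]
#'   rows or a published metrics table.
#' @param cols metric columns to average; default all numeric columns.
#' @param unions named list of character vectors of community labels; each
#'   entry yields a mean over all member species of those communities.
#' @param exclude species_ids to drop before averaging.
#' @return list with `groups` (per-community means, column `n` = species
#'   count) and `unions` (one row per requested union).
#' @export
community_aggregate <- function(metrics, cols = NULL, unions = list(),
                                exclude = NULL) {
  if (any(is.na(metrics$community) | metrics$community == ""))
    stop(sprintf("species without community assignment: %s",
                 paste(metrics$species_id[is.na(metrics$community) |
                                            metrics$community == ""],
                       collapse = ", ")))
  if (!is.null(exclude))
    metrics <- metrics[!(metrics$species_id %in% exclude), , drop = FALSE]
  if (is.null(cols))
    cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  mean_rows <- function(df) {
    m <- vapply(cols, function(cc) mean(df[[cc]]), numeric(1))
    c(list(n = nrow(df)), as.list(m))
  }
  groups <- do.call(rbind, lapply(split(metrics, metrics$community),
                                  function(df)
                                    as.data.frame(mean_rows(df))))
  groups <- cbind(community = rownames(groups), groups)
  rownames(groups) <- NULL
  union_df <- NULL
  if (length(unions)) {
    union_df <- do.call(rbind, lapply(names(unions), function(u) {
      df <- metrics[metrics$community %in% unions[[u]], , drop = FALSE]
      cbind(union = u, as.data.frame(mean_rows(df)))
    }))
  }
  list(groups = groups, unions = union_df)
}

#' Published range-change metrics for 17 Alaskan small mammals
#'
#' Per-species presence areas for the two modelled periods, net and percent
#' area change, median latitude / coast-distance / elevation shifts, and
#' community membership, as printed in the published statewide analysis
#' this pipeline re-implements. These values are carried as data (the
#' printed percent-change column is not derivable from the printed areas)
#' and serve as the arithmetic fixture for [community_aggregate] and
#' [add_decadal_rates].
#'
#' @return data.frame, one row per species.
#' @export
published_change_metrics <- function() {
  path <- system.file("extdata", "ak_small_mammal_change_metrics.csv",
                      package = "sdmshift", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-species change-metrics table
#'
#' @param metrics data.frame (rbind-ed [shift_metrics] rows).
#' @param path output CSV.
#' @export
write_change_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
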