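#' Stack binary ranges into a species-richness map
#'
#' Cellwise sum of presence indicators over all species of one time slice.
#'
#' @param binaries list of aligned [binarize] ranges, one per species.
#' @param time_slice label carried into the output.
#' @return object of class `richness_map`: fields `grid` (integer counts),
#'   `n_species`, `time_slice`, `pixel_area_km2`.
#' @export
stack_richness <- function(binaries, time_slice = "t0") {
  sp <- vapply(binaries, function(b) b$species_id, character(1))
  if (anyDuplicated(sp))
    stop(sprintf("duplicate species in richness stack: %s",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  g1 <- binaries[[1]]$grid
  acc <- matrix(0, g1$ny, g1$nx)
  for (b in binaries) {
    stop_if_misaligned(g1, b$grid, "binary ranges")
    acc <- acc + b$grid$values
  }
  structure(list(grid = sdm_grid(acc, g1$xmin, g1$ymin, g1$res),
                 n_species = length(binaries), time_slice = time_slice,
                 pixel_area_km2 = g1$res^2),
            class = "richness_map")
}

#' Composite change maps: delta-richness and delta-mean-RIO
#'
#' Builds the two-slice richness maps and their difference (second minus
#' first slice), and the cellwise unweighted mean RIO across species per
#' slice with its difference.
#'
#' @param binaries_t0,binaries_t1 lists of aligned [binarize] ranges, same
#'   species set in both slices.
#' @param rios_t0,rios_t1 lists of aligned [rio_surface]s, same species set.
#' @return list with `richness_t0`, `richness_t1` ([stack_richness] maps),
#'   `delta_bio` (integer [sdm_grid]), `mean_rio_t0`, `mean_rio_t1`,
#'   `delta_rio` ([sdm_grid]s).
#' @export
delta_maps <- function(binaries_t0, binaries_t1, rios_t0, rios_t1) {
  sp0 <- sort(vapply(binaries_t0, function(b) b$species_id, character(1)))
  sp1 <- sort(vapply(binaries_t1, function(b) b$species_id, character(1)))
  rsp0 <- sort(vapply(rios_t0, function(r) r$species_id, character(1)))
  rsp1 <- sort(vapply(rios_t1, function(r) r$species_id, character(1)))
  if (!identical(sp0, sp1) || !identical(rsp0, rsp1) || !identical(sp0, rsp0))
    stop("species sets differ between time slices or between ranges and RIO surfaces")
  rich0 <- stack_richness(binaries_t0, "t0")
  rich1 <- stack_richness(binaries_t1, "t1")
  g <- rich0$grid
  mean_grid <- function(rios) {
    acc <- matrix(0, g$ny, g$nx)
    for (r in rios) acc <- acc + as_grid(r)$values
    sdm_grid(acc / length(rios), g$xmin, g$ymin, g$res)
  }
  m0 <- mean_grid(rios_t0)
  m1 <- mean_grid(rios_t1)
  list(richness_t0 = rich0, richness_t1 = rich1,
       delta_bio = sdm_grid(rich1$grid$values - rich0$grid$values,
                            g$xmin, g$ymin, g$res),
       mean_rio_t0 = m0, mean_rio_t1 = m1,
       delta_rio = sdm_grid(m1$values - m0$values, g$xmin, g$ymin, g$res))
}

#' Histogram of a richness (or delta-richness) map
#'
#' Exhaustive count of cells per integer value; bin totals conserve the
#' unmasked cell count.
#'
#' @param map a `richness_map`, or an [sdm_grid] of integer values.
#' @param pixel_area_km2 cell area; taken from the map when available.
#' @return data.frame with columns `value`, `n_cells`, `area_km2`.
#' @export
richness_histogram <- function(map, pixel_area_km2 = NULL) {
  g <- as_grid(map)
  if (is.null(pixel_area_km2))
    pixel_area_km2 <- if (!is.null(map$pixel_area_km2)) map$pixel_area_km2
                      else g$res^2
  v <- g$values[!is.na(g$values)]
  tab <- table(v)
  data.frame(value = as.numeric(names(tab)),
             n_cells = as.integer(tab),
             area_km2 = as.integer(tab) * pixel_area_km2)
}

#' Area with species richness at or above a threshold
#'
#' @param richness a `richness_map`.
#' @param k minimum species count (>= 0).
#' @return area in km^2 of unmasked cells with value >= k.
#' @export
hotspot_area <- function(richness, k) {
  stopifnot(k >= 0)
  sum(richness$grid$values >= k, na.rm = TRUE) * richness$pixel_area_km2
}

#' Rank environmental drivers of a composite map
#'
#' Fits a tree-ensemble regression (random forest) of the composite values
#' at the lattice points on the lattice covariates, and ranks layers by
#' permutation importance on the out-of-bag points, descending (ties broken
#' by layer name). Composite analyses run at the lattice scale; maps are
#' rendered at the fine raster scale.
#'
#' @param composite an [sdm_grid] (e.g. delta-richness or delta-mean-RIO),
#'   sampled at the lattice points.
#' @param lattice a lattice with covariates attached.
#' @param time_slice which covariate slice to regress on (default `"t1"`,
#'   the projected conditions).
#' @param n_trees ensemble size.
#' @param seed integer seed.
#' @return data.frame with columns `layer`, `importance`, ordered.
#' @export
rank_composite_drivers <- function(composite, lattice, time_slice = "t1",
                                   n_trees = 500, seed = 1) {
  if (is.null(lattice$cov))
    stop("lattice has no covariates; call attach_timeslice() first")
  y <- grid_extract(as_grid(composite), lattice$points$x, lattice$points$y)
  x <- lattice$cov[[time_slice]]
  ok <- !is.na(y) & stats::complete.cases(x)
  y <- y[ok]; x <- x[ok, , drop = FALSE]
  if (length(unique(y)) < 2)
    stop("composite is constant at the lattice points: nothing to explain")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp))
  data.frame(layer = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
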