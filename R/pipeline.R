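#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one place: filter radii (km),
#' ensemble size, decision threshold, lattice spacing (km), IDW settings,
#' decades between slices, correlation sampling and thresholds, and the
#' number of community groups. The scenario block defines the synthetic
#' study conditions; `species = "default"` uses [default_species].
#'
#' @param seed top-level integer seed; every stage derives its own seed
#'   from it, so stages are individually reproducible.
#' @return nested list (class `run_config`).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    scenario = list(extent_km = c(160, 160), resolution_km = 1,
                    n_static = 2, n_dynamic = 2,
                    drift_km = 15, drift_delta = 0),
    species = "default",
    n_per_species = 400,
    params = list(
      precision_decimals = 5, thin_radius_km = 1, pa_radius_km = 1,
      n_trees = 500, threshold = 0.5, lattice_km = 5,
      idw = list(power = 2, neighbors = 12, resolution_km = 1),
      decades = 9,
      corr = list(n_points = 50000, pos = 0.25, neg = -0.25),
      n_groups = 2,
      elevation_layer = "elevation", coast_layer = "coast_distance")),
    class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of [default_config];
#' everything else keeps its default.
#'
#' @param path YAML or JSON config file.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  merge_lists <- function(base, override) {
    for (nm in names(override)) {
      if (is.list(base[[nm]]) && is.list(override[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
      else base[[nm]] <- override[[nm]]
    }
    base
  }
  cfg <- merge_lists(unclass(default_config()), raw)
  if (cfg$params$threshold <= 0 || cfg$params$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  for (f in c("thin_radius_km", "pa_radius_km", "lattice_km", "n_trees"))
    if (cfg$params[[f]] <= 0) stop(sprintf("%s must be positive", f))
  structure(cfg, class = "run_config")
}

config_species <- function(config, landscape) {
  if (identical(config$species, "default")) return(default_species(landscape))
  sp <- lapply(config$species, function(s)
    species_envelope(s$species_id, optimum = unlist(s$optimum),
                     breadth = unlist(s$breadth),
                     max_prob = if (is.null(s$max_prob)) 0.9 else s$max_prob))
  names(sp) <- vapply(sp, function(s) s$species_id, character(1))
  sp
}

#' Validate a pair of time-slice stacks against a mask
#'
#' Report-only consistency checks: grid alignment between slices and with
#' the mask, identical layer names and flags, bit-identical static layers,
#' matching categorical registries, and consistent no-data footprints
#' within the mask.
#'
#' @param stack_t0,stack_t1 [covariate_stack]s.
#' @param mask study-area [sdm_grid].
#' @return data.frame of violations (`component`, `message`); zero rows
#'   when the stacks are consistent.
#' @export
validate_stack <- function(stack_t0, stack_t1, mask) {
  bad <- list()
  note <- function(component, message)
    bad[[length(bad) + 1]] <<- data.frame(component = component,
                                          message = message)
  if (!grids_aligned(stack_geom(stack_t0), stack_geom(stack_t1)))
    note("alignment", "time-slice stacks are not grid-aligned")
  if (!grids_aligned(stack_geom(stack_t0), mask))
    note("alignment", "stack and mask are not grid-aligned")
  if (!identical(stack_names(stack_t0), stack_names(stack_t1))) {
    note("layers", "layer names differ between slices")
  } else {
    for (nm in stack_names(stack_t0)) {
      if (stack_t0$temporal[[nm]] != stack_t1$temporal[[nm]])
        note("flags", sprintf("layer '%s' static/dynamic flag differs", nm))
      if (stack_t0$type[[nm]] != stack_t1$type[[nm]])
        note("flags", sprintf("layer '%s' type flag differs", nm))
      if (stack_t0$temporal[[nm]] == "static" &&
          !identical(stack_t0$layers[[nm]]$values,
                     stack_t1$layers[[nm]]$values))
        note("static", sprintf("static layer '%s' differs between slices", nm))
      if (stack_t0$type[[nm]] == "categorical" &&
          !identical(stack_t0$levels[[nm]], stack_t1$levels[[nm]]))
        note("registry", sprintf("categorical registry for '%s' differs", nm))
      if (grids_aligned(stack_geom(stack_t0), mask)) {
        in_mask <- !is.na(mask$values)
        if (anyNA(stack_t0$layers[[nm]]$values[in_mask]) ||
            anyNA(stack_t1$layers[[nm]]$values[in_mask]))
          note("nodata", sprintf("layer '%s' has no-data inside the mask", nm))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(component = character(0), message = character(0))
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, fit = 23L, community = 37L, drivers = 41L)
  config$seed + unname(offsets[stage])
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes simulate, thin, pseudo-absence construction, per-species model
#' fit and out-of-bag evaluation, two-slice lattice projection, IDW
#' smoothing, binarization, change partition and shift metrics, richness
#' and mean-RIO composites with driver ranking, and community clustering
#' with cross-slice membership comparison. Every intermediate artifact is
#' written under `out_dir`; a manifest records versions, the seed, all
#' parameters, and an MD5 checksum for every file written. Any stage error
#' aborts with the stage and species context.
#'
#' @param config a `run_config` (list or YAML/JSON path).
#' @param out_dir output directory (created).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the main in-memory results: `evaluations`,
#'   `metrics` (shift-metrics table), `composites`, `assignments`,
#'   `membership_changes`, `importance`, `manifest_path`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  keep <- function(f) { files <<- c(files, f); f }
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- config$params

  # -- simulate -------------------------------------------------------------
  say("stage simulate: generating landscape and occurrences")
  scen <- do.call(synthetic_scenario,
                  c(config$scenario, list(seed = config$seed)))
  landscape <- make_landscape(scen)
  mask <- make_mask(scen$extent_km, res = scen$resolution_km)
  species <- config_species(config, landscape)
  occ <- simulate_occurrences(landscape, species,
                              n_per_species = config$n_per_species,
                              seed = stage_seed(config, "simulate"))
  keep(write_stack(landscape$t0, out_dir))
  keep(write_stack(landscape$t1, out_dir))
  keep(write_occurrences(occ, file.path(out_dir, "occurrences.csv")))

  report <- validate_stack(landscape$t0, landscape$t1, mask)
  if (nrow(report)) stop("stage simulate: inconsistent stacks: ",
                         paste(report$message, collapse = "; "))

  # -- thin -----------------------------------------------------------------
  say("stage thin: %d raw records", nrow(occ))
  occ <- filter_precision(occ, p$precision_decimals)
  thinned <- spatial_thin(occ, p$thin_radius_km)
  say("stage thin: %d records after thinning", nrow(thinned))
  keep(write_occurrences(thinned,
                         file.path(out_dir, "occurrences_thinned.csv")))

  # -- fit ------------------------------------------------------------------
  lattice <- build_lattice(mask, p$lattice_km)
  lattice <- attach_timeslice(lattice, landscape$t0, landscape$t1)
  models <- list(); evaluations <- list(); importance <- list()
  rios <- list(t0 = list(), t1 = list())
  binaries <- list(t0 = list(), t1 = list())
  fit_seed <- stage_seed(config, "fit")
  for (i in seq_along(species)) {
    sp <- names(species)[i]
    say("stage fit: %s", sp)
    pres <- thinned[thinned$species_id == sp, , drop = FALSE]
    pa <- build_pseudo_absences(thinned, sp, p$pa_radius_km)
    train <- assemble_training(sp, pres, pa, landscape$t0)
    model <- tryCatch(
      fit_envelope(train, n_trees = p$n_trees, seed = fit_seed + i),
      error = function(e) stop(sprintf("stage fit (%s): %s", sp,
                                       conditionMessage(e))))
    models[[sp]] <- model
    evaluations[[sp]] <- evaluate_oob(model, train, p$threshold)
    importance[[sp]] <- cbind(species_id = sp, rank_importance(model))
    for (slice in c("t0", "t1")) {
      vals <- predict_rio(model, lattice, slice)
      surf <- smooth_idw(lattice$points, vals, mask,
                         resolution_km = p$idw$resolution_km,
                         power = p$idw$power, n_neighbors = p$idw$neighbors)
      rio <- rio_surface(surf, sp, slice)
      rios[[slice]][[sp]] <- rio
      binaries[[slice]][[sp]] <- binarize(rio, p$threshold)
      keep(write_asc(surf, file.path(out_dir,
                                     sprintf("rio_%s_%s.asc", sp, slice))))
    }
  }
  keep(write_evaluation_table(evaluations,
                              file.path(out_dir, "model_evaluation.csv")))
  imp_tab <- do.call(rbind, importance)
  keep({f <- file.path(out_dir, "variable_importance.csv")
        utils::write.csv(imp_tab, f, row.names = FALSE); f})

  # -- change ---------------------------------------------------------------
  say("stage change: partitions and shift metrics")
  if (!(p$elevation_layer %in% stack_names(landscape$t0)) ||
      !(p$coast_layer %in% stack_names(landscape$t0)))
    stop("stage change: configured elevation/coast layers not in the stack")
  elev <- grid_at_resolution(landscape$t0$layers[[p$elevation_layer]],
                             p$idw$resolution_km)
  coast <- grid_at_resolution(landscape$t0$layers[[p$coast_layer]],
                              p$idw$resolution_km)
  metrics <- list()
  for (sp in names(species)) {
    cm <- change_partition(binaries$t0[[sp]], binaries$t1[[sp]])
    keep(write_asc(cm$grid, file.path(out_dir,
                                      sprintf("change_%s.asc", sp))))
    metrics[[sp]] <- shift_metrics(binaries$t0[[sp]], binaries$t1[[sp]],
                                   elev, coast, decades = p$decades)
  }
  metrics <- do.call(rbind, metrics)

  # -- biodiversity ---------------------------------------------------------
  say("stage biodiv: composites")
  comp <- delta_maps(binaries$t0, binaries$t1, rios$t0, rios$t1)
  for (nm in c("delta_bio", "mean_rio_t0", "mean_rio_t1", "delta_rio"))
    keep(write_asc(comp[[nm]], file.path(out_dir, paste0(nm, ".asc"))))
  keep(write_asc(comp$richness_t0$grid, file.path(out_dir, "richness_t0.asc")))
  keep(write_asc(comp$richness_t1$grid, file.path(out_dir, "richness_t1.asc")))
  hist_tab <- rbind(cbind(map = "richness_t0",
                          richness_histogram(comp$richness_t0)),
                    cbind(map = "richness_t1",
                          richness_histogram(comp$richness_t1)),
                    cbind(map = "delta_bio",
                          richness_histogram(comp$delta_bio)))
  keep({f <- file.path(out_dir, "richness_histograms.csv")
        utils::write.csv(hist_tab, f, row.names = FALSE); f})
  drivers <- rank_composite_drivers(comp$delta_bio, lattice,
                                    seed = stage_seed(config, "drivers"))
  keep({f <- file.path(out_dir, "composite_drivers.csv")
        utils::write.csv(drivers, f, row.names = FALSE); f})

  # -- community ------------------------------------------------------------
  say("stage community: correlation and clustering")
  pts <- sample_points(mask, n = min(p$corr$n_points,
                                     sum(!is.na(mask$values)) * 10),
                       seed = stage_seed(config, "community"))
  assignments <- list()
  for (slice in c("t0", "t1")) {
    corr <- correlation_matrix(pts, rios[[slice]])
    keep(write_correlation(corr, file.path(out_dir,
                                           sprintf("correlation_%s.csv",
                                                   slice))))
    asg <- cluster_species(corr, n_groups = p$n_groups, time_slice = slice)
    assignments[[slice]] <- asg
    keep(write_newick(asg, file.path(out_dir,
                                     sprintf("community_%s.nwk", slice))))
    keep(write_assignment(asg, file.path(out_dir,
                                         sprintf("community_%s.csv", slice))))
  }
  changes <- compare_memberships(assignments$t0, assignments$t1)
  metrics$community <- paste0("group_",
                              assignments$t0$groups[metrics$species_id])
  keep(write_change_metrics(metrics,
                            file.path(out_dir, "shift_metrics.csv")))

  # -- manifest -------------------------------------------------------------
  files <- unique(normalizePath(files))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("sdmshift")),
    learner = paste0("randomForest ",
                     utils::packageVersion("randomForest")),
    seed = config$seed, parameters = p, scenario = config$scenario,
    files = lapply(stats::setNames(as.list(files),
                                   basename(files)), function(f)
                     unname(tools::md5sum(f))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  say("pipeline complete: %d artifacts in %s", length(files), out_dir)
  invisible(list(evaluations = do.call(rbind, evaluations),
                 metrics = metrics, composites = comp,
                 assignments = assignments, membership_changes = changes,
                 importance = imp_tab, models = models, rios = rios,
                 binaries = binaries, lattice = lattice,
                 landscape = landscape,
                 manifest_path = manifest_path))
}
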