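#' Synthetic landscapes with a known covariate drift
#'
#' The generator builds a planar (equal-area, km) landscape of smooth
#' environmental layers for two time slices. Static layers are identical in
#' both slices; dynamic layers in the second slice are the first-slice field
#' translated north by `drift_km` and offset by `drift_delta`. Because each
#' field is an analytic function (latitudinal trend plus fixed low-frequency
#' sinusoidal noise) evaluated at `(x, y - drift_km)` for the future slice,
#' the imposed drift is exact at any resolution — a species whose envelope
#' tracks a dynamic layer has a known, recoverable northward displacement.
#'
#' @param extent_km c(width, height) of the landscape, km.
#' @param resolution_km raster cell size, km.
#' @param n_static,n_dynamic number of static / dynamic layers (each >= 1
#'   for the default species set to make sense).
#' @param drift_km northward displacement of dynamic-layer isolines between
#'   the two slices, km (>= 0).
#' @param drift_delta additive offset applied to dynamic layers in the
#'   second slice.
#' @param seed integer seed; the whole landscape is a pure function of the
#'   scenario fields and this seed.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(extent_km = c(160, 160), resolution_km = 1,
                               n_static = 2, n_dynamic = 2,
                               drift_km = 15, drift_delta = 0, seed = 1) {
  if (length(extent_km) != 2 || any(!is.finite(extent_km)) ||
      any(extent_km <= 0))
    stop("scenario extent must be two positive lengths (km)")
  if (!is.finite(resolution_km) || resolution_km <= 0)
    stop("scenario resolution must be positive")
  if (!is.finite(drift_km) || drift_km < 0)
    stop("drift_km must be non-negative")
  if (n_static < 0 || n_dynamic < 1)
    stop("need n_static >= 0 and n_dynamic >= 1")
  structure(list(extent_km = extent_km, resolution_km = resolution_km,
                 n_static = as.integer(n_static),
                 n_dynamic = as.integer(n_dynamic),
                 drift_km = drift_km, drift_delta = drift_delta,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Smooth scalar field: linear trend in y plus a fixed sum of low-frequency
# cosine waves. Returned as a closure so both time slices (and any probe
# coordinate) evaluate the identical analytic surface.
make_field <- function(base, slope_y, noise_amp,
                       wavelength_range = c(40, 120), n_waves = 4) {
  force(base); force(slope_y)
  amp <- noise_amp * stats::runif(n_waves, 0.5, 1) / n_waves * 2
  wl <- stats::runif(n_waves, wavelength_range[1], wavelength_range[2])
  theta <- stats::runif(n_waves, 0, 2 * pi)
  phase <- stats::runif(n_waves, 0, 2 * pi)
  kx <- cos(theta) / wl
  ky <- sin(theta) / wl
  function(x, y) {
    v <- base + slope_y * y
    for (k in seq_len(n_waves))
      v <- v + amp[k] * cos(2 * pi * (kx[k] * x + ky[k] * y) + phase[k])
    v
  }
}

eval_field_grid <- function(field, geom) {
  ctr <- grid_centers(geom)
  xm <- matrix(ctr$x, nrow = geom$ny, ncol = geom$nx, byrow = TRUE)
  ym <- matrix(ctr$y, nrow = geom$ny, ncol = geom$nx)
  sdm_grid(field(xm, ym), xmin = geom$xmin, ymin = geom$ymin, res = geom$res)
}

default_layer_names <- function(n_static, n_dynamic) {
  dyn <- c("mean_temp", "growing_days",
           if (n_dynamic > 2) paste0("dynamic_", seq_len(n_dynamic - 2) + 2))
  sta <- c("elevation", "coast_distance",
           if (n_static > 2) paste0("static_", seq_len(n_static - 2) + 2))
  list(dynamic = dyn[seq_len(n_dynamic)], static = sta[seq_len(n_static)])
}

#' Generate the two-slice covariate landscape of a scenario
#'
#' Dynamic layers follow a south-to-north gradient (e.g. a temperature-like
#' field cooling northward) so a northward isoline drift is ecologically
#' meaningful. The first two static layers are an elevation-like field (m)
#' and a coast-distance field (km, distance to the south/west edges), which
#' double as the terrain rasters used by the range-shift metrics.
#'
#' @param scenario a [synthetic_scenario].
#' @return list with elements `t0` and `t1` ([covariate_stack]s on identical
#'   grids with identical layer names) and `fields` (the analytic ground-
#'   truth functions, named by layer; dynamic fields take `(x, y)` for the
#'   first slice).
#' @export
make_landscape <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  geom <- make_mask(scenario$extent_km, res = scenario$resolution_km)
  nm <- default_layer_names(scenario$n_static, scenario$n_dynamic)
  set.seed(scenario$seed)

  fields <- list()
  # dynamic fields: decreasing northward, distinct bases/slopes per layer
  dyn_base <- c(16, 160)
  dyn_slope <- c(-0.1, -0.6)
  dyn_amp <- c(1.0, 6)
  for (i in seq_along(nm$dynamic)) {
    b <- if (i <= 2) dyn_base[i] else 10 * i
    s <- if (i <= 2) dyn_slope[i] else -0.05 * i
    a <- if (i <= 2) dyn_amp[i] else 1
    fields[[nm$dynamic[i]]] <- make_field(b, s, a)
  }
  for (i in seq_along(nm$static)) {
    lname <- nm$static[i]
    if (lname == "elevation") {
      # several oscillations across the extent, so terrain structure is
      # identifiable from (not collinear with) the latitudinal climate trend
      fields[[lname]] <- make_field(500, 0, 500,
                                    wavelength_range = c(30, 70))
    } else if (lname == "coast_distance") {
      fields[[lname]] <- function(x, y) pmin(x, y)
    } else {
      fields[[lname]] <- make_field(0, 0, 2)
    }
  }

  build_slice <- function(slice) {
    layers <- lapply(names(fields), function(lname) {
      f <- fields[[lname]]
      if (slice == "t1" && lname %in% nm$dynamic) {
        g <- eval_field_grid(function(x, y) f(x, y - scenario$drift_km),
                             geom)
        g$values <- g$values + scenario$drift_delta
        g
      } else {
        eval_field_grid(f, geom)
      }
    })
    names(layers) <- names(fields)
    temporal <- ifelse(names(fields) %in% nm$dynamic, "dynamic", "static")
    covariate_stack(layers, temporal = temporal, time_slice = slice)
  }

  list(t0 = build_slice("t0"), t1 = build_slice("t1"), fields = fields)
}

#' Ground-truth species envelope
#'
#' The true occurrence surface of a synthetic species is a product of
#' bell-shaped (Gaussian) responses to a subset of layers:
#' `p = max_prob * prod_l exp(-((v_l - optimum_l) / breadth_l)^2)`.
#'
#' @param species_id label.
#' @param optimum named numeric vector: per-layer response centre (names are
#'   layer names; they define `response_layers`).
#' @param breadth named numeric vector (same names): per-layer tolerance in
#'   layer units, all > 0.
#' @param max_prob peak occurrence probability, in (0, 1].
#' @return object of class `species_envelope`.
#' @export
species_envelope <- function(species_id, optimum, breadth, max_prob = 0.9) {
  stopifnot(length(optimum) >= 1, !is.null(names(optimum)))
  breadth <- breadth[names(optimum)]
  if (any(is.na(breadth)) || any(breadth <= 0))
    stop("breadth must be positive for every response layer")
  if (!is.finite(max_prob) || max_prob <= 0 || max_prob > 1)
    stop("max_prob must lie in (0, 1]")
  structure(list(species_id = species_id,
                 response_layers = names(optimum),
                 optimum = optimum, breadth = breadth, max_prob = max_prob),
            class = "species_envelope")
}

#' Evaluate a species' true occurrence probability on a stack
#'
#' @param envelope a [species_envelope].
#' @param stack a [covariate_stack] containing every response layer.
#' @return an [sdm_grid] of probabilities in `[0, max_prob]`.
#' @export
species_probability <- function(envelope, stack) {
  missing <- setdiff(envelope$response_layers, stack_names(stack))
  if (length(missing))
    stop(sprintf("stack is missing response layer(s): %s",
                 paste(missing, collapse = ", ")))
  geom <- stack_geom(stack)
  p <- matrix(envelope$max_prob, geom$ny, geom$nx)
  for (lname in envelope$response_layers) {
    v <- stack$layers[[lname]]$values
    z <- (v - envelope$optimum[[lname]]) / envelope$breadth[[lname]]
    p <- p * exp(-z^2)
  }
  sdm_grid(p, xmin = geom$xmin, ymin = geom$ymin, res = geom$res)
}

#' Draw presence-only occurrence records from a probability surface
#'
#' Cells are drawn with replacement with probability proportional to the
#' occurrence surface (times the sampling-bias surface, if given — bias
#' affects where records are collected, never the true envelope), and each
#' record is jittered uniformly within its cell. Output is reproducible
#' under a fixed seed.
#'
#' @param prob an [sdm_grid] of occurrence probabilities in `[0, 1]`.
#' @param n_target number of records to draw (> 0).
#' @param bias optional [sdm_grid] of non-negative sampling intensity.
#' @param seed integer seed.
#' @param species_id label written into the records.
#' @param year collection year written into the records.
#' @return data.frame of occurrence records (columns `species_id`, `x`, `y`,
#'   `catalog_id`, `year`), attribute `coord_mode = "planar"`.
#' @export
sample_occurrences <- function(prob, n_target, bias = NULL, seed = 1,
                               species_id = "species", year = 2010) {
  stopifnot(n_target > 0)
  p <- prob$values
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    stop("probability surface must lie in [0, 1]")
  w <- p
  if (!is.null(bias)) {
    stop_if_misaligned(prob, bias, "probability and bias grids")
    w <- w * bias$values
  }
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no habitat to sample: probability mass is zero")
  set.seed(seed)
  cells <- sample.int(length(w), n_target, replace = TRUE, prob = as.vector(w))
  ij <- arrayInd(cells, dim(w))
  jit_x <- stats::runif(n_target) * prob$res
  jit_y <- stats::runif(n_target) * prob$res
  out <- data.frame(
    species_id = species_id,
    x = prob$xmin + (ij[, 2] - 1) * prob$res + jit_x,
    y = prob$ymin + (ij[, 1] - 1) * prob$res + jit_y,
    catalog_id = sprintf("SYN-%s-%05d", species_id, seq_len(n_target)),
    year = year,
    stringsAsFactors = FALSE)
  attr(out, "coord_mode") <- "planar"
  out
}

#' Default synthetic species set
#'
#' Four species spanning the behaviours the pipeline must distinguish:
#' a specialist tracking the drifting dynamic gradient (known displacement),
#' a specialist on the static elevation field (no-drift control), a broad
#' generalist on the dynamic gradient, and a warm-edge species. Simulating
#' several species together gives the target-group pseudo-absence rule
#' dense non-target coverage.
#'
#' @param landscape output of [make_landscape] (used to centre optima on the
#'   realised field values).
#' @return named list of [species_envelope]s.
#' @export
default_species <- function(landscape) {
  elev <- landscape$t0$layers[["elevation"]]$values
  list(
    drifting_specialist = species_envelope(
      "drifting_specialist", optimum = c(mean_temp = 8),
      breadth = c(mean_temp = 1.5), max_prob = 0.9),
    static_specialist = species_envelope(
      "static_specialist",
      optimum = c(elevation = stats::median(elev)),
      breadth = c(elevation = stats::sd(elev) * 0.6), max_prob = 0.9),
    generalist = species_envelope(
      "generalist", optimum = c(mean_temp = 8),
      breadth = c(mean_temp = 6), max_prob = 0.6),
    warm_south = species_envelope(
      "warm_south", optimum = c(mean_temp = 14),
      breadth = c(mean_temp = 2), max_prob = 0.9))
}

#' Simulate a multi-species occurrence dataset for the first time slice
#'
#' @param landscape output of [make_landscape].
#' @param species named list of [species_envelope]s.
#' @param n_per_species records drawn per species.
#' @param bias optional sampling-bias [sdm_grid] shared by all species.
#' @param seed integer seed; each species gets a derived sub-seed.
#' @return single data.frame of occurrence records, `coord_mode = "planar"`.
#' @export
simulate_occurrences <- function(landscape, species, n_per_species = 400,
                                 bias = NULL, seed = 1) {
  recs <- lapply(seq_along(species), function(i) {
    sp <- species[[i]]
    p <- species_probability(sp, landscape$t0)
    sample_occurrences(p, n_per_species, bias = bias,
                       seed = seed + 1000L * i,
                       species_id = sp$species_id)
  })
  out <- do.call(rbind, recs)
  attr(out, "coord_mode") <- "planar"
  out
}
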