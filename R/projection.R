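#' Build a regular prediction lattice over a study mask
#'
#' Points are spaced `spacing_km` apart along both axes, anchored at the
#' lower-left corner of the mask bounding box and inclusive of both edges;
#' points falling outside the mask are dropped.
#'
#' @param mask study-area [sdm_grid] (NA = outside).
#' @param spacing_km lattice spacing, km (default 5).
#' @return object of class `prediction_lattice`: fields `points` (data.frame
#'   `x`, `y`), `spacing_km`, `mask`, and (after [attach_timeslice]) `cov`.
#' @export
build_lattice <- function(mask, spacing_km = 5) {
  xmax <- mask$xmin + mask$nx * mask$res
  ymax <- mask$ymin + mask$ny * mask$res
  if (spacing_km > (xmax - mask$xmin) || spacing_km > (ymax - mask$ymin))
    stop("lattice spacing exceeds the mask extent")
  xs <- seq(mask$xmin, xmax, by = spacing_km)
  ys <- seq(mask$ymin, ymax, by = spacing_km)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  inside <- !is.na(grid_extract(mask, pts$x, pts$y))
  structure(list(points = pts[inside, , drop = FALSE],
                 spacing_km = spacing_km, mask = mask, cov = NULL),
            class = "prediction_lattice")
}

#' @export
print.prediction_lattice <- function(x, ...) {
  cat(sprintf("<prediction_lattice> %d points at %g km spacing%s\n",
              nrow(x$points), x$spacing_km,
              if (is.null(x$cov)) "" else
                sprintf(", covariates attached for %s",
                        paste(names(x$cov), collapse = "/"))))
  invisible(x)
}

#' Attach two-slice covariates to a lattice
#'
#' Each lattice point receives one covariate vector per time slice. The two
#' stacks must be aligned with identical layer names and flags, and every
#' static layer must be bit-identical between slices (that is what "static"
#' means); a differing static layer is an error naming the layer. Points
#' with incomplete covariates in either slice are dropped with a reported
#' count so that every retained point carries a complete vector per slice.
#'
#' @param lattice a [build_lattice] lattice.
#' @param stack_t0,stack_t1 [covariate_stack]s for the two slices.
#' @return the lattice with a `cov` field: list of data.frames `t0`, `t1`.
#' @export
attach_timeslice <- function(lattice, stack_t0, stack_t1) {
  stop_if_misaligned(stack_geom(stack_t0), stack_geom(stack_t1),
                     "time-slice stacks")
  if (!identical(stack_names(stack_t0), stack_names(stack_t1)))
    stop("time-slice stacks must share layer names")
  if (!identical(unname(stack_t0$temporal), unname(stack_t1$temporal)))
    stop("time-slice stacks disagree on static/dynamic flags")
  for (nm in stack_names(stack_t0)[stack_t0$temporal == "static"]) {
    if (!identical(stack_t0$layers[[nm]]$values,
                   stack_t1$layers[[nm]]$values))
      stop(sprintf("static layer '%s' differs between time slices", nm))
  }
  cov_t0 <- stack_extract(stack_t0, lattice$points$x, lattice$points$y)
  cov_t1 <- stack_extract(stack_t1, lattice$points$x, lattice$points$y)
  ok <- stats::complete.cases(cov_t0) & stats::complete.cases(cov_t1)
  if (any(!ok))
    message(sprintf("attach_timeslice: dropped %d lattice point(s) on missing data",
                    sum(!ok)))
  lattice$points <- lattice$points[ok, , drop = FALSE]
  lattice$cov <- list(t0 = cov_t0[ok, , drop = FALSE],
                      t1 = cov_t1[ok, , drop = FALSE])
  lattice
}

#' Predict relative indices of occurrence on a lattice
#'
#' RIO at a point is the ensemble presence-vote fraction in `[0, 1]` — a
#' ranking of locations by presence-likeness, not a calibrated probability,
#' and it is never relabelled as one. Categorical labels unseen at training
#' (possible when projecting to the future slice) are routed to the largest
#' training category with a reported count.
#'
#' @param model an `envelope_model`.
#' @param lattice a lattice with covariates attached ([attach_timeslice]).
#' @param time_slice `"t0"` or `"t1"`.
#' @return numeric vector of RIO values, one per lattice point.
#' @export
predict_rio <- function(model, lattice, time_slice = "t0") {
  if (is.null(lattice$cov))
    stop("lattice has no covariates; call attach_timeslice() first")
  newdata <- lattice$cov[[time_slice]]
  missing <- setdiff(model$layer_names, colnames(newdata))
  if (length(missing))
    stop(sprintf("lattice lacks model layer(s): %s",
                 paste(missing, collapse = ", ")))
  newdata <- newdata[model$layer_names]
  for (nm in names(model$category_registry)) {
    reg <- model$category_registry[[nm]]
    lab <- as.character(newdata[[nm]])
    unseen <- !is.na(lab) & !(lab %in% reg)
    if (any(unseen)) {
      fallback <- model$category_fallback[[nm]]
      message(sprintf("predict_rio('%s'): %d unseen '%s' label(s) routed to '%s'",
                      model$species_id, sum(unseen), nm, fallback))
      lab[unseen] <- fallback
    }
    newdata[[nm]] <- factor(lab, levels = reg)
  }
  unname(stats::predict(model$rf, newdata, type = "prob")[, "presence"])
}

#' Smooth lattice values into a continuous surface by IDW
#'
#' Inverse-distance-weighted interpolation from the lattice points to a
#' fine raster clipped to the study mask: each cell takes the weighted mean
#' of its `n_neighbors` nearest lattice points with weights `d^-power`; a
#' cell coincident with a lattice point takes that point's exact value. IDW
#' is a convex combination, so the surface is bounded by the range of the
#' input values.
#'
#' @param points data.frame with `x`, `y` of lattice points (>= 1).
#' @param values numeric vector, one value per point.
#' @param mask study-area [sdm_grid]; output is clipped to it.
#' @param resolution_km output cell size, km (default 1).
#' @param power inverse-distance exponent (default 2).
#' @param n_neighbors number of nearest points used per cell (default 12).
#' @return an [sdm_grid] at the output resolution (NA outside the mask).
#' @export
smooth_idw <- function(points, values, mask, resolution_km = 1, power = 2,
                       n_neighbors = 12) {
  stopifnot(nrow(points) >= 1, length(values) == nrow(points))
  out_mask <- grid_at_resolution(mask, resolution_km)
  ctr <- grid_centers(out_mask)
  cells <- which(!is.na(out_mask$values))
  ij <- arrayInd(cells, dim(out_mask$values))
  cx <- ctr$x[ij[, 2]]
  cy <- ctr$y[ij[, 1]]
  k <- min(n_neighbors, nrow(points))
  px <- points$x; py <- points$y
  vals <- numeric(length(cells))
  chunk <- 4000L
  for (s in seq(1, length(cells), by = chunk)) {
    e <- min(s + chunk - 1L, length(cells))
    d2 <- outer(cx[s:e], px, "-")^2 + outer(cy[s:e], py, "-")^2
    for (r in seq_len(e - s + 1L)) {
      d <- d2[r, ]
      nn <- if (k < length(d)) order(d)[seq_len(k)] else order(d)
      if (d[nn[1]] < 1e-18) {
        vals[s + r - 1L] <- values[nn[1]]
      } else {
        w <- d[nn]^(-power / 2)             # d2 is squared distance
        vals[s + r - 1L] <- sum(w * values[nn]) / sum(w)
      }
    }
  }
  m <- matrix(NA_real_, out_mask$ny, out_mask$nx)
  m[cells] <- vals
  sdm_grid(m, xmin = out_mask$xmin, ymin = out_mask$ymin,
           res = out_mask$res)
}

#' RIO surface container
#'
#' @param grid an [sdm_grid] of RIO values in `[0, 1]` (NA = masked).
#' @param species_id species label.
#' @param time_slice `"t0"` or `"t1"`.
#' @return object of class `rio_surface`.
#' @export
rio_surface <- function(grid, species_id, time_slice) {
  v <- grid$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("RIO values must lie in [0, 1]")
  structure(list(grid = grid, species_id = species_id,
                 time_slice = time_slice),
            class = "rio_surface")
}

as_grid <- function(x) {
  if (inherits(x, "sdm_grid")) x
  else if (!is.null(x$grid)) x$grid
  else stop("expected an sdm_grid or a container holding one")
}
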