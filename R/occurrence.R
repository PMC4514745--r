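#' Occurrence records
#'
#' Occurrence records are plain data.frames with columns `species_id`, `x`,
#' `y`, `catalog_id` and (optionally) `year`, plus a `coord_mode` attribute:
#' `"planar"` (easting/northing in km, Euclidean distance) or `"lonlat"`
#' (decimal degrees, great-circle distance on the WGS84 sphere). Year is
#' carried as metadata and never filtered on.
#'
#' @name occurrence-records
NULL

coord_mode <- function(records, default = "planar") {
  m <- attr(records, "coord_mode")
  if (is.null(m)) default else m
}

# distance (km) from one point to many, honouring the coordinate mode
dist_to_km <- function(x0, y0, xs, ys, mode) {
  if (mode == "lonlat") {
    geosphere::distHaversine(c(x0, y0), cbind(xs, ys)) / 1000
  } else {
    sqrt((xs - x0)^2 + (ys - y0)^2)
  }
}

count_decimals <- function(s) {
  s <- as.character(s)
  has <- grepl("\\.", s)
  out <- integer(length(s))
  out[has] <- nchar(sub("^-?[0-9]*\\.", "", s[has]))
  out
}

#' Read an occurrence CSV
#'
#' Accepts either the package's native columns (`species_id`, `x`, `y`,
#' `catalog_id`, `year`) or Darwin-Core-style aliases
#' (`scientificName`/`decimalLongitude`/`decimalLatitude`/`catalogNumber`).
#' When coordinates are longitude/latitude, the stated decimal precision of
#' each coordinate is taken from the source strings and recorded in
#' `precision_x` / `precision_y` columns for [filter_precision].
#'
#' @param path CSV file (UTF-8, header row).
#' @param mode `"planar"`, `"lonlat"`, or `NULL` to infer (Darwin-Core alias
#'   columns imply `"lonlat"`).
#' @return occurrence data.frame (see [occurrence-records]).
#' @export
read_occurrences <- function(path, mode = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  alias <- c(species_id = "scientificName", x = "decimalLongitude",
             y = "decimalLatitude", catalog_id = "catalogNumber")
  used_alias <- FALSE
  for (nm in names(alias)) {
    if (!nm %in% names(raw) && alias[[nm]] %in% names(raw)) {
      names(raw)[names(raw) == alias[[nm]]] <- nm
      used_alias <- TRUE
    }
  }
  need <- c("species_id", "x", "y")
  if (!all(need %in% names(raw)))
    stop("occurrence CSV must provide species_id, x, y (or Darwin-Core aliases)")
  if (is.null(mode)) mode <- if (used_alias) "lonlat" else "planar"
  out <- data.frame(
    species_id = raw$species_id,
    x = as.numeric(raw$x), y = as.numeric(raw$y),
    catalog_id = if ("catalog_id" %in% names(raw)) raw$catalog_id
                 else sprintf("rec-%06d", seq_len(nrow(raw))),
    year = if ("year" %in% names(raw)) suppressWarnings(as.integer(raw$year))
           else NA_integer_,
    stringsAsFactors = FALSE)
  if (mode == "lonlat") {
    out$precision_x <- count_decimals(raw$x)
    out$precision_y <- count_decimals(raw$y)
  }
  if (any(!is.finite(out$x) | !is.finite(out$y)))
    stop("occurrence coordinates must be finite numbers")
  attr(out, "coord_mode") <- mode
  out
}

#' Write an occurrence CSV
#'
#' @param records occurrence data.frame.
#' @param path output file.
#' @export
write_occurrences <- function(records, path) {
  keep <- intersect(c("species_id", "x", "y", "catalog_id", "year"),
                    names(records))
  utils::write.csv(records[keep], path, row.names = FALSE)
  invisible(path)
}

#' Drop records below a stated coordinate precision
#'
#' Records whose longitude or latitude was reported with fewer than
#' `min_decimals` decimal places are removed. Precision applies to
#' longitude/latitude sources; if the `precision_x`/`precision_y` columns
#' are absent they are derived from the printed representation of the
#' coordinates. The number of removals is reported as a message.
#'
#' @param records occurrence data.frame.
#' @param min_decimals minimum decimal places required on both coordinates.
#' @return filtered records (possibly empty).
#' @export
filter_precision <- function(records, min_decimals = 5) {
  if (nrow(records) == 0) return(records)
  px <- records$precision_x
  py <- records$precision_y
  if (is.null(px)) px <- count_decimals(records$x)
  if (is.null(py)) py <- count_decimals(records$y)
  keep <- px >= min_decimals & py >= min_decimals
  if (any(!keep))
    message(sprintf("filter_precision: removed %d of %d records below %d decimals",
                    sum(!keep), length(keep), min_decimals))
  out <- records[keep, , drop = FALSE]
  attr(out, "coord_mode") <- coord_mode(records)
  out
}

#' Spatially thin records to one per species within a radius
#'
#' Within each species, at most one record is retained inside any
#' `radius_km` neighbourhood (exact coordinate duplicates are the degenerate
#' case). Removal is greedy in a deterministic order — records sorted by
#' (species_id, catalog_id, x, y), the first record of each conflict cluster
#' kept — so the retained set does not depend on input row order. Records of
#' different species never thin each other. Two records conflict when their
#' separation is `<= radius_km`.
#'
#' @param records occurrence data.frame (one or more species).
#' @param radius_km thinning radius, km.
#' @return thinned records in the deterministic sort order.
#' @export
spatial_thin <- function(records, radius_km = 1) {
  mode <- coord_mode(records)
  if (nrow(records) <= 1) return(records)
  ord <- order(records$species_id, records$catalog_id, records$x, records$y)
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  for (sp in unique(records$species_id)) {
    idx <- which(records$species_id == sp)
    kept_x <- numeric(0); kept_y <- numeric(0)
    for (i in idx) {
      if (length(kept_x) == 0 ||
          all(dist_to_km(records$x[i], records$y[i], kept_x, kept_y, mode) >
              radius_km)) {
        keep[i] <- TRUE
        kept_x <- c(kept_x, records$x[i])
        kept_y <- c(kept_y, records$y[i])
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- mode
  out
}

#' Target-group pseudo-absences
#'
#' Candidate sites are the unique locations holding at least one record of a
#' non-target species; a site becomes a pseudo-absence for the target
#' species iff no target record lies within `radius_km` of it. Apply to the
#' thinned, multi-species record set.
#'
#' @param records thinned occurrence data.frame for all species.
#' @param target species_id of the modelled species.
#' @param radius_km exclusion radius around target presences, km.
#' @return data.frame of pseudo-absence points (`x`, `y`), each site once.
#' @export
build_pseudo_absences <- function(records, target, radius_km = 1) {
  mode <- coord_mode(records)
  non_target <- records[records$species_id != target, , drop = FALSE]
  targets <- records[records$species_id == target, , drop = FALSE]
  if (nrow(non_target) == 0) {
    warning(sprintf("no non-target records available for '%s'; no pseudo-absences",
                    target))
    out <- data.frame(x = numeric(0), y = numeric(0))
    attr(out, "coord_mode") <- mode
    return(out)
  }
  sites <- unique(non_target[c("x", "y")])
  ok <- vapply(seq_len(nrow(sites)), function(i) {
    if (nrow(targets) == 0) return(TRUE)
    all(dist_to_km(sites$x[i], sites$y[i], targets$x, targets$y, mode) >
        radius_km)
  }, logical(1))
  out <- sites[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- mode
  out
}

#' Attach covariates to presences and pseudo-absences
#'
#' Every point is attributed with one value per stack layer (categorical
#' layers as factor labels, never numbers). Points falling on missing data
#' or outside the stack extent are dropped with a reported count; more than
#' half the points missing indicates a mask/stack mismatch and is an error.
#'
#' @param target species_id.
#' @param presences data.frame with `x`, `y` of presence points.
#' @param pseudo_absences data.frame with `x`, `y` of pseudo-absence points.
#' @param stack a [covariate_stack] for the training time slice.
#' @return object of class `training_set`: fields `species_id`, `features`
#'   (covariate data.frame), `label` (factor `absence`/`presence`), `coords`,
#'   `n_presence`, `n_absence`.
#' @export
assemble_training <- function(target, presences, pseudo_absences, stack) {
  pts <- rbind(
    data.frame(x = presences$x, y = presences$y, label = "presence"),
    data.frame(x = pseudo_absences$x, y = pseudo_absences$y,
               label = "absence"))
  feats <- stack_extract(stack, pts$x, pts$y)
  complete <- stats::complete.cases(feats)
  n_drop <- sum(!complete)
  if (n_drop > 0.5 * nrow(pts))
    stop(sprintf("assemble_training('%s'): %d of %d points fall on missing data; stack/mask mismatch?",
                 target, n_drop, nrow(pts)))
  if (n_drop > 0)
    message(sprintf("assemble_training('%s'): dropped %d point(s) on missing data",
                    target, n_drop))
  feats <- feats[complete, , drop = FALSE]
  pts <- pts[complete, , drop = FALSE]
  label <- factor(pts$label, levels = c("absence", "presence"))
  structure(list(species_id = target, features = feats, label = label,
                 coords = pts[c("x", "y")],
                 n_presence = sum(label == "presence"),
                 n_absence = sum(label == "absence")),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s: %d presences, %d pseudo-absences, %d covariates\n",
              x$species_id, x$n_presence, x$n_absence, ncol(x$features)))
  invisible(x)
}
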