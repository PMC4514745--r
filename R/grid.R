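#' Lightweight planar raster grids
#'
#' All raster math in the pipeline runs in an equal-area planar frame with
#' coordinates in kilometres ("latitude" is northing). A grid is a numeric
#' matrix plus its geometry; rows index northing from south to north, columns
#' index easting from west to east, so `values[i, j]` is the cell centred at
#' `(xmin + (j - 0.5) * res, ymin + (i - 0.5) * res)`. `NA` is the no-data
#' marker throughout.
#'
#' @param values numeric matrix (rows = south-to-north, cols = west-to-east).
#' @param xmin,ymin coordinates of the lower-left corner of the grid, km.
#' @param res cell size, km (> 0).
#' @return an object of class `sdm_grid`.
#' @export
sdm_grid <- function(values, xmin = 0, ymin = 0, res = 1) {
  values <- as.matrix(values)
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0)
    stop("grid resolution must be a single positive number")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         nx = ncol(values), ny = nrow(values)),
    class = "sdm_grid")
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("<sdm_grid> %d x %d cells, res %g km, origin (%g, %g)\n",
              x$ny, x$nx, x$res, x$xmin, x$ymin))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d no-data cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid an [sdm_grid].
#' @return list with vectors `x` (length nx) and `y` (length ny) of cell
#'   centres, km.
#' @export
grid_centers <- function(grid) {
  list(x = grid$xmin + (seq_len(grid$nx) - 0.5) * grid$res,
       y = grid$ymin + (seq_len(grid$ny) - 0.5) * grid$res)
}

#' Map point coordinates to grid cell indices
#'
#' Points on the exterior boundary are assigned to the nearest edge cell;
#' points outside the extent get `NA` indices.
#'
#' @param grid an [sdm_grid].
#' @param x,y point coordinates, km.
#' @return data.frame with integer columns `row`, `col` (`NA` outside extent).
#' @export
grid_cell_index <- function(grid, x, y) {
  xmax <- grid$xmin + grid$nx * grid$res
  ymax <- grid$ymin + grid$ny * grid$res
  inside <- x >= grid$xmin & x <= xmax & y >= grid$ymin & y <= ymax
  col <- floor((x - grid$xmin) / grid$res) + 1L
  row <- floor((y - grid$ymin) / grid$res) + 1L
  col <- pmin.int(pmax.int(col, 1L), grid$nx)
  row <- pmin.int(pmax.int(row, 1L), grid$ny)
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract cell values at point locations
#'
#' Nearest-cell (containing-cell) extraction; no interpolation. Points
#' outside the grid extent return `NA`.
#'
#' @inheritParams grid_cell_index
#' @return numeric vector of cell values.
#' @export
grid_extract <- function(grid, x, y) {
  idx <- grid_cell_index(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Test two grids for alignment
#'
#' Aligned means identical origin, resolution and dimensions.
#'
#' @param a,b [sdm_grid] objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(all.equal(a$xmin, b$xmin)) && isTRUE(all.equal(a$ymin, b$ymin)) &&
    isTRUE(all.equal(a$res, b$res)) && a$nx == b$nx && a$ny == b$ny
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop(sprintf("%s are not aligned (origin/resolution/dimensions differ)",
                 what))
  invisible(TRUE)
}

#' Write a grid as an Esri ASCII raster
#'
#' Plain-text headered grid format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header, then rows north to south). Readable by
#' standard GIS software.
#'
#' @param grid an [sdm_grid].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$nx),
    sprintf("nrows %d", grid$ny),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %g", nodata)), con)
  v <- grid$values
  v[is.na(v)] <- nodata
  # ASCII grids are stored top row first (northmost)
  for (i in rev(seq_len(grid$ny)))
    writeLines(paste(format(v[i, ], trim = TRUE, scientific = FALSE,
                            digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an Esri ASCII raster
#'
#' @param path file written by [write_asc] (or any Esri ASCII grid).
#' @return an [sdm_grid]; no-data cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nx * ny)
    stop("ASCII grid body does not match declared dimensions")
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m[rev(seq_len(ny)), , drop = FALSE]          # back to south-first rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  sdm_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner, res = hdr$cellsize)
}

#' Rectangular study-area mask
#'
#' @param extent_km c(width, height) of the study area, km.
#' @param res cell size, km.
#' @param xmin,ymin lower-left corner, km.
#' @return an [sdm_grid] with logical-valued cells (1 inside, NA outside).
#' @export
make_mask <- function(extent_km, res = 1, xmin = 0, ymin = 0) {
  nx <- as.integer(round(extent_km[1] / res))
  ny <- as.integer(round(extent_km[2] / res))
  if (nx < 1L || ny < 1L) stop("mask extent must cover at least one cell")
  sdm_grid(matrix(1, ny, nx), xmin = xmin, ymin = ymin, res = res)
}

#' Resample a grid to a new resolution by nearest-cell lookup
#'
#' Works for masks and value grids alike; no interpolation is performed.
#'
#' @param mask an [sdm_grid] (NA = no-data).
#' @param res target resolution, km.
#' @return an [sdm_grid] at the target resolution over the same extent.
#' @export
grid_at_resolution <- function(mask, res) {
  if (isTRUE(all.equal(res, mask$res))) return(mask)
  width <- mask$nx * mask$res
  height <- mask$ny * mask$res
  nx <- max(1L, as.integer(round(width / res)))
  ny <- max(1L, as.integer(round(height / res)))
  cx <- mask$xmin + (seq_len(nx) - 0.5) * res
  cy <- mask$ymin + (seq_len(ny) - 0.5) * res
  pts <- expand.grid(x = cx, y = cy)
  v <- grid_extract(mask, pts$x, pts$y)
  sdm_grid(matrix(v, nrow = ny, ncol = nx, byrow = TRUE),
           xmin = mask$xmin, ymin = mask$ymin, res = res)
}
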