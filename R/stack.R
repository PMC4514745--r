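#' Covariate stacks
#'
#' A covariate stack holds the aligned environmental layers for one time
#' slice. Each layer is an [sdm_grid]; per-layer metadata flags it
#' `static`/`dynamic` (is it updated between time slices?) and
#' `continuous`/`categorical`. Categorical layers store integer codes in the
#' grid plus a label registry fixing the code-to-label order, so model runs
#' are reproducible.
#'
#' @param layers named list of [sdm_grid]s, all aligned.
#' @param temporal character vector ("static"/"dynamic"), one per layer.
#' @param type character vector ("continuous"/"categorical"), one per layer.
#' @param levels named list: for each categorical layer, the character vector
#'   of labels corresponding to integer codes 1, 2, ...
#' @param time_slice label, e.g. "t0" or "t1".
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, temporal, type = NULL, levels = list(),
                            time_slice = "t0") {
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must be uniquely named")
  if (is.null(type)) type <- rep("continuous", length(layers))
  temporal <- rep_len(temporal, length(layers))
  type <- rep_len(type, length(layers))
  stopifnot(all(temporal %in% c("static", "dynamic")),
            all(type %in% c("continuous", "categorical")))
  for (i in seq_along(layers)[-1])
    stop_if_misaligned(layers[[1]], layers[[i]],
                       sprintf("layers '%s' and '%s'", nm[1], nm[i]))
  for (nm_cat in nm[type == "categorical"])
    if (is.null(levels[[nm_cat]]))
      stop(sprintf("categorical layer '%s' needs a level registry", nm_cat))
  structure(list(layers = layers, temporal = stats::setNames(temporal, nm),
                 type = stats::setNames(type, nm), levels = levels,
                 time_slice = time_slice),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> slice '%s': %d layers (%d static, %d dynamic)\n",
              x$time_slice, length(x$layers), sum(x$temporal == "static"),
              sum(x$temporal == "dynamic")))
  invisible(x)
}

stack_names <- function(stack) names(stack$layers)

stack_geom <- function(stack) stack$layers[[1]]

#' Extract covariate values at points
#'
#' Returns one column per layer; categorical layers come back as factors
#' with levels fixed by the stack's registry.
#'
#' @param stack a [covariate_stack].
#' @param x,y point coordinates, km.
#' @return data.frame of covariate values (NA where a point misses data).
#' @export
stack_extract <- function(stack, x, y) {
  out <- lapply(stack_names(stack), function(nm) {
    v <- grid_extract(stack$layers[[nm]], x, y)
    if (stack$type[[nm]] == "categorical")
      v <- factor(stack$levels[[nm]][as.integer(v)],
                  levels = stack$levels[[nm]])
    v
  })
  names(out) <- stack_names(stack)
  as.data.frame(out, optional = TRUE)
}

#' Write every layer of a stack as ASCII rasters
#'
#' Files are named `<prefix><layer>.asc`; a small JSON sidecar records the
#' static/dynamic and continuous/categorical flags and level registries.
#'
#' @param stack a [covariate_stack].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default the stack's time-slice label.
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir, prefix = paste0(stack$time_slice, "_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in stack_names(stack)) {
    f <- file.path(dir, paste0(prefix, nm, ".asc"))
    write_asc(stack$layers[[nm]], f)
    files <- c(files, f)
  }
  meta <- file.path(dir, paste0(prefix, "stack.json"))
  jsonlite::write_json(
    list(time_slice = stack$time_slice, layers = stack_names(stack),
         temporal = as.list(stack$temporal), type = as.list(stack$type),
         levels = stack$levels),
    meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, meta))
}

#' Read a stack written by [write_stack]
#'
#' @param dir directory holding the `.asc` layers and JSON sidecar.
#' @param prefix filename prefix used at write time.
#' @return a [covariate_stack].
#' @export
read_stack <- function(dir, prefix) {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "stack.json")),
                              simplifyVector = TRUE)
  layers <- lapply(meta$layers, function(nm) {
    f <- file.path(dir, paste0(prefix, nm, ".asc"))
    if (!file.exists(f)) stop("missing layer file: ", f)
    read_asc(f)
  })
  names(layers) <- meta$layers
  covariate_stack(layers,
                  temporal = unlist(meta$temporal)[meta$layers],
                  type = unlist(meta$type)[meta$layers],
                  levels = as.list(meta$levels),
                  time_slice = meta$time_slice)
}
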