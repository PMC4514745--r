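#' Uniform random points within a study mask
#'
#' Rejection sampling over the mask bounding box; reproducible under seed.
#'
#' @param mask study-area [sdm_grid].
#' @param n number of points (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_points <- function(mask, n = 50000, seed = 1) {
  stopifnot(n >= 2)
  if (all(is.na(mask$values)))
    stop("degenerate mask: no unmasked cells to sample")
  set.seed(seed)
  xmax <- mask$xmin + mask$nx * mask$res
  ymax <- mask$ymin + mask$ny * mask$res
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- ceiling((n - length(xs)) * 1.5) + 10
    cx <- stats::runif(m, mask$xmin, xmax)
    cy <- stats::runif(m, mask$ymin, ymax)
    keep <- !is.na(grid_extract(mask, cx, cy))
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Pairwise correlation of species RIO surfaces at sample points
#'
#' Samples every species' RIO surface at the same point set and computes
#' pairwise Pearson and Spearman correlations. A zero-variance species is
#' flagged and its row/column left undefined (NA); it is excluded from
#' clustering with a warning.
#'
#' @param points data.frame with `x`, `y` (e.g. from [sample_points]).
#' @param rios list of [rio_surface]s (>= 2 species).
#' @return object of class `rio_correlation`: fields `species`, `r`
#'   (Pearson), `rho` (Spearman), `samples` (points-by-species matrix),
#'   `n_points`, `degenerate` (species flagged zero-variance).
#' @export
correlation_matrix <- function(points, rios) {
  stopifnot(length(rios) >= 2)
  sp <- vapply(rios, function(r) r$species_id, character(1))
  m <- vapply(rios, function(r)
    grid_extract(as_grid(r), points$x, points$y), numeric(nrow(points)))
  colnames(m) <- sp
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  degenerate <- sp[apply(m, 2, stats::sd) == 0]
  if (length(degenerate))
    warning(sprintf("zero-variance RIO for: %s (correlations undefined)",
                    paste(degenerate, collapse = ", ")))
  suppressWarnings({
    r <- stats::cor(m, method = "pearson")
    rho <- stats::cor(m, method = "spearman")
  })
  r[degenerate, ] <- NA; r[, degenerate] <- NA
  rho[degenerate, ] <- NA; rho[, degenerate] <- NA
  diag(r) <- 1; diag(rho) <- 1
  structure(list(species = sp, r = r, rho = rho, samples = m,
                 n_points = nrow(m), degenerate = degenerate),
            class = "rio_correlation")
}

#' Classify species pairs by correlation
#'
#' Pairs with Pearson r >= `pos` are classified as likely to co-occur
#' (boundary inclusive); pairs with r < `neg` (strict) as spatially
#' exclusive; everything else as neutral.
#'
#' @param corr a [correlation_matrix] result (or bare correlation matrix).
#' @param pos positive threshold, default 0.25.
#' @param neg negative threshold, default -0.25.
#' @return data.frame with one row per unordered pair: `species_a`,
#'   `species_b`, `r`, `class` (`co_occurring`/`exclusive`/`neutral`).
#' @export
classify_pairs <- function(corr, pos = 0.25, neg = -0.25) {
  r <- if (is.matrix(corr)) corr else corr$r
  sp <- colnames(r)
  pairs <- utils::combn(sp, 2)
  rv <- r[t(pairs)]
  cls <- ifelse(is.na(rv), NA_character_,
                ifelse(rv >= pos, "co_occurring",
                       ifelse(rv < neg, "exclusive", "neutral")))
  data.frame(species_a = pairs[1, ], species_b = pairs[2, ], r = rv,
             class = cls, stringsAsFactors = FALSE)
}

#' Cluster species into community assemblages
#'
#' Agglomerative clustering of species on the dissimilarity 1 - rho^2
#' (squared Spearman rank correlation of RIO values, the classical
#' variable-clustering similarity), complete linkage by default. Groups are
#' cut at `n_groups` or at a tree `height`. Degenerate (zero-variance)
#' species are excluded. The correlation flavour and linkage are options,
#' not baked in.
#'
#' @param corr a [correlation_matrix] result.
#' @param n_groups number of groups to cut (mutually exclusive with
#'   `height`).
#' @param height tree height to cut at.
#' @param use similarity flavour: `"spearman2"` (1 - rho^2, default),
#'   `"pearson2"` (1 - r^2) or `"pearson"` (1 - r).
#' @param linkage linkage method passed to [stats::hclust].
#' @param time_slice label carried into the output.
#' @return object of class `community_assignment`: fields `groups` (named
#'   integer vector, species to group), `tree` (hclust), `merges`
#'   (data.frame of merge heights), `time_slice`.
#' @export
cluster_species <- function(corr, n_groups = NULL, height = NULL,
                            use = c("spearman2", "pearson2", "pearson"),
                            linkage = "complete", time_slice = "t0") {
  use <- match.arg(use)
  sp <- setdiff(corr$species, corr$degenerate)
  if (length(sp) < 2)
    stop("need at least 2 non-degenerate species to cluster")
  if (!is.null(n_groups) && n_groups > length(sp))
    stop("n_groups exceeds the number of species")
  d <- switch(use,
              spearman2 = 1 - corr$rho[sp, sp]^2,
              pearson2 = 1 - corr$r[sp, sp]^2,
              pearson = 1 - corr$r[sp, sp])
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  groups <- if (!is.null(n_groups)) stats::cutree(tree, k = n_groups)
            else if (!is.null(height)) stats::cutree(tree, h = height)
            else stop("supply n_groups or height")
  merges <- data.frame(height = tree$height)
  structure(list(groups = groups, tree = tree, merges = merges,
                 time_slice = time_slice),
            class = "community_assignment")
}

#' Write a community tree as Newick text
#'
#' Merge heights become branch lengths (ultrametric dendrogram).
#'
#' @param assignment a [cluster_species] result.
#' @param path output file.
#' @export
write_newick <- function(assignment, path) {
  phy <- ape::as.phylo(assignment$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Species whose community membership changed between time slices
#'
#' Group labels are arbitrary, so groups are first matched across the two
#' assignments by maximal membership overlap (greedy on the Jaccard index;
#' ties resolved lexicographically and flagged). A species is reported iff
#' its matched labels differ — a pure relabelling of an identical partition
#' reports nothing.
#'
#' @param a_t0,a_t1 [cluster_species] assignments over the same species set.
#' @return data.frame with columns `species_id`, `group_t0`, `group_t1`
#'   (matched into t0 labelling); attribute `ties` flags ambiguous matches.
#' @export
compare_memberships <- function(a_t0, a_t1) {
  g0 <- a_t0$groups; g1 <- a_t1$groups
  if (!setequal(names(g0), names(g1)))
    stop("assignments cover different species sets")
  g1 <- g1[names(g0)]
  labs0 <- sort(unique(g0)); labs1 <- sort(unique(g1))
  jac <- outer(labs1, labs0, Vectorize(function(b, a) {
    A <- names(g0)[g0 == a]; B <- names(g1)[g1 == b]
    length(intersect(A, B)) / length(union(A, B))
  }))
  dimnames(jac) <- list(labs1, labs0)
  map <- stats::setNames(rep(NA, length(labs1)), labs1)
  ties <- FALSE
  free1 <- as.character(labs1); free0 <- as.character(labs0)
  while (length(free1) && length(free0)) {
    sub <- jac[free1, free0, drop = FALSE]
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    if (nrow(hits) > 1) ties <- TRUE
    hit <- hits[order(rownames(sub)[hits[, 1]],
                      colnames(sub)[hits[, 2]])[1], ]
    b <- rownames(sub)[hit[1]]; a <- colnames(sub)[hit[2]]
    map[b] <- a
    free1 <- setdiff(free1, b); free0 <- setdiff(free0, a)
  }
  # unmatched future groups keep their own (new) label
  mapped <- ifelse(is.na(map[as.character(g1)]),
                   paste0("new_", g1), map[as.character(g1)])
  changed <- mapped != as.character(g0)
  out <- data.frame(species_id = names(g0)[changed],
                    group_t0 = as.character(g0)[changed],
                    group_t1 = mapped[changed],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ties") <- ties
  out
}

#' Write a correlation matrix as CSV
#'
#' @param corr a [correlation_matrix] result.
#' @param path output CSV.
#' @export
write_correlation <- function(corr, path) {
  utils::write.csv(as.data.frame(corr$r), path, row.names = TRUE)
  invisible(path)
}

#' Write a community assignment as CSV
#'
#' @param assignment a [cluster_species] result.
#' @param path output CSV.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.csv(
    data.frame(species_id = names(assignment$groups),
               group = unname(assignment$groups),
               time_slice = assignment$time_slice),
    path, row.names = FALSE)
  invisible(path)
}
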