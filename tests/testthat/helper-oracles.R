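# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal formulation of each operation.

# greedy thinning over the full pairwise-distance matrix (planar km)
oracle_thin <- function(records, radius_km) {
  ord <- order(records$species_id, records$catalog_id, records$x, records$y)
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  for (sp in unique(records$species_id)) {
    idx <- which(records$species_id == sp)
    d <- as.matrix(stats::dist(records[idx, c("x", "y")]))
    kept <- integer(0)
    for (k in seq_along(idx)) {
      if (length(kept) == 0 || all(d[k, kept] > radius_km)) kept <- c(kept, k)
    }
    keep[idx[kept]] <- TRUE
  }
  records[keep, , drop = FALSE]
}

# pseudo-absence sites by exhaustive distance check (planar km)
oracle_pa <- function(records, target, radius_km) {
  nt <- unique(records[records$species_id != target, c("x", "y")])
  tg <- records[records$species_id == target, c("x", "y")]
  if (nrow(nt) == 0) return(nt)
  ok <- vapply(seq_len(nrow(nt)), function(i) {
    if (nrow(tg) == 0) return(TRUE)
    d <- sqrt((tg$x - nt$x[i])^2 + (tg$y - nt$y[i])^2)
    all(d > radius_km)
  }, logical(1))
  out <- nt[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# AUC by counting concordant pairs (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# all-pairs inverse-distance weighting at probe locations
oracle_idw <- function(px, py, v, qx, qy, power = 2) {
  vapply(seq_along(qx), function(i) {
    d <- sqrt((px - qx[i])^2 + (py - qy[i])^2)
    if (any(d < 1e-9)) return(v[which.min(d)])
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, numeric(1))
}

# per-cell enumeration of change categories
oracle_partition_counts <- function(a, b) {
  counts <- c(absent = 0, loss = 0, gain = 0, persistence = 0)
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    key <- if (a[i] == 1 && b[i] == 0) "loss"
           else if (a[i] == 0 && b[i] == 1) "gain"
           else if (a[i] == 1 && b[i] == 1) "persistence"
           else "absent"
    counts[key] <- counts[key] + 1
  }
  counts
}

# naive O(n^3) complete-linkage agglomeration; returns merge heights and
# the partition after each merge (as sorted membership signatures)
oracle_agglomerate <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1]] <-
      sort(vapply(clusters, function(cl) paste(sort(cl), collapse = ","),
                  character(1)))
  }
  list(heights = heights, partitions = partitions)
}

# partition signature of a cutree-style membership vector
partition_signature <- function(groups) {
  sort(vapply(split(names(groups), groups),
              function(m) paste(sort(m), collapse = ","), character(1)))
}
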