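test_that("random points are uniform within the mask and reproducible", {
  mask <- make_mask(c(40, 40))
  p1 <- sample_points(mask, 10000, seed = 71)
  p2 <- sample_points(mask, 10000, seed = 71)
  expect_identical(p1, p2)
  expect_equal(nrow(sample_points(mask, 2, seed = 1)), 2)
  # quadrant counts within multinomial 99% bounds
  q <- table(p1$x > 20, p1$y > 20)
  expect_true(all(abs(q - 2500) < stats::qnorm(0.995) *
                    sqrt(10000 * 0.25 * 0.75) + 1))
  empty <- make_mask(c(10, 10)); empty$values[] <- NA
  expect_error(sample_points(empty, 10, seed = 1), "degenerate")
})

test_that("correlations recover identical and complementary surfaces", {
  a <- make_smooth_rio(30, 30, 17, 23, species = "a")
  b <- rio_surface(a$grid, "b", "t0")                      # B = A
  cgrid <- sdm_grid(1 - a$grid$values)                     # C = 1 - A
  cc <- rio_surface(cgrid, "c", "t0")
  pts <- sample_points(make_mask(c(30, 30)), 500, seed = 72)
  corr <- correlation_matrix(pts, list(a, b, cc))
  expect_equal(corr$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(corr$r["a", "c"], -1, tolerance = 1e-12)
  expect_equal(corr$r, t(corr$r))
  expect_equal(unname(diag(corr$r)), rep(1, 3))
})

test_that("Pearson entries match the textbook covariance formula", {
  set.seed(73)
  rios <- lapply(1:3, function(i)
    make_smooth_rio(20, 20, 7 + i, 11 + i, phase = i, species = paste0("s", i)))
  pts <- sample_points(make_mask(c(20, 20)), 100, seed = 74)
  corr <- correlation_matrix(pts, rios)
  vals <- corr$samples
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- vals[, i]; xj <- vals[, j]
    manual <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(corr$r[i, j], manual, tolerance = 1e-12)
  }
})

test_that("zero-variance species are flagged and excluded from clustering", {
  flat <- rio_surface(sdm_grid(matrix(0.4, 20, 20)), "flat", "t0")
  a <- make_smooth_rio(20, 20, 9, 13, species = "a")
  b <- make_smooth_rio(20, 20, 9, 13, phase = 2, species = "b")
  pts <- sample_points(make_mask(c(20, 20)), 200, seed = 75)
  expect_warning(corr <- correlation_matrix(pts, list(a, b, flat)),
                 "zero-variance")
  expect_true(is.na(corr$r["flat", "a"]))
  asg <- cluster_species(corr, n_groups = 2)
  expect_false("flat" %in% names(asg$groups))
})

test_that("pair classification uses the stated boundary rules", {
  r <- matrix(c(1, 0.25, -0.25, 0.25, 1, 0, -0.25, 0, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cls <- classify_pairs(r)
  get <- function(s1, s2) cls$class[cls$species_a == s1 & cls$species_b == s2]
  expect_equal(get("a", "b"), "co_occurring")   # r = 0.25 inclusive
  expect_equal(get("a", "c"), "neutral")        # r = -0.25 not < -0.25
  expect_equal(get("b", "c"), "neutral")
  r["a", "c"] <- r["c", "a"] <- -0.26
  expect_equal(classify_pairs(r)$class[2], "exclusive")
})

test_that("planted correlation blocks are recovered exactly", {
  set.seed(76)
  base1 <- make_smooth_rio(40, 40, 13, 19, species = "x")$grid$values
  base2 <- make_smooth_rio(40, 40, 23, 7, phase = 1.3,
                           species = "x")$grid$values
  jitter_rio <- function(base, sp) {
    v <- pmin(pmax(base + matrix(rnorm(1600, 0, 0.02), 40, 40), 0), 1)
    rio_surface(sdm_grid(v), sp, "t0")
  }
  rios <- c(lapply(paste0("A", 1:3), function(s) jitter_rio(base1, s)),
            lapply(paste0("B", 1:3), function(s) jitter_rio(base2, s)))
  pts <- sample_points(make_mask(c(40, 40)), 2000, seed = 77)
  corr <- correlation_matrix(pts, rios)
  asg <- cluster_species(corr, n_groups = 2)
  expect_equal(length(unique(asg$groups[paste0("A", 1:3)])), 1)
  expect_equal(length(unique(asg$groups[paste0("B", 1:3)])), 1)
  expect_false(asg$groups[["A1"]] == asg$groups[["B1"]])
})

test_that("identical surfaces merge at height zero into one group", {
  a <- make_smooth_rio(20, 20, 9, 13, species = "a")
  clones <- lapply(c("a", "b", "c"), function(s)
    rio_surface(a$grid, s, "t0"))
  pts <- sample_points(make_mask(c(20, 20)), 300, seed = 78)
  corr <- correlation_matrix(pts, clones)
  asg <- cluster_species(corr, height = 0)
  expect_equal(length(unique(asg$groups)), 1)
  expect_true(all(asg$tree$height < 1e-12))
})

test_that("the merge sequence matches a brute-force agglomeration oracle", {
  # hand-built 4x4 dissimilarity with distinct merge heights
  rho <- matrix(c(1, 0.9, 0.2, 0.1,
                  0.9, 1, 0.3, 0.2,
                  0.2, 0.3, 1, 0.8,
                  0.1, 0.2, 0.8, 1), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  corr <- structure(list(species = letters[1:4], r = rho, rho = rho,
                         degenerate = character(0)),
                    class = "rio_correlation")
  asg <- cluster_species(corr, n_groups = 2)
  d <- 1 - rho^2
  oracle <- oracle_agglomerate(d)
  expect_equal(sort(asg$tree$height), sort(oracle$heights),
               tolerance = 1e-12)
  for (k in 1:3) {
    groups <- stats::cutree(asg$tree, k = k)
    names(groups) <- as.character(match(names(groups), letters[1:4]))
    expect_equal(unname(partition_signature(groups)),
                 oracle$partitions[[4 - k]])
  }
  expect_error(cluster_species(corr, n_groups = 9), "exceeds")
})

test_that("membership comparison ignores relabelling and finds real moves", {
  mk <- function(groups, slice) structure(
    list(groups = groups, tree = NULL, time_slice = slice),
    class = "community_assignment")
  g0 <- c(a = 1, b = 1, c = 2, d = 2, e = 2)
  # identical assignment: nothing to report
  expect_equal(nrow(compare_memberships(mk(g0, "t0"), mk(g0, "t1"))), 0)
  # full relabelling of the same partition: nothing to report
  g1 <- c(a = 2, b = 2, c = 1, d = 1, e = 1)
  expect_equal(nrow(compare_memberships(mk(g0, "t0"), mk(g1, "t1"))), 0)
  # one species swapped between otherwise stable groups
  g2 <- c(a = 1, b = 2, c = 2, d = 2, e = 2)
  moved <- compare_memberships(mk(g0, "t0"), mk(g2, "t1"))
  expect_equal(moved$species_id, "b")
  expect_equal(moved$group_t0, "1")
  expect_equal(moved$group_t1, "2")
  # label invariance under permutation of the future labels
  g2_relab <- c(a = 7, b = 3, c = 3, d = 3, e = 3)
  moved2 <- compare_memberships(mk(g0, "t0"), mk(g2_relab, "t1"))
  expect_equal(moved2$species_id, "b")
})

test_that("correlation sampling converges to the full-raster value", {
  for (s in 1:5) {
    set.seed(80 + s)
    r1 <- make_smooth_rio(100, 100, 31 + s, 43, species = "a")
    r2 <- make_smooth_rio(100, 100, 23, 37 + s, phase = 0.7, species = "b")
    pts <- sample_points(make_mask(c(100, 100)), 50000, seed = 90 + s)
    corr <- correlation_matrix(pts, list(r1, r2))
    full <- stats::cor(as.vector(r1$grid$values),
                       as.vector(r2$grid$values))
    expect_lt(abs(corr$r["a", "b"] - full), 0.01)
  }
})
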