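test_that("the lattice spans the mask bounding box inclusively", {
  mask <- make_mask(c(100, 100), res = 1)
  lat <- build_lattice(mask, 5)
  expect_equal(nrow(lat$points), 21 * 21)
  expect_equal(range(lat$points$x), c(0, 100))
  expect_equal(range(lat$points$y), c(0, 100))
})

test_that("lattice points outside the mask are dropped", {
  mask <- make_mask(c(100, 100), res = 1)
  mask$values[51:100, 51:100] <- NA       # L-shape: NE block removed
  lat <- build_lattice(mask, 5)
  ne <- lat$points$x > 50 & lat$points$y > 50
  expect_false(any(ne))
  expect_lt(nrow(lat$points), 441)
})

test_that("a spacing larger than the mask is refused", {
  expect_error(build_lattice(make_mask(c(10, 10)), 20), "spacing")
})

test_that("time-slice attachment checks static identity and alignment", {
  scen <- synthetic_scenario(extent_km = c(40, 40), drift_km = 5, seed = 2)
  L <- make_landscape(scen)
  mask <- make_mask(c(40, 40))
  lat <- build_lattice(mask, 5)
  lat <- attach_timeslice(lat, L$t0, L$t1)
  static <- names(L$t0$layers)[L$t0$temporal == "static"]
  for (nm in static)
    expect_identical(lat$cov$t0[[nm]], lat$cov$t1[[nm]])

  # a static layer that changed is an error naming the layer
  broken <- L$t1
  broken$layers$elevation$values <- broken$layers$elevation$values + 1
  expect_error(attach_timeslice(build_lattice(mask, 5), L$t0, broken),
               "elevation")

  # misaligned grids are an error
  shifted <- L$t1
  shifted$layers <- lapply(shifted$layers, function(g) {
    g$xmin <- g$xmin + 0.5; g
  })
  expect_error(attach_timeslice(build_lattice(mask, 5), L$t0, shifted),
               "aligned")
})

test_that("a purely dynamic offset changes exactly one covariate component", {
  g <- sdm_grid(matrix(runif(100), 10, 10))
  g2 <- sdm_grid(g$values + 2, g$xmin, g$ymin, g$res)
  s <- sdm_grid(matrix(5, 10, 10))
  st0 <- covariate_stack(list(dyn = g, sta = s),
                         temporal = c("dynamic", "static"))
  st1 <- covariate_stack(list(dyn = g2, sta = s),
                         temporal = c("dynamic", "static"),
                         time_slice = "t1")
  lat <- attach_timeslice(build_lattice(make_mask(c(10, 10)), 5), st0, st1)
  expect_equal(lat$cov$t1$dyn - lat$cov$t0$dyn,
               rep(2, nrow(lat$points)))
  expect_identical(lat$cov$t0$sta, lat$cov$t1$sta)
})

test_that("RIO is high inside and low outside the trained envelope", {
  # one gradient layer; presences in the south band, absences in the north
  vals <- matrix(rep(1:40, 40), 40, 40)   # value = row index (northing)
  stack <- covariate_stack(list(grad = sdm_grid(vals)), temporal = "dynamic")
  set.seed(41)
  pres <- data.frame(x = runif(150, 0, 40), y = runif(150, 1, 10))
  abs <- data.frame(x = runif(150, 0, 40), y = runif(150, 30, 39))
  train <- assemble_training("sp", pres, abs, stack)
  model <- fit_envelope(train, seed = 3)
  mask <- make_mask(c(40, 40))
  lat <- attach_timeslice(build_lattice(mask, 5), stack, stack)
  rio <- predict_rio(model, lat, "t0")
  deep_in <- lat$points$y <= 5
  deep_out <- lat$points$y >= 35
  expect_true(all(rio[deep_in] >= 0.9))
  expect_true(all(rio[deep_out] <= 0.1))
  expect_true(all(rio >= 0 & rio <= 1))
  # identical covariate vectors give identical RIO
  south_row <- lat$points$y == 0          # same gradient value at every x
  expect_equal(length(unique(rio[south_row])), 1)
})

test_that("unseen categorical labels are routed to the largest category", {
  soil0 <- sdm_grid(matrix(rep(c(1, 1, 2), length.out = 100), 10, 10))
  soil1 <- sdm_grid(matrix(3, 10, 10))
  st0 <- covariate_stack(list(soil = soil0), temporal = "dynamic",
                         type = "categorical",
                         levels = list(soil = c("peat", "gravel")))
  st1 <- covariate_stack(list(soil = soil1), temporal = "dynamic",
                         type = "categorical",
                         levels = list(soil = c("peat", "gravel", "karst")),
                         time_slice = "t1")
  set.seed(43)
  pres <- data.frame(x = runif(60, 0, 10), y = runif(60, 0, 10))
  abs <- data.frame(x = runif(60, 0, 10), y = runif(60, 0, 10))
  train <- assemble_training("sp", pres, abs, st0)
  # karst never seen at training: registry carries it, the fit does not
  model <- fit_envelope(train, seed = 2)
  lat <- attach_timeslice(build_lattice(make_mask(c(10, 10)), 5), st0, st1)
  expect_message(rio <- predict_rio(model, lat, "t1"), "routed")
  expect_true(all(is.finite(rio)))
})

test_that("IDW reproduces the all-pairs oracle and its invariants", {
  set.seed(44)
  pts <- data.frame(x = runif(25, 0, 20), y = runif(25, 0, 20))
  v <- runif(25)
  mask <- make_mask(c(20, 20))
  surf <- smooth_idw(pts, v, mask, resolution_km = 2, power = 2,
                     n_neighbors = 25)    # k = n: oracle uses all pairs
  ctr <- grid_centers(surf)
  probe <- expand.grid(col = seq(1, 10, by = 3), row = seq(1, 10, by = 3))
  for (i in seq_len(nrow(probe))) {
    qx <- ctr$x[probe$col[i]]; qy <- ctr$y[probe$row[i]]
    expect_equal(surf$values[probe$row[i], probe$col[i]],
                 oracle_idw(pts$x, pts$y, v, qx, qy),
                 tolerance = 1e-10)
  }
  # convex combination: bounded by the input range
  expect_gte(min(surf$values, na.rm = TRUE), min(v))
  expect_lte(max(surf$values, na.rm = TRUE), max(v))
})

test_that("IDW is exact at lattice points and symmetric between two", {
  # points on cell centres of a 1-km grid
  pts <- data.frame(x = c(2.5, 6.5), y = c(2.5, 2.5))
  v <- c(0, 1)
  mask <- make_mask(c(9, 5))
  surf <- smooth_idw(pts, v, mask, resolution_km = 1, n_neighbors = 2)
  expect_equal(grid_extract(surf, 2.5, 2.5), 0)
  expect_equal(grid_extract(surf, 6.5, 2.5), 1)
  expect_equal(grid_extract(surf, 4.5, 2.5), 0.5)  # midway cell centre
  # constant input gives a constant surface
  flat <- smooth_idw(pts, c(0.3, 0.3), mask, resolution_km = 1)
  expect_true(all(abs(flat$values - 0.3) < 1e-12, na.rm = TRUE))
})

test_that("the smoothed surface is masked like the study area", {
  mask <- make_mask(c(10, 10))
  mask$values[1:5, 1:5] <- NA
  pts <- data.frame(x = c(2, 8), y = c(2, 8))
  surf <- smooth_idw(pts, c(0, 1), mask, resolution_km = 1)
  expect_true(all(is.na(surf$values[1:5, 1:5])))
  expect_true(all(!is.na(surf$values[6:10, 6:10])))
})
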