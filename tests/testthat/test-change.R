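test_that("binarization uses an inclusive threshold and keeps no-data", {
  m <- matrix(c(0.5, 0.49999, NA, 0.7), 2, 2)
  b <- binarize(rio_surface(sdm_grid(m), "sp", "t0"))
  expect_equal(b$grid$values[1, 1], 1)   # RIO exactly 0.5 is presence
  expect_equal(b$grid$values[2, 1], 0)
  expect_true(is.na(b$grid$values[1, 2]))
  all_na <- binarize(rio_surface(sdm_grid(matrix(NA_real_, 2, 2)), "s", "t0"))
  expect_true(all(is.na(all_na$grid$values)))
})

test_that("change partition handles the identity and complement cases", {
  m <- random_binary_matrix(10, 10)
  b <- make_range(m)
  same <- change_counts(change_partition(b, make_range(m, slice = "t1")))
  expect_equal(unname(same["loss"] + same["gain"]), 0)
  expect_equal(unname(same["persistence"]), sum(m == 1))
  flip <- change_counts(change_partition(b, make_range(1 - m, slice = "t1")))
  expect_equal(unname(flip["persistence"] + flip["absent"]), 0)
})

test_that("change categories match the per-cell oracle and partition the map", {
  set.seed(51)
  for (rep in 1:5) {
    a <- random_binary_matrix(20, 20, 0.4)
    b <- random_binary_matrix(20, 20, 0.6)
    a[1, 1] <- NA
    counts <- change_counts(change_partition(make_range(a),
                                             make_range(b, slice = "t1")))
    expect_equal(counts, oracle_partition_counts(a, b))
    expect_equal(sum(counts), sum(!is.na(a)))
  }
  expect_error(change_partition(make_range(random_binary_matrix(5, 5)),
                                make_range(random_binary_matrix(6, 6))),
               "aligned")
})

test_that("identical ranges have zero deltas and zero rates", {
  m <- random_binary_matrix(20, 20)
  flat <- sdm_grid(matrix(100, 20, 20))
  sm <- shift_metrics(make_range(m), make_range(m, slice = "t1"),
                      flat, flat)
  expect_equal(sm$d_latitude_km, 0)
  expect_equal(sm$d_elevation_m, 0)
  expect_equal(sm$d_coast_km, 0)
  expect_equal(sm$rate_latitude_km_decade, 0)
  expect_equal(sm$net_change_km2, 0)
})

test_that("a pure northward translation is recovered exactly", {
  m0 <- matrix(0, 100, 30); m0[11:20, ] <- 1    # band at y 10-20
  m1 <- matrix(0, 100, 30); m1[61:70, ] <- 1    # band at y 60-70
  flat <- sdm_grid(matrix(0, 100, 30))
  sm <- shift_metrics(make_range(m0), make_range(m1, slice = "t1"),
                      flat, flat)
  expect_equal(sm$d_latitude_km, 50)
  expect_equal(sm$rate_latitude_km_decade, 50 / 9, tolerance = 1e-12)
  expect_equal(sm$d_elevation_m, 0)
})

test_that("a -25 km latitude shift is -2.8 km per decade", {
  tab <- add_decadal_rates(data.frame(d_latitude_km = -25,
                                      d_coast_km = 14.7,
                                      d_elevation_m = 46.3))
  expect_equal(round(tab$rate_latitude_km_decade, 1), -2.8)
  expect_equal(round(tab$rate_coast_km_decade, 1), 1.6)
  expect_equal(round(tab$rate_elevation_m_decade, 1), 5.1)
})

test_that("area bookkeeping and translation equivariance hold on random maps", {
  set.seed(52)
  for (rep in 1:10) {
    a <- random_binary_matrix(30, 30, runif(1, 0.2, 0.8))
    b <- random_binary_matrix(30, 30, runif(1, 0.2, 0.8))
    elev <- sdm_grid(matrix(runif(900, 0, 1000), 30, 30))
    coast <- sdm_grid(matrix(runif(900, 0, 50), 30, 30))
    sm <- shift_metrics(make_range(a), make_range(b, slice = "t1"),
                        elev, coast)
    expect_equal(sm$area_t1_km2,
                 sm$area_t0_km2 - sm$loss_km2 + sm$gain_km2)
    expect_equal(sm$net_change_km2, sm$area_t1_km2 - sm$area_t0_km2)
    # translating both ranges (and terrain) leaves every delta unchanged
    shift_grid <- function(g, dy) sdm_grid(g$values, g$xmin, g$ymin + dy,
                                           g$res)
    a2 <- make_range(a); a2$grid <- shift_grid(a2$grid, 17)
    b2 <- make_range(b, slice = "t1"); b2$grid <- shift_grid(b2$grid, 17)
    sm2 <- shift_metrics(a2, b2, shift_grid(elev, 17),
                         shift_grid(coast, 17))
    expect_equal(sm2$d_latitude_km, sm$d_latitude_km)
    expect_equal(sm2$d_elevation_m, sm$d_elevation_m)
    expect_equal(sm2$d_coast_km, sm$d_coast_km)
  }
})

test_that("adding only northern presence pixels cannot pull the median south", {
  set.seed(53)
  m0 <- matrix(0, 40, 10); m0[5:20, ] <- 1
  m1 <- m0
  flat <- sdm_grid(matrix(0, 40, 10))
  base <- shift_metrics(make_range(m0), make_range(m1, slice = "t1"),
                        flat, flat)$d_latitude_km
  m1[30:34, 1:5] <- 1                     # extra pixels strictly north
  more <- shift_metrics(make_range(m0), make_range(m1, slice = "t1"),
                        flat, flat)$d_latitude_km
  expect_gte(more, base)
})

test_that("empty presence sets flag the metrics undefined, not zero", {
  m0 <- matrix(0, 10, 10); m0[3, 3] <- 1
  empty <- matrix(0, 10, 10)
  flat <- sdm_grid(matrix(0, 10, 10))
  expect_warning(
    sm <- shift_metrics(make_range(m0), make_range(empty, slice = "t1"),
                        flat, flat),
    "undefined")
  expect_true(is.na(sm$d_latitude_km))
  expect_true(is.na(sm$rate_latitude_km_decade))
})

test_that("community aggregation reproduces hand-computed means", {
  pub <- published_change_metrics()
  cold <- pub[pub$community == "cold-climate", ]
  agg <- community_aggregate(cold, cols = "pct_change")
  expect_equal(agg$groups$pct_change, mean(c(-6.0, -4.3, -4.8, -19.7)))
  expect_equal(agg$groups$pct_change, -8.7)
  # single-species community: the mean is that species' value
  one <- pub[pub$species_id == "Sorex hoyi", ]
  expect_equal(community_aggregate(one, cols = "pct_change")$groups$pct_change,
               3.5)
})

test_that("union means and exclusions are supported", {
  pub <- published_change_metrics()
  agg <- community_aggregate(
    pub, cols = "pct_change",
    unions = list(declining = c("cold-climate", "interior", "northern")))
  expect_equal(round(agg$unions$pct_change, 1), -20.2)
  excl <- community_aggregate(pub[pub$community == "southern", ],
                              cols = "d_elevation_m",
                              exclude = "Zapus hudsonius")
  expect_equal(round(excl$groups$d_elevation_m, 1), -74.4)
})

test_that("unassigned species abort aggregation", {
  df <- data.frame(species_id = c("a", "b"), community = c("x", NA),
                   v = c(1, 2))
  expect_error(community_aggregate(df, cols = "v"), "b")
})
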