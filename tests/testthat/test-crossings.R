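# Crossing detection, the common polygon, null-path generation, width
# binning and the chi-square barrier test.

test_that("crossing detection matches an exhaustive strip-interval oracle", {
  # three vertical channels; strips [950,1050], [1975,2025], [2900,3100]
  ch <- vertical_channels(c(1000, 2000, 3000), c(100, 50, 200))
  # path zig-zagging: crosses ch1, back over ch1, then through ch2 and ch3
  x <- c(500, 1500, 700, 1600, 2500, 3500)
  y <- c(0, 100, 200, 300, 400, 500)
  p <- fixture_daily_path(x, y)
  recs <- detect_crossings(p, ch)
  # oracle: per segment, test x-interval overlap with each strip
  strips <- cbind(lo = c(950, 1975, 2900), hi = c(1050, 2025, 3100))
  oracle <- 0
  for (s in 1:(length(x) - 1)) for (k in 1:3) {
    if (min(x[s], x[s + 1]) <= strips[k, "hi"] &&
        max(x[s], x[s + 1]) >= strips[k, "lo"]) oracle <- oracle + 1
  }
  expect_equal(nrow(recs), oracle)
  expect_equal(oracle, 5)
  expect_equal(sort(table(recs$channel_id), decreasing = TRUE)[[1]], 3)
  # a land-locked path yields nothing
  none <- detect_crossings(fixture_daily_path(c(0, 100, 200), c(0, 50, 0)),
                           ch)
  expect_equal(nrow(none), 0)
  # re-entering the same channel later in the day counts again
  reent <- detect_crossings(fixture_daily_path(c(500, 1500, 500), c(0, 0, 0)),
                            ch)
  expect_equal(nrow(reent), 2)
})

test_that("the common polygon is the exact hull of pooled fixes", {
  set.seed(19)
  t1 <- fixture_trajectory(runif(30, 0, 1000), runif(30, 0, 1000),
                           animal_id = "A")
  t2 <- fixture_trajectory(runif(30, 2000, 3000), runif(30, 0, 1000),
                           animal_id = "B")
  poly <- common_polygon(list(t1, t2))
  xy <- rbind(as.matrix(t1$fixes[, c("x_m", "y_m")]),
              as.matrix(t2$fixes[, c("x_m", "y_m")]))
  hull <- xy[grDevices::chull(xy), ]
  expect_equal(mangrovemove:::polygon_area(poly), oracle_area(hull))
  # pooled hull contains every individual hull vertex
  h1 <- compute_mcp(t1, percent = 100)$polygon
  expect_true(all(mangrovemove:::point_in_convex(h1[, 1], h1[, 2], poly)))
  # one animal alone: identical to its 100% MCP area
  p1 <- common_polygon(list(t1))
  expect_equal(mangrovemove:::polygon_area(p1) / 1e6,
               compute_mcp(t1, percent = 100)$area_km2)
  expect_error(common_polygon(fixture_trajectory(c(0, 1), c(0, 1))),
               "at least 3")
})

test_that("null paths honor step counts, bounds and constraints", {
  set.seed(41)
  land <- list(raster = uniform_raster(2, n = 60, cell = 100),
               channels = mangrovemove:::empty_channel_set())
  obs <- fixture_daily_path(cumsum(c(3000, rnorm(14, 0, 300))),
                            cumsum(c(3000, rnorm(14, 0, 300))))
  poly <- cbind(c(0, 6000, 6000, 0), c(0, 0, 6000, 6000))
  paths <- generate_null_paths(obs, n = 5, polygon = poly, landscape = land,
                               seed = 1)
  expect_length(paths, 5)
  steps_obs <- sqrt(diff(obs$fixes$x_m)^2 + diff(obs$fixes$y_m)^2)
  for (p in paths) {
    expect_equal(nrow(p), nrow(obs$fixes))
    expect_equal(p[1, 1], obs$fixes$x_m[1])
    len <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    expect_true(all(len >= min(steps_obs) - 1e-9 &
                      len <= max(steps_obs) + 1e-9))
    expect_true(all(mangrovemove:::point_in_convex(p[, 1], p[, 2], poly)))
  }
  expect_length(generate_null_paths(obs, n = 0, polygon = poly), 0)
  # impossible constraints fail loudly, or return partial sets when allowed
  tiny <- cbind(c(2995, 3005, 3005, 2995), c(2995, 2995, 3005, 3005))
  expect_error(generate_null_paths(obs, n = 1, polygon = tiny,
                                   max_attempts = 50),
               "rejection sampling failed")
  part <- generate_null_paths(obs, n = 3, polygon = tiny, max_attempts = 50,
                              allow_partial = TRUE)
  expect_length(part, 0)
})

test_that("null paths are reproducible under a fixed seed", {
  obs <- fixture_daily_path(c(0, 400, 800, 400), c(0, 200, 0, -200))
  poly <- cbind(c(-5000, 5000, 5000, -5000), c(-5000, -5000, 5000, 5000))
  a <- generate_null_paths(obs, n = 3, polygon = poly, seed = 7)
  b <- generate_null_paths(obs, n = 3, polygon = poly, seed = 7)
  expect_identical(a, b)
})

test_that("width bins are half-open 50 m intervals then 500 m intervals", {
  edges <- default_width_edges(2500)
  recs <- data.frame(path_id = "p", channel_id = "c",
                     width_m = c(54, 49.9, 50, 999.9, 1000, 1499, 1500, 2500),
                     source = "observed")
  recs <- rbind(recs, transform(recs, source = "null"))
  tab <- bin_crossings(recs, edges = edges)
  at <- function(w) which(tab$bin_lo <= w & tab$bin_hi > w)
  expect_equal(tab$bin_lo[at(54)], 50)
  expect_equal(tab$observed[at(54)], 2)       # [50, 100) holds 54 and 50
  expect_equal(tab$observed[at(49.9)], 1)     # [0, 50) holds only 49.9
  expect_equal(tab$bin_lo[at(1000)], 1000)    # exact 1000 -> [1000, 1500)
  expect_equal(tab$observed[at(1000)], 2)     # 1000 and 1499
  expect_equal(tab$observed[at(999)], 1)      # 999.9 in [950, 1000)
  expect_equal(tab$observed[at(1600)], 1)     # 1500 in [1500, 2000)
  expect_warning(bin_crossings(recs, edges = c(0, 100, 200)), "extending")
})

test_that("the chi-square test matches hand computations and conserves totals", {
  tab <- structure(data.frame(bin_lo = c(0, 50), bin_hi = c(50, 100),
                              observed = c(10, 0), availability = c(1, 1)),
                   class = c("width_bin_table", "data.frame"))
  ct <- crossing_chisq(tab, min_expected = 0)
  expect_equal(ct$chi_square, 10)
  expect_equal(ct$df, 1)
  expect_equal(sum(ct$merged$expected), sum(ct$merged$observed))
  # observed proportional to availability: statistic is exactly zero
  tab2 <- structure(data.frame(bin_lo = c(0, 50, 100),
                               bin_hi = c(50, 100, 150),
                               observed = c(10, 20, 30),
                               availability = c(5, 10, 15)),
                    class = c("width_bin_table", "data.frame"))
  expect_equal(crossing_chisq(tab2)$chi_square, 0)
  expect_error(crossing_chisq(structure(
    data.frame(bin_lo = 0, bin_hi = 50, observed = 5, availability = 3),
    class = c("width_bin_table", "data.frame"))), "at least 2 bins")
})

test_that("bins with tiny expected counts are merged into neighbors", {
  tab <- structure(data.frame(bin_lo = c(0, 50, 100, 150),
                              bin_hi = c(50, 100, 150, 200),
                              observed = c(50, 45, 4, 1),
                              availability = c(50, 45, 1, 1)),
                   class = c("width_bin_table", "data.frame"))
  ct <- crossing_chisq(tab, min_expected = 5)
  expect_true(all(ct$merged$expected >= 5))
  expect_equal(sum(ct$merged$observed), 100)
  expect_equal(ct$df, nrow(ct$merged) - 1)
})

test_that("crossings per day average over screened days including zeros", {
  recs <- data.frame(path_id = c("d1", "d1", "d2"), channel_id = "c",
                     width_m = 50, source = "observed")
  out <- crossings_per_day(recs, n_days = 3)
  expect_equal(out$mean, 1)
})

test_that("with planted reluctance wide channels are crossed below availability", {
  rep <- barrier_test_replicate(31, crossing_halfwidth = 150, n_days = 50)
  expect_lt(rep$p, 0.05)
})

test_that("crossing frequency falls off for wide channels while availability does not", {
  # two vertical channels, 50 m and 450 m wide, flanking the home center;
  # reluctance half-width 150 m suppresses the wide one ~8x more per attempt
  land <- list(raster = uniform_raster(2, n = 200, cell = 50),
               channels = vertical_channels(c(4000, 6000), c(50, 450)))
  vals <- land$raster$values
  xc <- (seq_len(200) - 0.5) * 50
  inw <- matrix(point_in_channels(rep(xc, each = 200), rep(xc, times = 200),
                                  land$channels), 200)
  vals[inw] <- 1L
  land$raster <- fixture_raster(vals, cell = 50)
  home <- nearest_land(land$raster, 5000, 5000)
  spec <- tiger_sim_spec(home_center = home, attraction_strength = 0.1,
                         step_scale = 550, turning_concentration = 0,
                         habitat_weights = c(Water = 1e-9, Phoenix = 1,
                                             Ceriops = 1, Barren = 1,
                                             AvicSonn = 1),
                         crossing_halfwidth = 150,
                         activity_profile = rep(1, 24),
                         fix_success_prob = 1, duration_days = 80, seed = 9)
  sim <- simulate_tiger(spec, land)
  days <- Filter(function(p) p$usable,
                 assemble_daily_paths(sim$trajectory, min_fixes = 12))
  poly <- common_polygon(sim$trajectory)
  obs <- do.call(rbind, lapply(days, detect_crossings,
                               channels = land$channels))
  set.seed(10)
  nul <- list()
  for (i in seq_along(days)) {
    paths <- generate_null_paths(days[[i]], n = 5, polygon = poly,
                                 landscape = land, allow_partial = TRUE)
    for (j in seq_along(paths))
      nul[[length(nul) + 1L]] <- detect_crossings(
        paths[[j]], land$channels, path_id = paste0("n", i, "_", j),
        source = "null")
  }
  nul <- do.call(rbind, nul)
  ratio <- function(recs, id) sum(recs$channel_id == id)
  # availability reaches the wide channel, but the tiger rarely crosses it
  expect_gt(ratio(nul, "ch2"), 0)
  obs_ratio <- ratio(obs, "ch2") / max(1, ratio(obs, "ch1"))
  nul_ratio <- ratio(nul, "ch2") / max(1, ratio(nul, "ch1"))
  expect_lt(obs_ratio, nul_ratio)
})
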