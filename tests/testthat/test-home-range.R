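# MCP and fixed-kernel home ranges, isopleths, core detection, masking,
# asymptote curves, summaries and the density extrapolation.

test_that("the 100% MCP of a right triangle is half a square kilometer", {
  m <- compute_mcp(cbind(c(0, 0, 1000), c(0, 1000, 0)), percent = 100)
  expect_equal(m$area_km2, 0.5)
  expect_equal(m$level, 100)
  expect_false(m$water_masked)
})

test_that("degenerate point sets are rejected or flagged", {
  expect_error(compute_mcp(cbind(c(0, 0), c(0, 1)), percent = 100),
               "at least 3 distinct")
  expect_error(compute_mcp(cbind(rep(5, 10), rep(5, 10)), percent = 100),
               "at least 3 distinct")
  expect_warning(m <- compute_mcp(cbind(1:5 * 100, 1:5 * 100), percent = 100),
                 "collinear")
  expect_equal(m$area_km2, 0)
  expect_true(m$degenerate)
})

test_that("percentage MCPs match the brute-force trim-and-hull oracle", {
  set.seed(31)
  for (rep in 1:5) {
    xy <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
    m <- compute_mcp(xy, percent = 95)
    # oracle: sort by centroid distance, drop ceil(5%), exact hull area
    d <- (xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2
    keep <- xy[order(d)[1:(200 - ceiling(0.05 * 200))], ]
    hull <- keep[grDevices::chull(keep), ]
    expect_equal(m$area_km2, oracle_area(hull) / 1e6, tolerance = 1e-9)
    # and the 100% hull against the exact oracle
    m100 <- compute_mcp(xy, percent = 100)
    hull100 <- xy[grDevices::chull(xy), ]
    expect_equal(m100$area_km2, oracle_area(hull100) / 1e6, tolerance = 1e-9)
  }
})

test_that("kernel UDs integrate to one and respect the cell-size guard", {
  set.seed(5)
  xy <- cbind(runif(30, 0, 3000), runif(30, 0, 3000))
  ud <- compute_fixed_kernel_ud(xy, h = 1000)
  expect_equal(sum(ud$density) * ud$cell^2, 1, tolerance = 1e-6)
  expect_error(compute_fixed_kernel_ud(xy, h = 1000, cell = 500),
               "too coarse")
})

test_that("single-fix isopleth areas match the bivariate normal closed form", {
  ud <- compute_fixed_kernel_ud(cbind(0, 0), h = 1000, cell = 100)
  prof <- extract_isopleths(ud, levels = c(50, 75, 95))
  closed <- function(p) -2 * log(1 - p / 100) * pi * 1e6 / 1e6  # km2 at h=1km
  for (i in 1:3)
    expect_equal(prof$area_km2[i], closed(prof$level[i]), tolerance = 0.02)
})

test_that("two distant fixes carry equal mass in two modes", {
  ud <- compute_fixed_kernel_ud(cbind(c(0, 20000), c(0, 0)), h = 1000,
                                cell = 250)
  nx <- ncol(ud$density)
  xc <- ud$xmin + (seq_len(nx) - 0.5) * ud$cell
  left <- sum(ud$density[, xc < 10000]) * ud$cell^2
  expect_equal(left, 0.5, tolerance = 1e-3)
})

test_that("isopleth areas are nondecreasing and uniform UDs scale linearly", {
  set.seed(6)
  xy <- cbind(rnorm(40, 0, 800), rnorm(40, 0, 800))
  prof <- extract_isopleths(compute_fixed_kernel_ud(xy, h = 1000))
  expect_true(all(diff(prof$area_km2) >= 0))
  # hand-built uniform UD on a 10 km2 island: area(p) ~ p/100 * 10
  vals <- matrix(0, 50, 50)
  vals[11:30, 11:35] <- 1  # 500 cells of 100 m x 200 m? no: cell 141.42 m
  cell <- sqrt(10e6 / 500)  # 500 cells totalling 10 km2
  vals <- vals / (500 * cell^2)
  ud <- structure(list(xmin = 0, ymin = 0, cell = cell, density = vals,
                       h = NA, n_fixes = NA),
                  class = "utilization_distribution")
  prof <- extract_isopleths(ud, levels = seq(10, 90, 10))
  expect_equal(prof$area_km2, prof$level / 100 * 10, tolerance = 0.02)
})

test_that("water masking removes only channels wider than the cutoff", {
  # 2 km x 2 km square home range; vertical channel of width 1500 covering
  # its right half; a 900 m channel elsewhere must not be subtracted
  sq <- compute_mcp(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)),
                    percent = 100)
  wide <- vertical_channels(1750, 1500)   # strip x in [1000, 2500]
  half <- mask_water(sq, wide)
  expect_equal(half$area_km2, sq$area_km2 / 2, tolerance = 1e-9)
  expect_true(half$water_masked)
  narrow <- vertical_channels(1000, 900)
  same <- mask_water(sq, narrow)
  expect_equal(same$area_km2, sq$area_km2)
  # fully-on-land polygon unchanged by a distant wide channel
  far <- vertical_channels(50000, 2000)
  expect_equal(mask_water(sq, far)$area_km2, sq$area_km2)
})

test_that("water masking of kernel ranges drops the flooded cells", {
  set.seed(8)
  xy <- cbind(runif(50, 0, 2000), runif(50, 0, 2000))
  hr <- fk_home_range(compute_fixed_kernel_ud(xy, h = 1000), level = 95)
  wide <- vertical_channels(1000, 1200)
  masked <- mask_water(hr, wide)
  expect_lt(masked$area_km2, hr$area_km2)
  expect_true(masked$water_masked)
})

test_that("asymptote curves are monotone for full hulls and flag stabilization", {
  set.seed(12)
  xy <- cbind(runif(400, 0, 3000), runif(400, 0, 3000))  # stationary, bounded
  cur <- asymptote_curve(xy, step = 50, estimator = "MCP", percent = 100)
  expect_true(all(diff(cur$area_km2) >= -1e-12))
  expect_false(is.na(attr(cur, "asymptote_n")))
  short <- asymptote_curve(xy[1:60, ], step = 50)
  expect_equal(nrow(short), 1)
  expect_true(is.na(attr(short, "asymptote_n")))
  expect_error(asymptote_curve(xy[1:30, ], step = 50), "at least 50")
})

test_that("core detection finds a planted mass boundary and ignores scale", {
  # tight core holding 75% of mass, diffuse background holding 25%
  vals <- matrix(0, 100, 100)
  vals[48:52, 48:52] <- 0.75 / (25 * 100^2)
  bg <- which(vals == 0)
  vals[bg] <- 0.25 / (length(bg) * 100^2)
  ud <- structure(list(xmin = 0, ymin = 0, cell = 100, density = vals,
                       h = NA, n_fixes = NA),
                  class = "utilization_distribution")
  prof <- extract_isopleths(ud)
  lvl <- detect_core_isopleth(prof)
  expect_lte(abs(lvl - 75), 5)
  # invariance under uniform rescaling of all areas
  prof2 <- prof
  prof2$area_km2 <- prof2$area_km2 * 37.5
  expect_equal(detect_core_isopleth(prof2), lvl)
  # linear profile carries no inflection
  lin <- data.frame(level = seq(5, 95, 5), area_km2 = seq(5, 95, 5) * 0.3)
  expect_true(is.na(detect_core_isopleth(lin)))
})

test_that("home-range summaries average the non-excluded animals by sex", {
  tab <- data.frame(
    animal_id = c("7825M", "7831M", "10250F", "RCF", "7224M", "7825F"),
    sex = c("M", "M", "F", "F", "M", "F"),
    estimator = "FK", level = 95,
    area_km2 = c(60.97, 159.09, 62.17, 50.80, 68.7, 191.31),
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    exclude_reason = c("", "", "", "", "too few tracking days", "transient"))
  out <- summarize_home_ranges(tab)
  f <- out$summary[out$summary$sex == "F", ]
  m <- out$summary[out$summary$sex == "M", ]
  expect_equal(f$mean_km2, 56.49)
  expect_equal(f$se_km2, 5.69)
  expect_equal(m$mean_km2, 110.03)
  expect_equal(nrow(out$excluded), 2)
  # a single includable animal reports no SE
  one <- summarize_home_ranges(tab[c(1, 5), ])
  expect_true(is.na(one$summary$se_km2[1]))
})

test_that("exclusive-core density follows the rounding conventions", {
  d <- estimate_density(1645, 34.81, 7.26, 58.27, 25.51)
  expect_equal(d$n_females, 47L)
  expect_equal(d$n_females_range, c(39L, 60L))
  expect_equal(d$n_males, 28L)
  expect_equal(d$n_males_range, c(20L, 50L))
  expect_equal(d$density_per_100km2, 4.6)
  expect_equal(d$density_range, c(3.6, 6.7))
  # doubling land with fixed cores leaves density unchanged up to rounding
  d2 <- estimate_density(3290, 34.81, 7.26, 58.27, 25.51)
  expect_lte(abs(d2$density_per_100km2 - d$density_per_100km2), 0.1)
  # core as large as the land accommodates one animal per sex (warns)
  wn <- testthat::capture_warnings(
    d3 <- estimate_density(30, 34.81, 7.26, 58.27, 25.51))
  expect_true(any(grepl("one animal", wn)))
  expect_equal(d3$n_females, 1L)
  expect_equal(d3$n_males, 1L)
  expect_equal(d3$density_per_100km2, mangrovemove:::round_half_up(200 / 30, 1))
  expect_error(estimate_density(1645, 30, 35, 58, 20), "SE must be smaller")
})
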