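# Daily distance, activity profile, day/night and tide classification, and
# the mixed model of log movement.

test_that("daily distance sums consecutive steps", {
  p <- fixture_daily_path(x = (0:12) * 1000, y = rep(0, 13))
  md <- daily_distance(p)
  expect_equal(md$distance_km, 12)
  same <- fixture_daily_path(x = rep(5, 13), y = rep(5, 13))
  expect_equal(daily_distance(same)$distance_km, 0)
  expect_error(daily_distance(fixture_daily_path(x = 1, y = 1)),
               "at least 2 fixes")
})

test_that("daily distance equals the brute-force pairwise-norm oracle and is additive", {
  set.seed(4)
  x <- cumsum(rnorm(20, 0, 400)); y <- cumsum(rnorm(20, 0, 400))
  p <- fixture_daily_path(x, y)
  oracle <- sum(sqrt(diff(x)^2 + diff(y)^2)) / 1000
  expect_equal(daily_distance(p)$distance_km, oracle)
  # additive over any split of the step sequence
  d1 <- sum(sqrt(diff(x[1:9])^2 + diff(y[1:9])^2)) / 1000
  d2 <- sum(sqrt(diff(x[9:20])^2 + diff(y[9:20])^2)) / 1000
  expect_equal(d1 + d2, oracle)
})

test_that("hourly activity assigns step distance to the start hour", {
  # all movement between 07:00 and 08:00 local (offset 0)
  start <- as.POSIXct("2011-03-01 07:00:00", tz = "UTC")
  tr <- fixture_trajectory(x = c(0, 500, 1200), y = c(0, 0, 0),
                           start = start, interval_h = 0.5)
  act <- hourly_activity(list(tr), tz_offset_hours = 0)
  expect_equal(act$mean_km[act$hour == 7], 0.6)
  expect_true(all(act$mean_km[act$hour != 7] == 0))
  expect_equal(act$n_steps[act$hour == 7], 2)
})

test_that("a dawn-peaked simulator yields a dawn-peaked estimated profile", {
  land <- list(raster = uniform_raster(2, n = 100, cell = 100),
               channels = mangrovemove:::empty_channel_set())
  spec <- tiger_sim_spec(home_center = c(5000, 5000), duration_days = 60,
                         fix_success_prob = 1, seed = 17)
  sim <- simulate_tiger(spec, land)
  act <- hourly_activity(list(sim$trajectory))
  expect_true(act$hour[which.max(act$mean_km)] %in% 5:10)
  # flat simulator activity gives a flat profile within sampling error
  spec2 <- tiger_sim_spec(home_center = c(5000, 5000), duration_days = 60,
                          activity_profile = rep(1, 24),
                          fix_success_prob = 1, seed = 18)
  act2 <- hourly_activity(list(simulate_tiger(spec2, land)$trajectory))
  expect_lt(diff(range(act2$mean_km)) / mean(act2$mean_km), 0.5)
})

test_that("day/night classification uses the [06:00, 18:00) local window", {
  mk <- function(hhmm) as.POSIXct(paste("2011-03-01", hhmm), tz = "UTC")
  cl <- classify_daynight(mk(c("06:00:00", "17:59:59", "18:00:00",
                               "03:30:00", "05:59:59")),
                          tz_offset_hours = 0)
  expect_equal(as.character(cl), c("day", "day", "night", "night", "night"))
  # partition property: every timestamp is exactly one of the two
  set.seed(2)
  ts <- mk("00:00:00") + runif(200, 0, 86400 * 30)
  expect_false(anyNA(classify_daynight(ts)))
})

test_that("tide phase is an 8-day spring window anchored on each syzygy", {
  syz <- as.Date(c("2011-03-04", "2011-03-19"))
  expect_equal(as.character(classify_tide(as.Date("2011-03-04"), syz)),
               "spring")
  expect_equal(as.character(classify_tide(as.Date("2011-03-08"), syz)),
               "spring")   # syzygy + 4
  expect_equal(as.character(classify_tide(as.Date("2011-03-09"), syz)),
               "neap")     # syzygy + 5
  # a full synodic half-month around one syzygy holds exactly 8 spring days
  days <- seq(as.Date("2011-02-28"), as.Date("2011-03-11"), by = 1)
  cl <- classify_tide(days, syz)
  expect_equal(sum(cl == "spring"), 8)
  expect_error(classify_tide(as.Date("2013-07-01"), syz), "coverage")
})

test_that("movement records split usable days into day and night halves", {
  land <- list(raster = uniform_raster(2, n = 100, cell = 100),
               channels = mangrovemove:::empty_channel_set())
  spec <- tiger_sim_spec(home_center = c(5000, 5000), duration_days = 20,
                         fix_success_prob = 1, seed = 23)
  sim <- simulate_tiger(spec, land)
  syz <- seq(as.Date("2009-12-25"), by = "15 days", length.out = 10)
  recs <- assemble_movement_records(list(sim$trajectory), syz)
  expect_true(all(table(paste(recs$animal_id, recs$date)) == 2))
  expect_true(all(levels(recs$period) == c("day", "night")))
  expect_false(anyNA(recs$tide))
})

make_records <- function(n_animals, days_per_animal, day_mult = 1,
                         tide_mult = 1, sd_animal = 0.3, sd_resid = 0.6) {
  rows <- list()
  syz0 <- as.Date("2011-01-04")
  for (a in seq_len(n_animals)) {
    ai <- rnorm(1, 0, sd_animal)
    for (d in seq_len(days_per_animal)) {
      date <- as.Date("2011-01-01") + d
      tide <- if (abs(as.numeric(date - syz0)) %% 14 <= 5) "spring" else "neap"
      for (per in c("day", "night")) {
        mu <- 0.5 + ai + log(day_mult) * (per == "day") +
          log(tide_mult) * (tide == "spring")
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = paste0("A", a), date = date, period = per, tide = tide,
          distance_km = exp(rnorm(1, mu, sd_resid)))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$period <- factor(out$period, levels = c("day", "night"))
  out$tide <- factor(out$tide, levels = c("spring", "neap"))
  out
}

test_that("the mixed model is near nominal under no effect and detects a real one", {
  set.seed(61)
  hits <- replicate(60, {
    recs <- make_records(4, 15)
    fit <- fit_movement_model(recs)
    abs(fit$coefficients$t[fit$coefficients$term == "periodnight"]) > 2
  })
  expect_lt(mean(hits), 0.15)  # ~5% nominal, binomial slack at 60 replicates
  set.seed(62)
  power <- replicate(20, {
    recs <- make_records(4, 50, day_mult = 2)
    fit <- fit_movement_model(recs)
    co <- fit$coefficients
    co$t[co$term == "periodnight"] < -2  # day moves more, night coefficient < 0
  })
  expect_gte(mean(power), 0.8)
})

test_that("scaling all distances shifts only the model intercept", {
  set.seed(63)
  recs <- make_records(3, 20)
  f1 <- fit_movement_model(recs)
  recs2 <- recs
  recs2$distance_km <- recs2$distance_km * 10
  f2 <- fit_movement_model(recs2)
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + log(10),
               tolerance = 1e-6)
  expect_equal(c2$estimate[c2$term != "(Intercept)"],
               c1$estimate[c1$term != "(Intercept)"], tolerance = 1e-6)
})

test_that("zero distances and single animals are handled explicitly", {
  set.seed(64)
  recs <- make_records(2, 10)
  recs$distance_km[1] <- 0
  expect_silent(fit <- fit_movement_model(recs))
  expect_equal(fit$n_animals, 2)
  one <- make_records(1, 15)
  expect_warning(f1 <- fit_movement_model(one), "single animal")
  expect_true(is.na(f1$random_intercept_var))
  expect_error(fit_movement_model(make_records(2, 2)), "at least 10")
})

test_that("speeding steps are flagged, never dropped", {
  tr <- fixture_trajectory(x = c(0, 12000, 12500), y = c(0, 0, 0))
  steps <- trajectory_steps(tr, max_speed_kmh = 10)
  expect_equal(nrow(steps), 2)
  expect_equal(steps$speeding, c(TRUE, FALSE))
})
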