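# Daily travel distance, hourly activity profile, day/night and tide-phase
# classification, and the mixed model of log daily movement.

#' Daily travel distance of one daily path
#'
#' Sum of Euclidean distances between consecutive valid fixes within the day.
#'
#' @param day a `daily_path` from [assemble_daily_paths()].
#' @return Object of class `movement_day`: list(animal_id, date, distance_km,
#'   fix_count, usable).
#' @export
daily_distance <- function(day) {
  stopifnot(inherits(day, "daily_path"))
  f <- day$fixes
  if (nrow(f) < 2) stop("need at least 2 fixes to measure distance (",
                        day$animal_id, " ", day$date, ")")
  d <- sum(sqrt(diff(f$x_m)^2 + diff(f$y_m)^2)) / 1000
  structure(list(animal_id = day$animal_id, date = day$date,
                 distance_km = d, fix_count = day$fix_count,
                 usable = day$usable),
            class = "movement_day")
}

#' Step table of a trajectory
#'
#' One row per consecutive-fix step: start/end coordinates and times,
#' distance (km), duration (h), and speed (km/h). Steps faster than
#' `max_speed_kmh` are flagged (`speeding`), never dropped.
#'
#' @param traj a [trajectory()].
#' @param max_speed_kmh speed flag threshold (default 10 km/h).
#' @return data.frame of steps.
#' @export
trajectory_steps <- function(traj, max_speed_kmh = 10) {
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2) return(data.frame())
  d_km <- sqrt(diff(f$x_m)^2 + diff(f$y_m)^2) / 1000
  dt_h <- diff(as.numeric(f$timestamp)) / 3600
  data.frame(animal_id = traj$animal_id,
             t_start = f$timestamp[-n],
             x0 = f$x_m[-n], y0 = f$y_m[-n],
             x1 = f$x_m[-1], y1 = f$y_m[-1],
             distance_km = d_km, duration_h = dt_h,
             speed_kmh = d_km / dt_h,
             speeding = d_km / dt_h > max_speed_kmh,
             stringsAsFactors = FALSE)
}

#' Hourly activity profile
#'
#' Each step's distance is assigned to the local clock hour of the step
#' start; the profile is the mean step distance per hour across all steps of
#' all animals, with SE and sample counts. Hours with no steps report 0.
#'
#' @param trajectories list of [trajectory()] objects (or a single one).
#' @param tz_offset_hours local-time offset from UTC.
#' @return data.frame of class `activity_profile`: hour (0-23), mean_km,
#'   se_km, n_steps.
#' @export
hourly_activity <- function(trajectories, tz_offset_hours = 5.5) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  steps <- do.call(rbind, lapply(trajectories, trajectory_steps))
  hr <- floor((as.numeric(steps$t_start) / 3600 + tz_offset_hours) %% 24)
  out <- data.frame(hour = 0:23, mean_km = 0, se_km = NA_real_, n_steps = 0L)
  for (h in 0:23) {
    d <- steps$distance_km[hr == h]
    out$n_steps[h + 1] <- length(d)
    if (length(d) > 0) out$mean_km[h + 1] <- mean(d)
    if (length(d) > 1) out$se_km[h + 1] <- stats::sd(d) / sqrt(length(d))
  }
  class(out) <- c("activity_profile", "data.frame")
  out
}

#' Plot an hourly activity profile
#'
#' @param x an `activity_profile`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.activity_profile <- function(x, ...) {
  bp <- graphics::barplot(x$mean_km, names.arg = x$hour,
                          xlab = "local hour", ylab = "mean distance (km)",
                          ...)
  ok <- !is.na(x$se_km)
  graphics::arrows(bp[ok], x$mean_km[ok] - x$se_km[ok],
                   bp[ok], x$mean_km[ok] + x$se_km[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(bp)
}

#' Classify timestamps as day or night
#'
#' Day is the local 12-hour window [06:00, 18:00); everything else is night.
#'
#' @param timestamps POSIXct (UTC).
#' @param tz_offset_hours local-time offset from UTC.
#' @return Factor with levels "day", "night".
#' @export
classify_daynight <- function(timestamps, tz_offset_hours = 5.5) {
  hr <- (as.numeric(timestamps) / 3600 + tz_offset_hours) %% 24
  factor(ifelse(hr >= 6 & hr < 18, "day", "night"),
         levels = c("day", "night"))
}

#' Classify dates into spring or neap tide phase
#'
#' Spring tide is the 8-day window [syzygy - 3, syzygy + 4] around each new
#' or full moon; the remaining ~6 days before the next syzygy window are
#' neap. Dates further than 15 days from any listed syzygy are outside the
#' table's coverage and raise an error.
#'
#' @param dates Date vector.
#' @param syzygy_dates Date vector of new/full moon dates (a lunar calendar).
#' @return Factor with levels "spring", "neap".
#' @export
classify_tide <- function(dates, syzygy_dates) {
  dates <- as.Date(dates)
  syz <- sort(as.Date(syzygy_dates))
  out <- character(length(dates))
  for (i in seq_along(dates)) {
    dd <- as.numeric(dates[i] - syz)
    j <- which.min(abs(dd))
    if (abs(dd[j]) > 15)
      stop("date ", dates[i], " outside the syzygy table coverage")
    off <- dd[j]
    out[i] <- if (off >= -3 && off <= 4) "spring" else "neap"
  }
  factor(out, levels = c("spring", "neap"))
}

#' Read a syzygy (lunar calendar) table
#'
#' CSV with a `date` column of new/full moon dates (ISO dates).
#'
#' @param path CSV path.
#' @return Date vector.
#' @export
read_syzygy_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(tab)) stop("syzygy table needs a 'date' column")
  as.Date(tab$date)
}

#' Assemble day/night movement records for the mixed model
#'
#' Splits each usable day's steps into the day ([06:00, 18:00)) and night
#' halves by step start time, sums distances within each half, and attaches
#' the tide phase of the date.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param syzygy_dates Date vector of new/full moons.
#' @param min_fixes usable-day threshold passed to [assemble_daily_paths()].
#' @param tz_offset_hours local-time offset from UTC.
#' @return data.frame: animal_id, date, period (day/night), tide
#'   (spring/neap), distance_km.
#' @export
assemble_movement_records <- function(trajectories, syzygy_dates,
                                      min_fixes = 12, tz_offset_hours = 5.5) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  rows <- list()
  for (tr in trajectories) {
    steps <- trajectory_steps(tr)
    if (nrow(steps) == 0) next
    paths <- assemble_daily_paths(tr, min_fixes = min_fixes,
                                  tz_offset_hours = tz_offset_hours)
    step_day <- as.Date(floor(as.numeric(steps$t_start) / 86400 +
                                tz_offset_hours / 24), origin = "1970-01-01")
    period <- classify_daynight(steps$t_start, tz_offset_hours)
    for (p in paths) {
      if (!p$usable) next
      sel <- step_day == p$date
      for (per in c("day", "night")) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = tr$animal_id, date = p$date, period = per,
          distance_km = sum(steps$distance_km[sel & period == per]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$tide <- classify_tide(out$date, syzygy_dates)
  out$period <- factor(out$period, levels = c("day", "night"))
  out
}

#' Mixed model of log movement distance
#'
#' Fits `log(distance) ~ period + tide + (1 | animal_id)`. Zero distances are
#' replaced by half the minimum positive distance before the log transform.
#' With a single animal the random intercept is dropped and a fixed-effects
#' model is fitted with a warning.
#'
#' @param records data.frame from [assemble_movement_records()] (columns
#'   animal_id, period, tide, distance_km).
#' @return Object of class `movement_model_result`: `coefficients` data.frame
#'   (term, estimate, se, t, p), `random_intercept_var`, `n_records`,
#'   `n_animals`, and the fitted model object.
#' @export
fit_movement_model <- function(records) {
  need <- c("animal_id", "period", "tide", "distance_km")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) < 10) stop("need at least 10 usable records")
  d <- records$distance_km
  if (any(d < 0)) stop("negative distance")
  if (any(d == 0)) {
    sub <- min(d[d > 0]) / 2
    d[d == 0] <- sub
  }
  records$log_dist <- log(d)
  n_animals <- length(unique(records$animal_id))
  if (n_animals >= 2) {
    fit <- lmerTest::lmer(log_dist ~ period + tide + (1 | animal_id),
                          data = records)
    cf <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], t = cf[, "t value"],
                        p = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    rand_var <- vc$vcov[vc$grp == "animal_id"][1]
  } else {
    warning("single animal: fitting fixed effects only, no random intercept")
    fit <- stats::lm(log_dist ~ period + tide, data = records)
    cf <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], t = cf[, "t value"],
                        p = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE)
    rand_var <- NA_real_
  }
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, random_intercept_var = rand_var,
                 n_records = nrow(records), n_animals = n_animals,
                 fit = fit),
            class = "movement_model_result")
}

#' @export
print.movement_model_result <- function(x, ...) {
  cat(sprintf("movement model: %d records, %d animals, random-intercept var %.4g\n",
              x$n_records, x$n_animals, x$random_intercept_var))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, 3)
  cf$se <- round(cf$se, 3)
  cf$t <- round(cf$t, 3)
  cf$p <- signif(cf$p, 3)
  print(cf, row.names = FALSE)
  invisible(x)
}
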