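# Reading, writing and validating GPS fix tables, plus the data-sufficiency
# filters applied before any movement analysis.
#
# Fix CSV contract: columns animal_id, timestamp (ISO-8601, UTC), x_m, y_m,
# status ("valid" or "failed"). Coordinates must arrive projected in meters.

#' Construct a trajectory
#'
#' @param animal_id single animal identifier.
#' @param fixes data.frame with columns `timestamp` (POSIXct, UTC), `x_m`,
#'   `y_m`; rows are sorted by time on construction.
#' @param metadata list of per-animal metadata (sex, tracking_days,
#'   transient, short_deployment, ...).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(animal_id, fixes, metadata = list()) {
  stopifnot(all(c("timestamp", "x_m", "y_m") %in% names(fixes)))
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  if (nrow(fixes) > 1) {
    dt <- diff(as.numeric(fixes$timestamp))
    if (any(dt <= 0))
      stop("duplicate timestamp for animal ", animal_id, " at row ",
           which(dt <= 0)[1] + 1)
  }
  if (nrow(fixes) > 0 && any(!is.finite(fixes$x_m) | !is.finite(fixes$y_m)))
    stop("non-finite coordinate in valid fixes of animal ", animal_id)
  structure(list(animal_id = animal_id, fixes = fixes, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory %s: %d fixes, %s to %s\n", x$animal_id,
              nrow(x$fixes),
              format(min(x$fixes$timestamp)), format(max(x$fixes$timestamp))))
  invisible(x)
}

parse_ts <- function(s) {
  out <- as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(s[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read GPS fixes from CSV into trajectories
#'
#' Validates required columns, parses ISO-8601 timestamps, sorts fixes in
#' time per animal, and rejects duplicate timestamps within an animal. Rows
#' with `status = "failed"` are excluded from the trajectories but counted in
#' the acquisition metadata (`n_attempted`, `n_valid`).
#'
#' @param path CSV file path.
#' @return Named list of [trajectory()] objects, one per animal_id.
#' @export
read_fixes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- names(utils::read.csv(path, nrows = 1))
  need <- c("animal_id", "timestamp", "x_m", "y_m", "status")
  miss <- setdiff(need, hdr)
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(animal_id = "character",
                                        timestamp = "character",
                                        status = "character"))
  ts <- suppressWarnings(parse_ts(raw$timestamp))
  bad <- which(is.na(ts))
  if (length(bad)) stop("unparseable timestamp at row ", bad[1], ": '",
                        raw$timestamp[bad[1]], "'")
  raw$timestamp <- ts
  valid <- raw$status == "valid"
  badco <- which(valid & (!is.finite(raw$x_m) | !is.finite(raw$y_m)))
  if (length(badco)) stop("non-finite coordinate at row ", badco[1])
  out <- list()
  for (id in unique(raw$animal_id)) {
    sub <- raw[raw$animal_id == id & valid, c("timestamp", "x_m", "y_m")]
    tr <- trajectory(id, sub,
                     metadata = list(n_attempted = sum(raw$animal_id == id),
                                     n_valid = nrow(sub)))
    out[[id]] <- tr
  }
  out
}

#' Write a fix table (or trajectories) to CSV
#'
#' The written file round-trips losslessly through [read_fixes()]:
#' timestamps are ISO-8601 UTC and coordinates keep full double precision.
#'
#' @param x a fix data.frame (animal_id, timestamp, x_m, y_m, status) or a
#'   list of [trajectory()] objects (written with status "valid").
#' @param path output CSV path.
#' @export
write_fixes <- function(x, path) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "trajectory"))) {
    x <- do.call(rbind, lapply(x, function(tr)
      data.frame(animal_id = tr$animal_id, timestamp = tr$fixes$timestamp,
                 x_m = tr$fixes$x_m, y_m = tr$fixes$y_m, status = "valid",
                 stringsAsFactors = FALSE)))
  }
  out <- data.frame(
    animal_id = x$animal_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x_m = ifelse(is.na(x$x_m), "", sprintf("%.17g", x$x_m)),
    y_m = ifelse(is.na(x$y_m), "", sprintf("%.17g", x$y_m)),
    status = x$status, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fix acquisition success rate and mean fixes per day
#'
#' @param fix_table data.frame of all fix attempts including failed ones
#'   (columns animal_id, timestamp, status).
#' @return List: `rate` (valid/attempted), `se` (binomial SE of the rate),
#'   `mean_fixes_per_day` (valid fixes per distinct calendar day tracked),
#'   `n_attempted`, `n_valid`.
#' @export
acquisition_rate <- function(fix_table) {
  n_att <- nrow(fix_table)
  if (n_att == 0) stop("zero fix attempts")
  n_val <- sum(fix_table$status == "valid")
  rate <- n_val / n_att
  days <- unique(format(fix_table$timestamp, "%Y-%m-%d", tz = "UTC"))
  list(rate = rate,
       se = sqrt(rate * (1 - rate) / n_att),
       mean_fixes_per_day = n_val / length(days),
       n_attempted = n_att, n_valid = n_val)
}

#' Partition a trajectory into daily paths
#'
#' Days are bounded by local civil midnight of a fixed UTC offset (default
#' +05:30). A day is flagged usable when it holds at least `min_fixes` valid
#' fixes; every valid fix belongs to exactly one day.
#'
#' @param traj a [trajectory()].
#' @param min_fixes minimum fixes for a usable day (default 12).
#' @param tz_offset_hours local-time offset from UTC in hours.
#' @return List of `daily_path` objects: list(animal_id, date, fixes,
#'   fix_count, usable).
#' @export
assemble_daily_paths <- function(traj, min_fixes = 12, tz_offset_hours = 5.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj$fixes) == 0) return(list())
  local_day <- as.Date(floor(as.numeric(traj$fixes$timestamp) / 86400 +
                               tz_offset_hours / 24), origin = "1970-01-01")
  split_idx <- split(seq_len(nrow(traj$fixes)), local_day)
  lapply(names(split_idx), function(d) {
    idx <- split_idx[[d]]
    structure(list(animal_id = traj$animal_id, date = as.Date(d),
                   fixes = traj$fixes[idx, , drop = FALSE],
                   fix_count = length(idx),
                   usable = length(idx) >= min_fixes),
              class = "daily_path")
  })
}

#' Count usable days across daily paths
#' @param paths list of `daily_path` objects.
#' @return Integer count of days flagged usable.
#' @export
count_usable_days <- function(paths) {
  sum(vapply(paths, function(p) isTRUE(p$usable), TRUE))
}
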