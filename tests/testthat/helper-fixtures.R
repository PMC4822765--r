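# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# Raster whose classes are set by a small integer matrix (rows = y south
# first, columns = x), cell size in meters.
fixture_raster <- function(values, cell = 100, xmin = 0, ymin = 0) {
  habitat_raster(values, xmin = xmin, ymin = ymin, cell = cell)
}

# Single-class square raster.
uniform_raster <- function(class_code, n = 40, cell = 100) {
  fixture_raster(matrix(as.integer(class_code), n, n), cell = cell)
}

# Vertical channel strips centered at x positions with given widths; long
# enough to span any test extent.
vertical_channels <- function(x_centers, widths, y0 = -1e5, y1 = 1e5) {
  channel_set(x0 = x_centers, y0 = rep(y0, length(x_centers)),
              x1 = x_centers, y1 = rep(y1, length(x_centers)),
              width_m = widths)
}

# Fix data.frame for one animal from coordinate vectors and a start time.
fixture_fixes <- function(x, y, start = as.POSIXct("2011-03-01 00:00:00",
                                                   tz = "UTC"),
                          interval_h = 1, animal_id = "T1",
                          status = "valid") {
  data.frame(animal_id = animal_id,
             timestamp = start + (seq_along(x) - 1) * interval_h * 3600,
             x_m = x, y_m = y,
             status = rep_len(status, length(x)),
             stringsAsFactors = FALSE)
}

fixture_trajectory <- function(x, y, ...) {
  f <- fixture_fixes(x, y, ...)
  trajectory(f$animal_id[1], f[, c("timestamp", "x_m", "y_m")])
}

# A daily_path object assembled directly (local offset 0 for clarity).
fixture_daily_path <- function(x, y, start = as.POSIXct("2011-03-01 00:00:00",
                                                        tz = "UTC"),
                               interval_h = 1) {
  tr <- fixture_trajectory(x, y, start = start, interval_h = interval_h)
  assemble_daily_paths(tr, min_fixes = 2, tz_offset_hours = 0)[[1]]
}

# Independent shoelace area oracle via pracma.
oracle_area <- function(xy) abs(pracma::polyarea(xy[, 1], xy[, 2]))
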