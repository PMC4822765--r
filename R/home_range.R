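# Home-range estimation: minimum convex polygon, fixed-kernel utilization
# distributions, isopleth profiles, core-area detection, water masking,
# asymptote curves, cross-animal summaries and the exclusive-core density
# extrapolation.

# Decimal half-up rounding (the convention of printed summary tables, where
# e.g. a mean of 56.485 km2 prints as 56.49); base round() is half-to-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

as_xy <- function(fixes) {
  if (inherits(fixes, "trajectory")) fixes <- fixes$fixes
  if (is.matrix(fixes)) return(cbind(x = fixes[, 1], y = fixes[, 2]))
  nm <- names(fixes)
  xcol <- intersect(c("x_m", "x"), nm)[1]
  ycol <- intersect(c("y_m", "y"), nm)[1]
  if (is.na(xcol) || is.na(ycol)) stop("cannot find x/y columns in fixes")
  cbind(x = fixes[[xcol]], y = fixes[[ycol]])
}

#' Minimum convex polygon home range
#'
#' For `percent < 100`, the `ceiling((1 - percent/100) * n)` fixes farthest
#' from the arithmetic centroid are removed before constructing the hull.
#'
#' @param fixes a [trajectory()], data.frame with x/y columns, or matrix.
#' @param percent isopleth percentage in (0, 100]; 95 and 100 are the
#'   conventional choices.
#' @param animal_id optional label carried into the result.
#' @return Object of class `home_range_result` with fields `estimator`
#'   ("MCP"), `level`, `polygon` (counter-clockwise matrix), `area_km2`,
#'   `degenerate` and `water_masked`.
#' @export
compute_mcp <- function(fixes, percent = 95, animal_id = NA_character_) {
  xy <- as_xy(fixes)
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  n <- nrow(xy)
  if (percent < 100) {
    drop_n <- ceiling((1 - percent / 100) * n - 1e-9)
    if (drop_n > 0) {
      cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
      d <- (xy[, 1] - cx)^2 + (xy[, 2] - cy)^2
      keep <- order(d)[seq_len(n - drop_n)]
      xy <- xy[keep, , drop = FALSE]
    }
  }
  uxy <- unique(xy)
  if (nrow(uxy) < 3) stop("need at least 3 distinct fixes for an MCP (got ",
                          nrow(uxy), ")")
  hull <- convex_hull(xy[, 1], xy[, 2])
  area <- polygon_area(hull)
  degenerate <- FALSE
  if (area <= 0) {
    degenerate <- TRUE
    warning("collinear fixes: MCP is degenerate with zero area")
  }
  structure(list(animal_id = animal_id, estimator = "MCP", level = percent,
                 polygon = hull, area_km2 = area / 1e6,
                 degenerate = degenerate, water_masked = FALSE),
            class = "home_range_result")
}

#' @export
print.home_range_result <- function(x, ...) {
  cat(sprintf("%s %g%% home range%s: %.2f km2%s\n", x$estimator, x$level,
              if (!is.na(x$animal_id)) paste0(" [", x$animal_id, "]") else "",
              x$area_km2, if (x$water_masked) " (water-masked)" else ""))
  invisible(x)
}

#' Fixed-kernel utilization distribution
#'
#' Places a circular bivariate Gaussian kernel of standard deviation `h`
#' meters on every fix, averages, and renormalizes on a square grid that pads
#' at least `4 * h` beyond the fix extent.
#'
#' @param fixes fixes as in [compute_mcp()].
#' @param h kernel bandwidth (m); the study default is 1000 m.
#' @param cell grid cell size (m); must be at most `h / 4`, default `h / 10`.
#' @return Object of class `utilization_distribution`: grid origin (`xmin`,
#'   `ymin`), `cell`, `density` matrix (rows = y south to north), `h`.
#'   Densities integrate to 1 over the grid.
#' @export
compute_fixed_kernel_ud <- function(fixes, h = 1000, cell = h / 10) {
  xy <- as_xy(fixes)
  if (nrow(xy) < 1) stop("need at least one fix")
  if (cell > h / 4) stop("cell size ", cell, " too coarse: must be <= h/4 = ",
                         h / 4)
  pad <- 4 * h
  xmin <- min(xy[, 1]) - pad; xmax <- max(xy[, 1]) + pad
  ymin <- min(xy[, 2]) - pad; ymax <- max(xy[, 2]) + pad
  nx <- ceiling((xmax - xmin) / cell)
  ny <- ceiling((ymax - ymin) / cell)
  xc <- xmin + (seq_len(nx) - 0.5) * cell
  yc <- ymin + (seq_len(ny) - 0.5) * cell
  # separable Gaussian: density = (1/n) * sum_i gy_i %o% gx_i
  gx <- outer(xc, xy[, 1], function(a, b) stats::dnorm(a, b, h))
  gy <- outer(yc, xy[, 2], function(a, b) stats::dnorm(a, b, h))
  dens <- gy %*% t(gx) / nrow(xy)   # ny x nx
  tot <- sum(dens) * cell^2
  dens <- dens / tot
  structure(list(xmin = xmin, ymin = ymin, cell = cell, density = dens,
                 h = h, n_fixes = nrow(xy)),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("utilization_distribution: %d x %d cells of %g m, h = %g m, n = %d fixes\n",
              ncol(x$density), nrow(x$density), x$cell, x$h, x$n_fixes))
  invisible(x)
}

# Density threshold whose superlevel set is the smallest set holding mass p.
ud_threshold <- function(ud, p) {
  v <- sort(as.vector(ud$density), decreasing = TRUE)
  cum <- cumsum(v) * ud$cell^2
  k <- which(cum >= p)[1]
  if (is.na(k)) k <- length(v)
  v[k]
}

#' Isopleth area profile of a utilization distribution
#'
#' The level-p isopleth is the smallest-area density superlevel set
#' containing probability p/100, evaluated exactly on the grid by
#' accumulating cells in decreasing density order.
#'
#' @param ud a `utilization_distribution`.
#' @param levels isopleth percentages, default 5, 10, ..., 95.
#' @return Object of class `isopleth_profile`: data.frame with `level`,
#'   `area_km2` and `threshold` (density cutoff), plus the source grid
#'   attributes needed to rebuild masks.
#' @export
extract_isopleths <- function(ud, levels = seq(5, 95, by = 5)) {
  stopifnot(inherits(ud, "utilization_distribution"))
  if (all(ud$density == 0)) stop("empty utilization distribution")
  v <- sort(as.vector(ud$density), decreasing = TRUE)
  cum <- cumsum(v) * ud$cell^2
  areas <- numeric(length(levels))
  thr <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- which(cum >= levels[i] / 100)[1]
    if (is.na(k)) k <- length(v)
    areas[i] <- k * ud$cell^2 / 1e6
    thr[i] <- v[k]
  }
  structure(data.frame(level = levels, area_km2 = areas, threshold = thr),
            class = c("isopleth_profile", "data.frame"), ud = ud)
}

#' Grid mask of one isopleth
#'
#' @param ud a `utilization_distribution`.
#' @param level isopleth percentage.
#' @return Logical matrix over the UD grid (TRUE inside the isopleth).
#' @export
isopleth_mask <- function(ud, level) {
  thr <- ud_threshold(ud, level / 100)
  ud$density >= thr
}

#' Isopleth boundary polygons
#'
#' Contour rings of the density threshold of the given level, for export
#' (e.g. to GeoJSON). Areas should be taken from [extract_isopleths()], which
#' is exact on the grid; these rings are for display.
#'
#' @param ud a `utilization_distribution`.
#' @param level isopleth percentage.
#' @return List of two-column matrices (rings).
#' @export
isopleth_polygons <- function(ud, level) {
  thr <- ud_threshold(ud, level / 100)
  nx <- ncol(ud$density); ny <- nrow(ud$density)
  xc <- ud$xmin + (seq_len(nx) - 0.5) * ud$cell
  yc <- ud$ymin + (seq_len(ny) - 0.5) * ud$cell
  cl <- grDevices::contourLines(x = xc, y = yc, z = t(ud$density),
                                levels = thr)
  lapply(cl, function(r) cbind(x = r$x, y = r$y))
}

#' Fixed-kernel home range at one isopleth level
#'
#' @param ud a `utilization_distribution`.
#' @param level isopleth percentage (default 95).
#' @param animal_id optional label.
#' @return A `home_range_result` whose geometry is the grid mask.
#' @export
fk_home_range <- function(ud, level = 95, animal_id = NA_character_) {
  mask <- isopleth_mask(ud, level)
  structure(list(animal_id = animal_id, estimator = "FK", level = level,
                 mask = mask, ud = ud,
                 area_km2 = sum(mask) * ud$cell^2 / 1e6,
                 degenerate = FALSE, water_masked = FALSE),
            class = "home_range_result")
}

#' Exclude wide water channels from a home range
#'
#' Channels strictly wider than `min_width` meters (default 1000 m) are
#' non-habitat: their overlap with the home range is removed from the area.
#' MCP polygons are clipped exactly against each channel rectangle; fixed
#' kernel grid masks drop the cells whose centers fall in a wide channel.
#'
#' @param result a `home_range_result`.
#' @param channels a [channel_set()].
#' @param min_width width cutoff in meters; only wider channels are excluded.
#' @return The result with `area_km2` reduced and `water_masked = TRUE`.
#' @export
mask_water <- function(result, channels, min_width = 1000) {
  stopifnot(inherits(result, "home_range_result"))
  wide <- channels[channels$width_m > min_width, , drop = FALSE]
  if (nrow(wide) > 0) {
    if (result$estimator == "MCP") {
      cut_area <- 0
      for (k in seq_len(nrow(wide))) {
        rect <- channel_corners(wide[k, ])
        inter <- clip_convex(result$polygon, rect)
        if (nrow(inter) >= 3) cut_area <- cut_area + polygon_area(inter)
      }
      result$area_km2 <- max(0, result$area_km2 - cut_area / 1e6)
    } else {
      ud <- result$ud
      nx <- ncol(result$mask); ny <- nrow(result$mask)
      xc <- ud$xmin + (seq_len(nx) - 0.5) * ud$cell
      yc <- ud$ymin + (seq_len(ny) - 0.5) * ud$cell
      XX <- matrix(rep(xc, each = ny), nrow = ny)
      YY <- matrix(rep(yc, times = nx), nrow = ny)
      inw <- matrix(point_in_channels(as.vector(XX), as.vector(YY), wide),
                    nrow = ny)
      result$mask <- result$mask & !inw
      result$area_km2 <- sum(result$mask) * ud$cell^2 / 1e6
    }
  }
  result$water_masked <- TRUE
  result
}

#' Home-range area versus number of fixes
#'
#' Recomputes the home range on the first 50, 100, ... fixes in
#' chronological order and flags the first sample size after which the area
#' gain over the next increment falls below `gain_frac` of the current area
#' (the asymptote point).
#'
#' @param fixes fixes as in [compute_mcp()] (chronological order).
#' @param step increment of fixes per evaluation (default 50).
#' @param estimator "MCP" (default) or "FK".
#' @param percent isopleth level for the estimator.
#' @param gain_frac relative-gain threshold declaring the asymptote.
#' @param h,cell kernel parameters when `estimator = "FK"`.
#' @return data.frame with `n_fixes`, `area_km2`; attribute `asymptote_n`
#'   holds the flagged sample size or NA when none is reached.
#' @export
asymptote_curve <- function(fixes, step = 50, estimator = c("MCP", "FK"),
                            percent = 95, gain_frac = 0.05,
                            h = 1000, cell = h / 10) {
  estimator <- match.arg(estimator)
  xy <- as_xy(fixes)
  n <- nrow(xy)
  if (n < step) stop("need at least ", step, " fixes")
  ns <- seq(step, n, by = step)
  areas <- vapply(ns, function(k) {
    sub <- xy[seq_len(k), , drop = FALSE]
    if (estimator == "MCP") compute_mcp(sub, percent = percent)$area_km2
    else {
      ud <- compute_fixed_kernel_ud(sub, h = h, cell = cell)
      fk_home_range(ud, level = percent)$area_km2
    }
  }, 0)
  out <- data.frame(n_fixes = ns, area_km2 = areas)
  asym <- NA_integer_
  if (length(ns) >= 2) {
    for (i in seq_len(length(ns) - 1)) {
      if (areas[i] > 0 && (areas[i + 1] - areas[i]) < gain_frac * areas[i]) {
        asym <- ns[i]; break
      }
    }
  }
  attr(out, "asymptote_n") <- asym
  out
}

#' Core-area isopleth from an area-vs-level profile
#'
#' The core is read off the isopleth at which the area-versus-level curve
#' bends upward most sharply: the level maximizing the second forward
#' difference of area over level, ties broken toward the higher level. A
#' profile with no curvature (area linear in level) has no core; NA is
#' returned.
#'
#' @param profile an `isopleth_profile` (or data.frame with `level` and
#'   `area_km2`, levels ascending and equally spaced).
#' @return The core isopleth level, or NA when the profile is linear.
#' @export
detect_core_isopleth <- function(profile) {
  lv <- profile$level
  a <- profile$area_km2
  if (length(lv) < 5) stop("need at least 5 isopleth levels")
  d2 <- a[3:length(a)] - 2 * a[2:(length(a) - 1)] + a[1:(length(a) - 2)]
  if (max(abs(d2)) < 1e-9 * max(abs(a), 1e-12)) return(NA_real_)
  best <- max(which(d2 == max(d2)))   # ties toward higher level
  lv[best]
}

#' Summarize home ranges across animals
#'
#' Means and standard errors (SE = sd / sqrt(n), n = animals) by sex and
#' estimator/level, over animals not flagged excluded. Excluded animals
#' (transients, short deployments) are listed with their reason.
#'
#' @param results data.frame with columns `animal_id`, `sex` ("F"/"M"),
#'   `estimator`, `level`, `area_km2`, `excluded` (logical) and optionally
#'   `exclude_reason`.
#' @return List: `summary` data.frame (sex, estimator, level, n, mean_km2,
#'   se_km2 — mean/SE rounded to 2 decimals, NA SE for single animals) and
#'   `excluded` data.frame.
#' @export
summarize_home_ranges <- function(results) {
  stopifnot(all(c("animal_id", "sex", "estimator", "level", "area_km2",
                  "excluded") %in% names(results)))
  inc <- results[!results$excluded, , drop = FALSE]
  key <- interaction(inc$sex, inc$estimator, inc$level, drop = TRUE)
  rows <- lapply(split(inc, key), function(g) {
    n <- nrow(g)
    data.frame(sex = g$sex[1], estimator = g$estimator[1], level = g$level[1],
               n = n, mean_km2 = round_half_up(mean(g$area_km2), 2),
               se_km2 = if (n > 1)
                 round_half_up(stats::sd(g$area_km2) / sqrt(n), 2)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  smry <- do.call(rbind, rows)
  rownames(smry) <- NULL
  if (nrow(smry) == 0) warning("no includable animals")
  excl <- results[results$excluded,
                  intersect(c("animal_id", "sex", "estimator", "level",
                              "area_km2", "exclude_reason"), names(results)),
                  drop = FALSE]
  list(summary = smry, excluded = excl)
}

#' Exclusive-core density extrapolation
#'
#' Treats mean core areas as exclusive territories tiling the available land:
#' the number of animals of each sex accommodated is `round(land / core)`,
#' with an SE range from `land / (core +/- SE)`; density is
#' `100 * (n_f + n_m) / land` per 100 km2, reported to 1 decimal.
#'
#' @param land_area_km2 total land area of the region (km2).
#' @param core_female,core_female_se mean female core area and its SE (km2).
#' @param core_male,core_male_se mean male core area and its SE (km2).
#' @return Object of class `density_estimate`: counts and ranges per sex,
#'   total population, density and density range.
#' @export
estimate_density <- function(land_area_km2, core_female, core_female_se,
                             core_male, core_male_se) {
  stopifnot(land_area_km2 > 0, core_female > 0, core_male > 0)
  if (core_female_se >= core_female || core_male_se >= core_male)
    stop("core SE must be smaller than the mean core area")
  n_of <- function(core) {
    if (core >= land_area_km2) {
      warning("core area >= land area; one animal accommodated")
      return(1L)
    }
    as.integer(round(land_area_km2 / core))
  }
  nf <- n_of(core_female)
  nm <- n_of(core_male)
  nf_rng <- c(n_of(core_female + core_female_se),
              n_of(core_female - core_female_se))
  nm_rng <- c(n_of(core_male + core_male_se),
              n_of(core_male - core_male_se))
  dens <- round_half_up(100 * (nf + nm) / land_area_km2, 1)
  dens_rng <- round_half_up(100 * c(nf_rng[1] + nm_rng[1],
                                    nf_rng[2] + nm_rng[2]) /
                              land_area_km2, 1)
  structure(list(land_area_km2 = land_area_km2,
                 n_females = nf, n_females_range = nf_rng,
                 n_males = nm, n_males_range = nm_rng,
                 total = nf + nm, total_range = nf_rng + nm_rng,
                 density_per_100km2 = dens, density_range = dens_rng),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "exclusive-core density: %d females (range %d-%d), %d males (range %d-%d)\n",
    x$n_females, x$n_females_range[1], x$n_females_range[2],
    x$n_males, x$n_males_range[1], x$n_males_range[2]))
  cat(sprintf("  %.1f animals / 100 km2 (range %.1f-%.1f) on %.0f km2 land\n",
              x$density_per_100km2, x$density_range[1], x$density_range[2],
              x$land_area_km2))
  invisible(x)
}
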