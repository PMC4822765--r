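# Channel-crossing detection, the random-walk null availability model, width
# binning and the chi-square barrier test.

#' Detect channel crossings along a daily path
#'
#' One record per maximal intersection of a consecutive-fix segment with a
#' channel corridor; a path re-entering the same channel on a later segment
#' counts again.
#'
#' @param path a `daily_path`, a [trajectory()], or a data.frame/matrix of
#'   ordered x/y positions.
#' @param channels a [channel_set()].
#' @param path_id label stored in the records (defaults to animal/date when
#'   available).
#' @param source "observed" or "null".
#' @return data.frame: path_id, channel_id, width_m, source.
#' @export
detect_crossings <- function(path, channels, path_id = NULL,
                             source = "observed") {
  if (inherits(path, "daily_path")) {
    if (is.null(path_id)) path_id <- paste(path$animal_id, path$date)
    xy <- as_xy(path$fixes)
  } else if (inherits(path, "trajectory")) {
    if (is.null(path_id)) path_id <- path$animal_id
    xy <- as_xy(path$fixes)
  } else {
    if (is.null(path_id)) path_id <- "path"
    xy <- as_xy(path)
  }
  if (nrow(xy) < 2) stop("path needs at least 2 fixes")
  recs <- list()
  for (s in seq_len(nrow(xy) - 1)) {
    hits <- segment_channel_hits(xy[s, 1], xy[s, 2], xy[s + 1, 1],
                                 xy[s + 1, 2], channels)
    for (k in hits) {
      recs[[length(recs) + 1L]] <- data.frame(
        path_id = path_id, channel_id = channels$id[k],
        width_m = channels$width_m[k], source = source,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0)
    return(data.frame(path_id = character(0), channel_id = character(0),
                      width_m = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Common minimum convex polygon of pooled fixes
#'
#' Convex hull around all fixes of all animals; the study-area polygon that
#' bounds the null trajectories.
#'
#' @param trajectories list of [trajectory()] objects, or anything
#'   [compute_mcp()] accepts.
#' @return Counter-clockwise hull matrix.
#' @export
common_polygon <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (is.list(trajectories) &&
      all(vapply(trajectories, inherits, TRUE, "trajectory"))) {
    xy <- do.call(rbind, lapply(trajectories, function(tr) as_xy(tr$fixes)))
  } else {
    xy <- as_xy(trajectories)
  }
  if (nrow(unique(xy)) < 3) stop("need at least 3 distinct pooled fixes")
  hull <- convex_hull(xy[, 1], xy[, 2])
  if (polygon_area(hull) <= 0) stop("pooled fixes are collinear")
  hull
}

#' Generate random-walk null paths for one observed path
#'
#' Each null path starts at the observed start point, has the same step
#' count, draws step lengths uniformly within the observed path's [min, max]
#' step length, and takes a fresh uniform heading at every node. Whole paths
#' are rejection-sampled until no node lies outside the study polygon and no
#' node terminates in Water.
#'
#' @param observed a `daily_path` or data.frame/matrix of ordered positions.
#' @param n number of null paths (default 5 per observed path).
#' @param polygon study-area polygon (counter-clockwise matrix), e.g. from
#'   [common_polygon()].
#' @param landscape list with a `raster` element (for the Water test); pass
#'   NULL to skip the water constraint.
#' @param seed optional integer seed.
#' @param max_attempts rejection-sampling budget per requested path.
#' @param allow_partial if TRUE, return however many paths were accepted
#'   within the budget (possibly fewer than `n`, matching the field
#'   convention of "5 per path minus failures") instead of raising an error.
#' @return List of two-column matrices (the null paths).
#' @export
generate_null_paths <- function(observed, n = 5, polygon, landscape = NULL,
                                seed = NULL, max_attempts = 10000,
                                allow_partial = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(list())
  xy <- if (inherits(observed, "daily_path")) as_xy(observed$fixes)
        else as_xy(observed)
  if (nrow(xy) < 2) stop("observed path needs at least 2 fixes")
  steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  n_steps <- length(steps)
  lmin <- min(steps); lmax <- max(steps)
  water_code <- if (!is.null(landscape))
    match("Water", landscape$raster$classes) else NA_integer_

  out <- vector("list", n)
  accepted <- 0L
  attempts <- 0L
  batch <- 32L
  while (accepted < n) {
    if (attempts >= max_attempts) {
      if (allow_partial) return(out[seq_len(accepted)])
      stop("null-path rejection sampling failed after ", max_attempts,
           " attempts: the polygon/water constraints are too tight for ",
           "paths of ", n_steps, " steps from (", xy[1, 1], ", ", xy[1, 2],
           ")")
    }
    b <- min(batch, max_attempts - attempts)
    attempts <- attempts + b
    len <- matrix(stats::runif(b * n_steps, lmin, lmax), nrow = b)
    ang <- matrix(stats::runif(b * n_steps, -pi, pi), nrow = b)
    px <- xy[1, 1] + t(apply(len * cos(ang), 1, cumsum))
    py <- xy[1, 2] + t(apply(len * sin(ang), 1, cumsum))
    if (n_steps == 1) { px <- t(px); py <- t(py) }
    ok_poly <- matrix(point_in_convex(as.vector(px), as.vector(py), polygon),
                      nrow = b)
    ok <- rowSums(!ok_poly) == 0
    if (!is.na(water_code) && any(ok)) {
      cls <- matrix(raster_class_at(landscape$raster, as.vector(px),
                                    as.vector(py)), nrow = b)
      ok <- ok & rowSums(is.na(cls) | cls == water_code) == 0
    }
    for (i in which(ok)) {
      if (accepted >= n) break
      accepted <- accepted + 1L
      out[[accepted]] <- cbind(x = c(xy[1, 1], px[i, ]),
                               y = c(xy[1, 2], py[i, ]))
    }
  }
  out
}

#' Default channel width bin edges
#'
#' 50-m intervals up to 1000 m, then 500-m intervals up to `max_width`.
#' Bins are left-closed, right-open, so a width of exactly 1000 m falls in
#' the first 500-m bin.
#'
#' @param max_width largest width that must be covered (m).
#' @return Numeric vector of bin edges starting at 0.
#' @export
default_width_edges <- function(max_width = 2500) {
  top <- max(1500, ceiling(max_width / 500) * 500)
  if (max_width >= top) top <- top + 500
  c(seq(0, 1000, by = 50), seq(1500, top, by = 500))
}

#' Tabulate observed and null crossings by width bin
#'
#' @param records data.frame of [detect_crossings()] records with both
#'   `source = "observed"` and `source = "null"` rows.
#' @param edges bin edges (left-closed, right-open); default
#'   [default_width_edges()] extended to the widest record.
#' @return Object of class `width_bin_table`: data.frame with bin_lo, bin_hi,
#'   observed, availability.
#' @export
bin_crossings <- function(records, edges = NULL) {
  if (nrow(records) == 0) stop("no crossing records")
  if (is.null(edges)) edges <- default_width_edges(max(records$width_m))
  if (max(records$width_m) >= max(edges)) {
    warning("record wider than the final edge; extending the last bin")
    edges <- c(edges, ceiling(max(records$width_m) / 500 + 1) * 500)
  }
  k <- length(edges) - 1
  bin_of <- function(w) findInterval(w, edges, rightmost.closed = FALSE)
  obs <- records$width_m[records$source == "observed"]
  nul <- records$width_m[records$source == "null"]
  tab <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    observed = tabulate(bin_of(obs), nbins = k),
    availability = tabulate(bin_of(nul), nbins = k))
  class(tab) <- c("width_bin_table", "data.frame")
  tab
}

#' Chi-square test of crossings against availability
#'
#' Expected counts are the availability profile scaled to the observed total;
#' adjacent bins are merged (each under-floor bin into its lower-expected
#' neighbor) until every expected count reaches `min_expected`. The statistic
#' is the usual sum of (observed - expected)^2 / expected with
#' df = merged bins - 1.
#'
#' @param table a `width_bin_table` from [bin_crossings()].
#' @param min_expected minimum expected count per merged bin (default 1).
#' @return The table completed: `merged` data.frame (bin_lo, bin_hi,
#'   observed, availability, expected), `chi_square`, `df`, `p`.
#' @export
crossing_chisq <- function(table, min_expected = 1) {
  if (sum(table$availability > 0) < 2)
    stop("availability counts must be positive in at least 2 bins")
  m <- table[, c("bin_lo", "bin_hi", "observed", "availability")]
  # drop bins with no availability and no observation (uninformative)
  m <- m[m$availability > 0 | m$observed > 0, , drop = FALSE]
  tot_obs <- sum(m$observed)
  expected <- function(mm) tot_obs * mm$availability / sum(mm$availability)
  repeat {
    e <- expected(m)
    low <- which(e < min_expected)
    if (length(low) == 0 || nrow(m) <= 2) break
    i <- low[1]
    j <- if (i == 1) 2L
         else if (i == nrow(m)) i - 1L
         else if (e[i - 1] <= e[i + 1]) i - 1L else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    m$bin_hi[lo] <- m$bin_hi[hi]
    m$observed[lo] <- m$observed[lo] + m$observed[hi]
    m$availability[lo] <- m$availability[lo] + m$availability[hi]
    m <- m[-hi, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("fewer than 2 bins remain after merging")
  m$expected <- expected(m)
  chi <- sum((m$observed - m$expected)^2 / m$expected)
  df <- nrow(m) - 1
  rownames(m) <- NULL
  structure(list(merged = m, chi_square = chi, df = df,
                 p = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "crossing_test")
}

#' @export
print.crossing_test <- function(x, ...) {
  cat(sprintf("channel-crossing chi-square: X2 = %.2f, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' Mean channels crossed per day
#'
#' @param records observed crossing records (one row per crossing).
#' @param n_days number of daily paths screened.
#' @return List with `mean` and `se` (across days, including zero-crossing
#'   days).
#' @export
crossings_per_day <- function(records, n_days) {
  counts <- table(factor(records$path_id[records$source == "observed"]))
  per_day <- c(as.numeric(counts), rep(0, max(0, n_days - length(counts))))
  list(mean = mean(per_day),
       se = stats::sd(per_day) / sqrt(length(per_day)))
}
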