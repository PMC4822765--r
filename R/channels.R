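# Water channels as straight constant-width corridors: a centerline segment
# plus a width in meters. GeoJSON I/O uses LineString centerlines with a
# "width_m" property.

#' Construct a channel set
#'
#' @param x0,y0,x1,y1 centerline endpoints (m).
#' @param width_m channel widths (m), all positive.
#' @param id optional feature ids.
#' @return data.frame of class `channel_set`.
#' @export
channel_set <- function(x0, y0, x1, y1, width_m, id = NULL) {
  n <- length(x0)
  if (is.null(id)) id <- paste0("ch", seq_len(n))
  stopifnot(length(width_m) == n, all(width_m > 0))
  ch <- data.frame(id = as.character(id), x0 = x0, y0 = y0,
                   x1 = x1, y1 = y1, width_m = width_m,
                   stringsAsFactors = FALSE)
  class(ch) <- c("channel_set", "data.frame")
  ch
}

empty_channel_set <- function() {
  channel_set(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
              id = character(0))
}

#' Corner polygon of one channel corridor
#'
#' @param ch one-row slice of a `channel_set`.
#' @return 4 x 2 matrix, counter-clockwise rectangle.
#' @export
channel_corners <- function(ch) {
  dx <- ch$x1 - ch$x0; dy <- ch$y1 - ch$y0
  L <- sqrt(dx^2 + dy^2)
  nx <- -dy / L; ny <- dx / L
  hw <- ch$width_m / 2
  m <- rbind(c(ch$x0 + nx * hw, ch$y0 + ny * hw),
             c(ch$x0 - nx * hw, ch$y0 - ny * hw),
             c(ch$x1 - nx * hw, ch$y1 - ny * hw),
             c(ch$x1 + nx * hw, ch$y1 + ny * hw))
  # ensure counter-clockwise orientation
  if (cross2(m[1, 1], m[1, 2], m[2, 1], m[2, 2], m[3, 1], m[3, 2]) < 0)
    m <- m[4:1, , drop = FALSE]
  m
}

#' Channels intersected by one movement segment
#'
#' @param x1,y1,x2,y2 segment endpoints (m).
#' @param channels a `channel_set`.
#' @return Integer row indices of intersected channels (maximal intersection
#'   per channel, so each channel appears at most once per segment).
#' @export
segment_channel_hits <- function(x1, y1, x2, y2, channels) {
  if (nrow(channels) == 0) return(integer(0))
  hit <- logical(nrow(channels))
  for (k in seq_len(nrow(channels))) {
    iv <- segment_rect_interval(x1, y1, x2, y2,
                                channels$x0[k], channels$y0[k],
                                channels$x1[k], channels$y1[k],
                                channels$width_m[k] / 2)
    hit[k] <- !is.null(iv)
  }
  which(hit)
}

#' Test whether points fall inside any channel corridor
#'
#' @param x,y point coordinates.
#' @param channels a `channel_set`.
#' @param min_width only consider channels strictly wider than this (m).
#' @return Logical vector.
#' @export
point_in_channels <- function(x, y, channels, min_width = 0) {
  out <- rep(FALSE, length(x))
  sel <- which(channels$width_m > min_width)
  for (k in sel) {
    dx <- channels$x1[k] - channels$x0[k]
    dy <- channels$y1[k] - channels$y0[k]
    L <- sqrt(dx^2 + dy^2)
    ux <- dx / L; uy <- dy / L
    u <- (x - channels$x0[k]) * ux + (y - channels$y0[k]) * uy
    v <- (x - channels$x0[k]) * (-uy) + (y - channels$y0[k]) * ux
    out <- out | (u >= 0 & u <= L & abs(v) <= channels$width_m[k] / 2)
  }
  out
}

#' Write channels to GeoJSON
#'
#' Features are LineString centerlines carrying a `width_m` property.
#'
#' @param channels a `channel_set`.
#' @param path output path.
#' @export
write_channels_geojson <- function(channels, path) {
  feats <- lapply(seq_len(nrow(channels)), function(k) {
    list(type = "Feature",
         properties = list(id = channels$id[k],
                           width_m = channels$width_m[k]),
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(channels$x0[k], channels$y0[k]),
                           c(channels$x1[k], channels$y1[k]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read channels from GeoJSON
#'
#' Accepts LineString centerlines with a `width_m` property.
#'
#' @param path GeoJSON file path.
#' @return A `channel_set`.
#' @export
read_channels_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0) return(empty_channel_set())
  rows <- lapply(fc$features, function(f) {
    if (f$geometry$type != "LineString")
      stop("channel features must be LineString centerlines with width_m")
    cc <- f$geometry$coordinates
    data.frame(id = as.character(f$properties$id),
               x0 = as.numeric(cc[[1]][[1]]), y0 = as.numeric(cc[[1]][[2]]),
               x1 = as.numeric(cc[[2]][[1]]), y1 = as.numeric(cc[[2]][[2]]),
               width_m = as.numeric(f$properties$width_m),
               stringsAsFactors = FALSE)
  })
  ch <- do.call(rbind, rows)
  channel_set(ch$x0, ch$y0, ch$x1, ch$y1, ch$width_m, id = ch$id)
}
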