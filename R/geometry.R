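# Planar geometry primitives used by the home-range and channel modules.
# All coordinates are projected meters; no geographic CRS handling here.

#' Polygon area by the shoelace formula
#'
#' @param xy two-column matrix of vertices (closed or open ring).
#' @return Area in square meters (nonnegative).
#' @keywords internal
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  # drop duplicated closing vertex if present
  if (isTRUE(all(xy[1, ] == xy[n, ]))) {
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 3) return(0)
  }
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Convex hull of a point set, counter-clockwise
#'
#' @param x,y coordinate vectors.
#' @return Two-column matrix of hull vertices in counter-clockwise order.
#' @keywords internal
convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)  # chull returns clockwise order
  hull <- cbind(x = x[idx], y = y[idx])
  hull[rev(seq_len(nrow(hull))), , drop = FALSE]
}

# Signed area of triangle (a, b, c); > 0 when counter-clockwise.
cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Test points against a convex polygon
#'
#' @param px,py point coordinate vectors.
#' @param poly counter-clockwise convex polygon (two-column matrix).
#' @param eps boundary tolerance in meters.
#' @return Logical vector, TRUE when inside or on the boundary.
#' @keywords internal
point_in_convex <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- cross2(poly[i, 1], poly[i, 2], poly[j, 1], poly[j, 2], px, py)
    inside <- inside & (s >= -eps * (abs(s) + 1))
  }
  inside
}

#' Intersection of two convex polygons (Sutherland-Hodgman)
#'
#' @param subject,clip counter-clockwise convex polygons.
#' @return Two-column matrix of the intersection polygon (possibly 0 rows).
#' @keywords internal
clip_convex <- function(subject, clip) {
  out <- as.matrix(subject)
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    j <- if (i == nc) 1L else i + 1L
    ax <- clip[i, 1]; ay <- clip[i, 2]
    bx <- clip[j, 1]; by <- clip[j, 2]
    inp <- out
    n <- nrow(inp)
    keep <- cross2(ax, ay, bx, by, inp[, 1], inp[, 2]) >= 0
    res <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      p <- inp[k, ]; q <- inp[k2, ]
      if (keep[k]) res <- rbind(res, p)
      if (keep[k] != keep[k2]) {
        # edge pq crosses the clip line: compute intersection point
        d1 <- cross2(ax, ay, bx, by, p[1], p[2])
        d2 <- cross2(ax, ay, bx, by, q[1], q[2])
        t <- d1 / (d1 - d2)
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  unname(out)
}

# Parametric overlap of segment (x1,y1)->(x2,y2) with the slab/rectangle of a
# corridor: local frame u along the centerline in [0, L], v across in
# [-hw, hw]. Returns c(t0, t1) in [0,1] or NULL when disjoint.
segment_rect_interval <- function(x1, y1, x2, y2, ax, ay, bx, by, halfwidth) {
  dx <- bx - ax; dy <- by - ay
  L <- sqrt(dx^2 + dy^2)
  ux <- dx / L; uy <- dy / L        # unit along
  nx <- -uy; ny <- ux               # unit across
  # endpoint coordinates in corridor frame
  u1 <- (x1 - ax) * ux + (y1 - ay) * uy
  u2 <- (x2 - ax) * ux + (y2 - ay) * uy
  v1 <- (x1 - ax) * nx + (y1 - ay) * ny
  v2 <- (x2 - ax) * nx + (y2 - ay) * ny
  t0 <- 0; t1 <- 1
  for (s in list(c(u1, u2, 0, L), c(v1, v2, -halfwidth, halfwidth))) {
    p1 <- s[1]; p2 <- s[2]; lo <- s[3]; hi <- s[4]
    d <- p2 - p1
    if (abs(d) < 1e-12) {
      if (p1 < lo || p1 > hi) return(NULL)
    } else {
      ta <- (lo - p1) / d; tb <- (hi - p1) / d
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  c(t0, t1)
}
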