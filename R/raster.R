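# Minimal in-memory habitat raster with ESRI ASCII grid I/O.
#
# The value matrix is stored with rows = y (row 1 at ymin, increasing north)
# and columns = x (column 1 at xmin), i.e. matrix[iy, ix]. Cell registration
# is by lower-left corner of the grid; lookups use cell membership of the
# point, not nearest-center.

#' The five mangrove habitat classes
#'
#' Integer codes 1..5 name, in order: open water and channels; Phoenix
#' paludosa thicket on high ground; Ceriops decandra shrub; barren
#' salt-encrusted flats; low-lying Avicennia-Sonneratia stands.
#'
#' @return Character vector of class names, in code order.
#' @export
habitat_classes <- function() {
  c("Water", "Phoenix", "Ceriops", "Barren", "AvicSonn")
}

#' Construct a habitat raster
#'
#' @param values integer matrix of class codes, rows = y (south to north),
#'   columns = x (west to east).
#' @param xmin,ymin coordinates of the grid's lower-left corner (m).
#' @param cell cell size (m), square cells.
#' @param classes character vector naming the class codes.
#' @return Object of class `habitat_raster`.
#' @export
habitat_raster <- function(values, xmin, ymin, cell,
                           classes = habitat_classes()) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cell = cell, classes = classes),
            class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("habitat_raster: %d x %d cells of %g m, origin (%g, %g)\n",
              ncol(x$values), nrow(x$values), x$cell, x$xmin, x$ymin))
  print(round(raster_fractions(x), 4))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cell,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cell)
}

#' Habitat class code at point locations
#'
#' @param r a `habitat_raster`.
#' @param x,y point coordinates (m).
#' @return Integer class codes; `NA` for points outside the raster extent.
#' @export
raster_class_at <- function(r, x, y) {
  ix <- floor((x - r$xmin) / r$cell) + 1L
  iy <- floor((y - r$ymin) / r$cell) + 1L
  ok <- ix >= 1L & ix <= ncol(r$values) & iy >= 1L & iy <= nrow(r$values)
  out <- rep(NA_integer_, length(x))
  if (any(ok)) out[ok] <- r$values[cbind(iy[ok], ix[ok])]
  out
}

#' Realized class-area fractions of a raster
#'
#' @param r a `habitat_raster`.
#' @return Named numeric vector of proportions over all cells.
#' @export
raster_fractions <- function(r) {
  n <- length(r$values)
  counts <- vapply(seq_along(r$classes), function(k) sum(r$values == k), 0)
  stats::setNames(counts / n, r$classes)
}

#' Total land area of a raster in km^2 (all non-Water classes)
#' @param r a `habitat_raster`.
#' @return Land area in km^2.
#' @export
raster_land_area_km2 <- function(r) {
  sum(r$values != match("Water", r$classes)) * r$cell^2 / 1e6
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard six-line header; rows are written
#' north to south as the format requires.
#'
#' @param r a `habitat_raster`.
#' @param path output file path.
#' @export
write_esri_ascii <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymin),
    sprintf("cellsize %.6f", r$cell),
    "NODATA_value -9999"), con)
  for (iy in rev(seq_len(nrow(r$values)))) {
    writeLines(paste(r$values[iy, ], collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid as a habitat raster
#'
#' @param path file path.
#' @param classes class names for the integer codes.
#' @return A `habitat_raster`.
#' @export
read_esri_ascii <- function(path, classes = habitat_classes()) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(ncol(m) == hdr$ncols, nrow(m) == hdr$nrows)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  habitat_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, classes)
}
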