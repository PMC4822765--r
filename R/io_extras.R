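# Export helpers for downstream GIS work: utilization distributions as
# ESRI ASCII grids, polygons as GeoJSON, and simulation truth as JSON.

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' @param ud a `utilization_distribution`.
#' @param path output `.asc` path.
#' @export
write_ud_esri_ascii <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(ud$density)),
    sprintf("nrows %d", nrow(ud$density)),
    sprintf("xllcorner %.6f", ud$xmin),
    sprintf("yllcorner %.6f", ud$ymin),
    sprintf("cellsize %.6f", ud$cell),
    "NODATA_value -9999"), con)
  for (iy in rev(seq_len(nrow(ud$density))))
    writeLines(paste(sprintf("%.8e", ud$density[iy, ]), collapse = " "), con)
  invisible(path)
}

#' Write polygons to GeoJSON
#'
#' @param polys a single two-column matrix or a list of them (rings).
#' @param path output path.
#' @param properties optional list of per-feature property lists.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  if (is.matrix(polys)) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(k) {
    ring <- polys[[k]]
    if (!isTRUE(all(ring[1, ] == ring[nrow(ring), ])))
      ring <- rbind(ring, ring[1, ])  # close the ring
    list(type = "Feature",
         properties = if (is.null(properties)) list(id = k)
                      else properties[[k]],
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i)
                                                     unname(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_tiger()] (the path matrix is
#'   omitted; it lives in the fix table).
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    animal_id = truth$spec$animal_id,
    step_scale = truth$spec$step_scale,
    habitat_weights = as.list(truth$spec$habitat_weights),
    crossing_halfwidth = truth$spec$crossing_halfwidth,
    fix_success_prob = truth$spec$fix_success_prob,
    duration_days = truth$spec$duration_days,
    daily_distance_km = truth$daily_distance_km,
    mean_daily_distance_km = mean(truth$daily_distance_km),
    occupancy = as.list(truth$occupancy),
    crossings_by_channel = as.list(table(truth$crossings$channel_id)),
    crossing_proposals = as.list(truth$crossing_proposals),
    crossing_accepts = as.list(truth$crossing_accepts))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
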