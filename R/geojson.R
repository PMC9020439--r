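# GeoJSON export of sites, grid cells, and neighbor graphs (for mapping in
# any GIS; the package itself does no cartography).

.geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       null = "null")
  invisible(path)
}

#' Export site points as GeoJSON
#'
#' @param table A [survey_table()] (or a `landscape`'s `sites` data.frame
#'   with `site_id`, `lon`, `lat`).
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
geojson_sites <- function(table, path) {
  sites <- if (inherits(table, "survey_table")) table$sites else table
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$lon[i], sites$lat[i])),
         properties = list(site_id = sites$site_id[i]))
  })
  .geojson_write(feats, path)
}

#' Export grid-cell polygons as GeoJSON
#'
#' Cell corners are unprojected from the grid CRS, so polygons render
#' correctly on a lon/lat map.
#'
#' @param cells A [assign_sites()] result or a [generate_landscape()] result.
#' @param path Output `.geojson` path.
#' @param values Optional named list of per-cell property vectors, e.g.
#'   fitted cell slopes.
#' @return `path`, invisibly.
#' @export
geojson_cells <- function(cells, path, values = NULL) {
  if (inherits(cells, "cell_assignment")) {
    g <- cells$grid
    df <- cells$cells
    s <- g$cell_size
    crs <- g$crs %||% "ETRS89-LAEA"
    x0 <- g$x0 + df$col * s
    y0 <- g$y0 + df$row * s
    props <- Map(function(i) list(cell_id = df$cell_id[i], lat = df$lat[i],
                                  n_sites = df$n_sites[i]),
                 seq_len(nrow(df)))
  } else if (inherits(cells, "landscape")) {
    df <- cells$cells
    s <- cells$cell_size
    crs <- cells$crs
    x0 <- df$cx - s / 2
    y0 <- df$cy - s / 2
    props <- Map(function(i) list(cell_id = df$cell_id[i], lat = df$lat[i]),
                 seq_len(nrow(df)))
  } else {
    stop_arg("`cells` must be a cell_assignment or a landscape")
  }
  feats <- lapply(seq_len(nrow(df)), function(i) {
    corners <- laea_unproject(c(x0[i], x0[i] + s, x0[i] + s, x0[i], x0[i]),
                              c(y0[i], y0[i], y0[i] + s, y0[i] + s, y0[i]),
                              crs)
    pr <- props[[i]]
    for (nm in names(values)) pr[[nm]] <- values[[nm]][i]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, corners$lon, corners$lat))),
         properties = pr)
  })
  .geojson_write(feats, path)
}

#' Export a neighbor graph as GeoJSON line features
#'
#' @param graph A [relative_neighborhood_graph()] result (projected
#'   coordinates).
#' @param path Output `.geojson` path.
#' @param crs CRS of the graph coordinates, for unprojection.
#' @return `path`, invisibly.
#' @export
geojson_graph <- function(graph, path, crs = "ETRS89-LAEA") {
  stopifnot(inherits(graph, "neighbor_graph"))
  ll <- laea_unproject(graph$coords[, 1], graph$coords[, 2], crs)
  feats <- lapply(seq_len(nrow(graph$edges)), function(k) {
    i <- graph$edges[k, 1]
    j <- graph$edges[k, 2]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(ll$lon[i], ll$lat[i]),
                                            c(ll$lon[j], ll$lat[j]))),
         properties = list(from = graph$ids[i], to = graph$ids[j]))
  })
  .geojson_write(feats, path)
}
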