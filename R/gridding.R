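#' Build a square metric grid over a projected survey table
#'
#' Defines the grid used to standardize sampling units: square cells of
#' `cell_size` meters covering the bounding box of the projected sites. By
#' default the origin is anchored by flooring the bounding-box minimum to a
#' multiple of `cell_size`, which makes the grid independent of site order
#' and reproducible; an explicit `origin` can override the anchor (e.g. to
#' match an externally defined grid).
#'
#' @param table A projected [survey_table()] (see [project_coordinates()]).
#' @param cell_size Cell side length in meters (default 75 km).
#' @param origin Optional `c(x0, y0)` anchor override in meters.
#' @return A list of class `grid_spec` with fields `x0`, `y0`, `cell_size`,
#'   `nx`, `ny` (extent in cells) and `crs`.
#' @export
build_grid <- function(table, cell_size = 75000, origin = NULL) {
  stopifnot(inherits(table, "survey_table"))
  cell_size <- check_number(cell_size, "cell_size", lower = 1e-6)
  if (is.null(table$sites$x) || !nrow(table$sites)) {
    stop_arg("`table` has no projected sites; call project_coordinates() first")
  }
  x <- table$sites$x
  y <- table$sites$y
  if (is.null(origin)) {
    x0 <- floor(min(x) / cell_size) * cell_size
    y0 <- floor(min(y) / cell_size) * cell_size
  } else {
    if (length(origin) != 2L || !all(is.finite(origin))) {
      stop_arg("`origin` must be c(x0, y0) in meters")
    }
    x0 <- origin[1]
    y0 <- origin[2]
    if (x0 > min(x) || y0 > min(y)) stop_arg("`origin` does not cover all sites")
  }
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 nx = as.integer(floor((max(x) - x0) / cell_size)) + 1L,
                 ny = as.integer(floor((max(y) - y0) / cell_size)) + 1L,
                 crs = table$crs),
            class = "grid_spec")
}

#' Assign sites to grid cells
#'
#' Half-open membership on both axes: a site with `x` in
#' `[x0 + k*s, x0 + (k+1)*s)` belongs to column `k` (same for rows), so
#' boundary sites go to the higher-index cell and the assignment partitions
#' the sites. Only occupied cells are listed; cell centroid latitudes `L_q`
#' (the latitude covariate of the hierarchical model) are the unprojected
#' latitudes of the cell polygon centers.
#'
#' @param table A projected [survey_table()].
#' @param grid A [build_grid()] result.
#' @return A list of class `cell_assignment` with data.frames `sites`
#'   (`site_id`, `cell_id`) and `cells` (`cell_id`, `row`, `col`, `cx`, `cy`,
#'   `lon`, `lat`, `n_sites`), plus the `grid`.
#' @export
assign_sites <- function(table, grid) {
  stopifnot(inherits(table, "survey_table"), inherits(grid, "grid_spec"))
  if (is.null(table$sites$x) || !nrow(table$sites)) {
    stop_arg("`table` has no projected sites")
  }
  s <- grid$cell_size
  col <- floor((table$sites$x - grid$x0) / s)
  row <- floor((table$sites$y - grid$y0) / s)
  out_of <- which(col < 0 | row < 0 | col >= grid$nx | row >= grid$ny)
  if (length(out_of)) {
    stop_arg("site(s) outside the grid extent: %s",
             paste(utils::head(table$sites$site_id[out_of], 5), collapse = ", "))
  }
  key <- paste(row, col, sep = "_")
  ukey <- sort(unique(key))
  cell_id <- sprintf("g%s", ukey)
  idx <- match(key, ukey)
  urow <- as.integer(sub("_.*", "", ukey))
  ucol <- as.integer(sub(".*_", "", ukey))
  cx <- grid$x0 + (ucol + 0.5) * s
  cy <- grid$y0 + (urow + 0.5) * s
  cen <- laea_unproject(cx, cy, grid$crs %||% "ETRS89-LAEA")
  cells <- data.frame(cell_id = cell_id, row = urow, col = ucol,
                      cx = cx, cy = cy, lon = cen$lon, lat = cen$lat,
                      n_sites = as.integer(tabulate(idx, length(ukey))),
                      stringsAsFactors = FALSE)
  sites <- data.frame(site_id = table$sites$site_id,
                      cell_id = cell_id[idx], stringsAsFactors = FALSE)
  structure(list(sites = sites, cells = cells, grid = grid),
            class = "cell_assignment")
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("<cell_assignment> %d sites in %d occupied cells (%g km pitch)\n",
              nrow(x$sites), nrow(x$cells), x$grid$cell_size / 1000))
  invisible(x)
}

#' Cell centroid latitudes
#'
#' @param assignment A [assign_sites()] result.
#' @return Named numeric vector of centroid latitudes `L_q` (degrees), one
#'   per occupied cell.
#' @export
cell_latitudes <- function(assignment) {
  stopifnot(inherits(assignment, "cell_assignment"))
  if (!nrow(assignment$cells)) stop_arg("empty assignment")
  stats::setNames(assignment$cells$lat, assignment$cells$cell_id)
}
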