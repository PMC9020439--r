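#' Ground-truth parameters for the synthetic count-survey generator
#'
#' Returns the parameter set of the hierarchical trend model used as the
#' default generating truth: a global year slope `beta0`, a per-degree
#' latitude effect `gamma` on cell mean slopes, standard deviations of the
#' cell-level (`sigma_b`) and site-level (`sigma_d`) random slopes, the
#' observation-level lognormal overdispersion SD `sigma_e`, and the
#' mean/SD of the Gaussian site intercepts on the log scale. The defaults
#' are the point estimates reported for the NW-European pochard winter-count
#' analysis, so simulated surveys carry realistic between-site heterogeneity
#' and overdispersion.
#'
#' @param beta0 Global year slope, log-count units per (centered) year.
#' @param gamma Latitude effect on the cell mean slope, per degree latitude.
#' @param sigma_b SD of cell slope effects around `gamma * L`.
#' @param sigma_d SD of site slope effects around their cell mean.
#' @param sigma_e SD of observation-level log-scale residuals (overdispersion).
#' @param alpha_mean,alpha_sd Mean and SD of Gaussian site intercepts
#'   (log-count units). Intercepts are not reported by the source analysis;
#'   the defaults give heavy right-skewed counts typical of waterbird sites.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(beta0 = 0.38, gamma = -0.008,
                         sigma_b = 0.033, sigma_d = 0.073, sigma_e = 1.18,
                         alpha_mean = 3, alpha_sd = 1.5) {
  out <- list(beta0 = check_number(beta0, "beta0"),
              gamma = check_number(gamma, "gamma"),
              sigma_b = check_number(sigma_b, "sigma_b", lower = 0),
              sigma_d = check_number(sigma_d, "sigma_d", lower = 0),
              sigma_e = check_number(sigma_e, "sigma_e", lower = 0),
              alpha_mean = check_number(alpha_mean, "alpha_mean"),
              alpha_sd = check_number(alpha_sd, "alpha_sd", lower = 0))
  class(out) <- "truth_params"
  out
}

#' Generate a synthetic survey landscape
#'
#' Lays grid cells of a given pitch (default 75 km) on the projected plane so
#' that cell-centroid latitudes span `lat_range`, then scatters survey sites
#' around each cell centroid with a Gaussian cluster spread (truncated to the
#' cell tile, so the generating cell of every site is also its geometric
#' cell). Cell corners fall on multiples of `cell_size`, so a grid rebuilt
#' from the sites with floor-anchoring reproduces the generating tiles.
#'
#' @param n_cells Number of grid cells (>= 1).
#' @param lat_range Length-2 degree interval covered by cell centroids.
#' @param sites_per_cell Either a single integer (constant number of sites in
#'   every cell), a length-2 integer range (discrete uniform), or a
#'   `function(n)` returning `n` positive integers.
#' @param cluster_sd Gaussian spread of sites around their cell centroid, in
#'   meters.
#' @param cell_size Grid pitch in meters.
#' @param crs CRS used to relate the projected plane to longitude/latitude.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A list of class `landscape` with data.frames `cells`
#'   (`cell_id`, `row`, `col`, `cx`, `cy`, `lon`, `lat`) and `sites`
#'   (`site_id`, `cell_id`, `x`, `y`, `lon`, `lat`).
#' @export
generate_landscape <- function(n_cells, lat_range = c(46, 60),
                               sites_per_cell = 5, cluster_sd = 15000,
                               cell_size = 75000, crs = "ETRS89-LAEA",
                               seed = 1) {
  n_cells <- check_number(n_cells, "n_cells", lower = 1)
  if (length(lat_range) != 2L || !all(is.finite(lat_range)) ||
      any(abs(lat_range) >= 90) || lat_range[1] > lat_range[2]) {
    stop_arg("`lat_range` must be an increasing degree interval within (-90, 90)")
  }
  cluster_sd <- check_number(cluster_sd, "cluster_sd", lower = 0)
  cell_size <- check_number(cell_size, "cell_size", lower = 1)
  crs <- crs_params(crs)

  draw_n <- if (is.function(sites_per_cell)) {
    sites_per_cell
  } else if (length(sites_per_cell) == 1L) {
    n0 <- as.integer(sites_per_cell)
    if (is.na(n0) || n0 < 1L) stop_arg("`sites_per_cell` must yield >= 1 site")
    function(n) rep.int(n0, n)
  } else if (length(sites_per_cell) == 2L) {
    rng <- as.integer(sites_per_cell)
    if (any(is.na(rng)) || rng[1] < 1L || rng[1] > rng[2]) {
      stop_arg("`sites_per_cell` range must be increasing and >= 1")
    }
    function(n) sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
  } else {
    stop_arg("`sites_per_cell` must be a count, a range, or a function")
  }

  # Row positions: snap the projected y of the latitude span to the grid pitch.
  yr <- laea_project(c(crs$lon0, crs$lon0), lat_range, crs)$y
  y_lo <- floor(yr[1] / cell_size) * cell_size
  n_rows <- max(1L, as.integer(floor((yr[2] - y_lo) / cell_size)) + 1L)
  n_rows <- min(n_rows, n_cells)
  n_cols <- as.integer(ceiling(n_cells / n_rows))
  x_mid <- laea_project(crs$lon0, mean(lat_range), crs)$x
  x_lo <- (round(x_mid / cell_size) - ceiling(n_cols / 2)) * cell_size

  idx <- seq_len(n_cells) - 1L
  row <- idx %% n_rows
  col <- idx %/% n_rows
  cx <- x_lo + (col + 0.5) * cell_size
  cy <- y_lo + (row + 0.5) * cell_size
  cen <- laea_unproject(cx, cy, crs)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
                      row = as.integer(row), col = as.integer(col),
                      cx = cx, cy = cy, lon = cen$lon, lat = cen$lat,
                      stringsAsFactors = FALSE)

  with_seed(seed, {
    ns <- draw_n(n_cells)
    if (length(ns) != n_cells || any(!is.finite(ns)) || any(ns < 1)) {
      stop_arg("`sites_per_cell` must yield one count >= 1 per cell")
    }
    ns <- as.integer(ns)
    cell_of_site <- rep.int(seq_len(n_cells), ns)
    half <- cell_size / 2
    # truncated-normal scatter: redraw offsets that escape the cell tile
    n_sites <- length(cell_of_site)
    dx <- rnorm(n_sites, 0, cluster_sd)
    dy <- rnorm(n_sites, 0, cluster_sd)
    for (it in 1:100) {
      bad <- which(abs(dx) >= half | abs(dy) >= half)
      if (!length(bad)) break
      dx[bad] <- rnorm(length(bad), 0, cluster_sd)
      dy[bad] <- rnorm(length(bad), 0, cluster_sd)
    }
    dx <- pmin(pmax(dx, -half + 1), half - 1)
    dy <- pmin(pmax(dy, -half + 1), half - 1)
    sx <- cx[cell_of_site] + dx
    sy <- cy[cell_of_site] + dy
    sll <- laea_unproject(sx, sy, crs)
    sites <- data.frame(site_id = sprintf("s%04d", seq_len(n_sites)),
                        cell_id = cells$cell_id[cell_of_site],
                        x = sx, y = sy, lon = sll$lon, lat = sll$lat,
                        stringsAsFactors = FALSE)
    structure(list(cells = cells, sites = sites, crs = crs,
                   cell_size = cell_size, lat_range = lat_range),
              class = "landscape")
  })
}

#' Simulate survey counts from the hierarchical trend model
#'
#' Draws, in order: cell slope effects `b_q ~ N(gamma * L_q, sigma_b)`, site
#' slope effects `d_i ~ N(b_q(i), sigma_d)`, site intercepts
#' `alpha_i ~ N(alpha_mean, alpha_sd)`, observation-level residuals
#' `e_it ~ N(0, sigma_e)`, and counts
#' `N_it ~ Poisson(exp(alpha_i + (beta0 + d_i) * t + e_it))` with
#' `t = year - center`. A fraction of site-years is then deleted uniformly at
#' random, mimicking unbalanced survey coverage.
#'
#' @param landscape A [generate_landscape()] result.
#' @param truth A [truth_params()] list.
#' @param years Calendar years surveyed (default 2002-2012).
#' @param missing_frac Fraction of site-year records deleted at random in
#'   `[0, 1)`.
#' @param center Year at which `t` is centered.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A [survey_table()] with attribute `"truth"`: a list holding the
#'   drawn `alpha`, `d` (per site), `b` (per cell) and the input parameters.
#' @export
generate_counts <- function(landscape, truth = truth_params(),
                            years = 2002:2012, missing_frac = 0.15,
                            center = 2007, seed = 1) {
  stopifnot(inherits(landscape, "landscape"))
  if (!inherits(truth, "truth_params")) truth <- do.call(truth_params, truth)
  if (!length(years)) stop_arg("`years` must be non-empty")
  missing_frac <- check_number(missing_frac, "missing_frac", lower = 0, upper = 1)
  if (missing_frac >= 1) stop_arg("`missing_frac` must be < 1")

  cells <- landscape$cells
  sites <- landscape$sites
  n_sites <- nrow(sites)
  cell_idx <- match(sites$cell_id, cells$cell_id)

  with_seed(seed, {
    b <- rnorm(nrow(cells), truth$gamma * cells$lat, truth$sigma_b)
    d <- rnorm(n_sites, b[cell_idx], truth$sigma_d)
    alpha <- rnorm(n_sites, truth$alpha_mean, truth$alpha_sd)
    recs <- expand.grid(site = seq_len(n_sites), year = years,
                        KEEP.OUT.ATTRS = FALSE)
    tt <- recs$year - center
    e <- rnorm(nrow(recs), 0, truth$sigma_e)
    eta <- alpha[recs$site] + (truth$beta0 + d[recs$site]) * tt + e
    count <- rpois(nrow(recs), exp(eta))
    if (missing_frac > 0) {
      drop <- sample.int(nrow(recs), size = floor(missing_frac * nrow(recs)))
      if (length(drop)) {
        recs <- recs[-drop, , drop = FALSE]
        count <- count[-drop]
        e <- e[-drop]
        tt <- tt[-drop]
      }
    }
    records <- data.frame(site_id = sites$site_id[recs$site],
                          year = recs$year, count = count,
                          stringsAsFactors = FALSE)
    ord <- order(match(records$site_id, sites$site_id), records$year)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    tab <- survey_table(records,
                        sites[, c("site_id", "lon", "lat", "x", "y")],
                        crs = landscape$crs)
    tab <- center_years(tab, center)
    attr(tab, "truth") <- list(params = truth, alpha = alpha, d = d, b = b,
                               e = e[ord], cell_of_site = cell_idx,
                               cell_lat = cells$lat, center = center)
    tab
  })
}
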