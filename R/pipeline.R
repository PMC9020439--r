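#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path or a plain list, applies documented defaults,
#' range-checks every numeric option, and rejects unknown keys (all
#' violations are reported at once). Either `input` (a counts CSV) or
#' `synthetic` (generator settings) must be given.
#'
#' @param config YAML path or named list. Recognized keys: `input`,
#'   `synthetic` (`n_cells`, `sites_per_cell`, `cluster_sd`, `lat_range`,
#'   `years`, `missing_frac`, `truth`), `min_years` (default 7), `center`
#'   (default 2007), `crs` (default `"ETRS89-LAEA"`), `cell_size` (default
#'   75000 m), `grid_origin`, `moran` (`style`, `null`, `alternative`,
#'   `jitter`), `control` (see [trend_control()]), `window` (total-decline
#'   duration, default 11), `latitudes` (summary latitudes, default
#'   c(46, 60)), `outdir`, `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_arg("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_arg("`config` must be a list or a YAML path")
  known <- c("input", "synthetic", "min_years", "center", "crs", "cell_size",
             "grid_origin", "moran", "control", "window", "latitudes",
             "outdir", "seed")
  problems <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  def_syn <- list(n_cells = 200, sites_per_cell = 5, cluster_sd = 15000,
                  lat_range = c(46, 60), years = 2002:2012,
                  missing_frac = 0.15, truth = list())
  def_moran <- list(style = "row", null = "randomization",
                    alternative = "greater", jitter = 1)
  out <- list(input = config$input %||% NULL,
              synthetic = NULL,
              min_years = config$min_years %||% 7,
              center = config$center %||% 2007,
              crs = config$crs %||% "ETRS89-LAEA",
              cell_size = config$cell_size %||% 75000,
              grid_origin = config$grid_origin %||% NULL,
              moran = def_moran,
              control = do.call(trend_control, config$control %||% list()),
              window = config$window %||% 11,
              latitudes = config$latitudes %||% c(46, 60),
              outdir = config$outdir %||% NULL,
              seed = config$seed %||% 1)
  if (!is.null(config$synthetic)) {
    unk <- setdiff(names(config$synthetic), names(def_syn))
    if (length(unk)) {
      problems <- c(problems, sprintf("unknown synthetic key(s): %s",
                                      paste(unk, collapse = ", ")))
    }
    def_syn[names(config$synthetic)] <- config$synthetic
    out$synthetic <- def_syn
  }
  if (!is.null(config$moran)) {
    unk <- setdiff(names(config$moran), names(def_moran))
    if (length(unk)) {
      problems <- c(problems, sprintf("unknown moran key(s): %s",
                                      paste(unk, collapse = ", ")))
    }
    out$moran[names(config$moran)] <- config$moran
  }
  if (is.null(out$input) && is.null(out$synthetic)) {
    problems <- c(problems, "one of `input` or `synthetic` is required")
  }
  if (!is.null(out$input) && !file.exists(out$input)) {
    problems <- c(problems, sprintf("input file not found: %s", out$input))
  }
  chk <- function(val, name, lower, upper = Inf) {
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < lower || val > upper) {
      problems <<- c(problems, sprintf("`%s` out of range [%s, %s]",
                                       name, format(lower), format(upper)))
    }
  }
  chk(out$min_years, "min_years", 1)
  chk(out$center, "center", 1800, 2200)
  chk(out$cell_size, "cell_size", 1)
  chk(out$window, "window", 1)
  chk(out$seed, "seed", -2^31, 2^31)
  if (!is.null(out$synthetic)) {
    chk(out$synthetic$n_cells, "synthetic.n_cells", 1)
    chk(out$synthetic$missing_frac, "synthetic.missing_frac", 0, 0.999)
  }
  if (!out$moran$style %in% c("row", "binary")) {
    problems <- c(problems, "`moran.style` must be 'row' or 'binary'")
  }
  if (length(problems)) {
    stop(paste(c("invalid configuration:", paste(" -", problems)),
               collapse = "\n"), call. = FALSE)
  }
  structure(out, class = "pipeline_config")
}

#' Run the full trend-estimation pipeline
#'
#' Executes the complete workflow in order: load or simulate counts; apply
#' the coverage retention filter and year centering; project coordinates;
#' fit the preliminary site-slope model and test its site slopes for spatial
#' autocorrelation (Moran's I on a relative neighborhood graph — the
#' diagnosis that motivates gridding); overlay the metric grid and assign
#' sites to cells; fit the hierarchical model; re-test the predicted random
#' effects for residual autocorrelation at site and cell level; and derive
#' the trend summaries and diagnostics. All tables and layers are written to
#' `config$outdir` (when set) and the run is fully deterministic given the
#' config.
#'
#' @param config A [validate_config()] input or result.
#' @return A list of class `trend_report` (stage log, record counts,
#'   preliminary summary, Moran results pre/post, parameter table, trend
#'   summaries, diagnostics, provenance).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  stages <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    stages <<- c(stages, msg)
    message("[gridtrend] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    tab <- read_counts(config$input)
    note("loaded %d records / %d sites from %s",
         nrow(tab$records), nrow(tab$sites), config$input)
  } else {
    syn <- config$synthetic
    land <- generate_landscape(syn$n_cells,
                               lat_range = syn$lat_range,
                               sites_per_cell = if (length(syn$sites_per_cell) > 1)
                                 unlist(syn$sites_per_cell) else syn$sites_per_cell,
                               cluster_sd = syn$cluster_sd,
                               cell_size = config$cell_size,
                               crs = config$crs, seed = config$seed)
    truth <- do.call(truth_params, syn$truth)
    tab <- generate_counts(land, truth, years = unlist(syn$years),
                           missing_frac = syn$missing_frac,
                           center = config$center, seed = config$seed + 1)
    note("simulated %d records / %d sites in %d cells",
         nrow(tab$records), nrow(tab$sites), nrow(land$cells))
  }
  n_input_sites <- nrow(tab$sites)

  tab <- filter_by_coverage(tab, config$min_years)
  note("retention filter (>= %d years): %d of %d sites kept",
       config$min_years, nrow(tab$sites), n_input_sites)
  tab <- center_years(tab, config$center)
  tab <- project_coordinates(tab, config$crs)

  # --- preliminary model and spatial diagnosis ----------------------------
  prelim <- stage("preliminary fit", fit_preliminary(tab, config$control))
  note("preliminary fit: mean slope %.4f (SE %.4f)",
       prelim$coef["mu"], sqrt(diag(prelim$vcov))[1])
  pre_sites <- predict_random_effects(prelim, se = FALSE)$sites
  xy <- as.matrix(tab$sites[, c("x", "y")])
  rownames(xy) <- tab$sites$site_id
  graph <- relative_neighborhood_graph(xy, jitter = config$moran$jitter)
  w <- to_weights(graph, style = config$moran$style)
  moran_pre <- morans_test(pre_sites$slope, w, null = config$moran$null,
                           alternative = config$moran$alternative)
  note("pre-grid Moran on site slopes: I = %.3f, p = %.4g",
       moran_pre$I, moran_pre$p.value)

  # --- grid standardization and hierarchical fit --------------------------
  grid <- stage("gridding",
                build_grid(tab, config$cell_size, origin = config$grid_origin))
  asn <- stage("gridding", assign_sites(tab, grid))
  note("grid: %d occupied cells of %g km", nrow(asn$cells),
       config$cell_size / 1000)
  fit <- stage("hierarchical fit",
               fit_hierarchical(tab, asn, config$control))
  note("hierarchical fit: beta0 = %.3f, gamma = %.4f%s",
       fit$coef["beta0"], fit$coef["gamma"],
       if (fit$convergence$converged) "" else " [NOT CONVERGED]")
  pred <- predict_random_effects(fit, se = TRUE)

  # residual autocorrelation is tested on the slope deviations (v at site
  # level, u at cell level): the fitted latitude gradient is mean structure,
  # not autocorrelation to be diagnosed
  moran_post_site <- morans_test(pred$sites$v, w, null = config$moran$null,
                                 alternative = config$moran$alternative)
  cxy <- as.matrix(asn$cells[, c("cx", "cy")])
  rownames(cxy) <- asn$cells$cell_id
  moran_post_cell <- if (nrow(cxy) >= 4) {
    gc <- relative_neighborhood_graph(cxy)
    morans_test(pred$cells$u, to_weights(gc, style = config$moran$style),
                null = config$moran$null,
                alternative = config$moran$alternative)
  } else NULL
  note("post-fit Moran: site I = %.3f (p = %.3g)%s — spatial autocorrelation %s",
       moran_post_site$I, moran_post_site$p.value,
       if (!is.null(moran_post_cell))
         sprintf(", cell I = %.3f (p = %.3g)", moran_post_cell$I,
                 moran_post_cell$p.value) else "",
       if (moran_post_site$p.value > 0.05) "removed" else "REMAINING")

  # --- summaries ----------------------------------------------------------
  se_all <- sqrt(pmax(diag(fit$vcov), 0))
  params <- data.frame(
    parameter = c(names(fit$coef), names(fit$sigmas)),
    estimate = c(unname(fit$coef), unname(fit$sigmas)),
    se = c(unname(se_all[seq_along(fit$coef)]), unname(fit$sigma_se)))
  flyway <- flyway_mean_trend(fit, asn, D = config$window)
  decline <- do.call(rbind, lapply(config$latitudes, function(L) {
    data.frame(latitude = L,
               annual_pct = percent_change(fit$coef["beta0"],
                                           fit$coef["gamma"], L, D = 1),
               annual_se = percent_change_se(fit, L, D = 1),
               total_pct = percent_change(fit$coef["beta0"],
                                          fit$coef["gamma"], L,
                                          D = config$window),
               total_se = percent_change_se(fit, L, D = config$window),
               cell_lo = typical_range(fit, L, "cell")[1],
               cell_hi = typical_range(fit, L, "cell")[2],
               site_lo = typical_range(fit, L, "site")[1],
               site_hi = typical_range(fit, L, "site")[2])
  }))
  rownames(decline) <- NULL
  yrs <- sort(unique(fit$data$year))
  traj <- do.call(rbind, lapply(config$latitudes, function(L) {
    cbind(latitude = L, expected_trajectory(fit, L, yrs))
  }))
  corr <- intercept_slope_correlation(fit)
  diagnostics <- residual_diagnostics(fit)
  note("flyway mean decline %.1f%%/yr (SE %.1f), %.1f%% over %d years",
       flyway$annual_pct, flyway$annual_se, flyway$total_pct, config$window)

  report <- structure(list(
    stages = stages,
    counts = list(input_sites = n_input_sites, retained = nrow(tab$sites),
                  dropped = n_input_sites - nrow(tab$sites),
                  records = nrow(tab$records), cells = nrow(asn$cells)),
    preliminary = list(mu = unname(prelim$coef["mu"]),
                       se = unname(sqrt(diag(prelim$vcov))[1]),
                       sigmas = as.list(prelim$sigmas),
                       converged = prelim$convergence$converged),
    vcov = fit$vcov,
    moran = list(pre_site = unclass(moran_pre),
                 post_site = unclass(moran_post_site),
                 post_cell = if (!is.null(moran_post_cell))
                   unclass(moran_post_cell) else NULL),
    params = params,
    flyway = flyway,
    decline = decline,
    correlation_intercept_slope = corr,
    diagnostics = diagnostics,
    convergence = fit$convergence,
    provenance = list(seed = config$seed, package = "gridtrend",
                      version = as.character(utils::packageVersion("gridtrend")))),
    class = "trend_report")

  # --- artifacts ----------------------------------------------------------
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_counts(tab, p("counts.csv"))
    utils::write.csv(merge(asn$sites,
                           asn$cells[, c("cell_id", "lat")], by = "cell_id")[
                             , c("site_id", "cell_id", "lat")],
                     p("assignment.csv"), row.names = FALSE, quote = FALSE)
    geojson_sites(tab, p("sites.geojson"))
    geojson_cells(asn, p("cells.geojson"),
                  values = list(slope = pred$cells$slope))
    utils::write.csv(data.frame(from = graph$ids[graph$edges[, 1]],
                                to = graph$ids[graph$edges[, 2]]),
                     p("graph_edges.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(params, p("params.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(pred$cells, p("effects_cells.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(pred$sites, p("effects_sites.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(traj, p("trajectory.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(decline, p("decline.csv"), row.names = FALSE,
                     quote = FALSE)
    rep_json <- report
    rep_json$diagnostics <- list(normality = diagnostics$normality,
                                 by_year = diagnostics$by_year)
    jsonlite::write_json(rep_json, p("report.json"), auto_unbox = TRUE,
                         digits = 12, force = TRUE)
    note("artifacts written to %s", config$outdir)
    report$stages <- stages
  }
  report
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report>\n")
  for (s in x$stages) cat(" -", s, "\n")
  invisible(x)
}
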