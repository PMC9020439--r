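# Headline trend summaries: percentage declines, typical ranges, flyway
# mean, intercept-slope correlation, trajectory bands.

# Accept either a fitted model or a plain parameter list wherever only
# (beta0, gamma, sigma_b, sigma_d) are needed.
.trend_pars <- function(object) {
  if (inherits(object, "trend_fit")) {
    list(beta0 = unname(object$coef["beta0"]),
         gamma = unname(object$coef["gamma"]),
         sigma_b = unname(object$sigmas["sigma_b"]),
         sigma_d = unname(object$sigmas["sigma_d"]))
  } else {
    list(beta0 = object$beta0 %||% 0, gamma = object$gamma %||% 0,
         sigma_b = object$sigma_b %||% NA_real_,
         sigma_d = object$sigma_d %||% NA_real_)
  }
}

#' Median percentage decline over a duration
#'
#' `r = 100 * (1 - exp(D * (beta0 + gamma * L)))`: the median percentage
#' change in counts at latitude `L` over `D` years, positive values meaning
#' decline.
#'
#' @param beta0 Year slope on the log scale (or a full annual log-trend if
#'   `gamma = 0, L = 0`).
#' @param gamma Latitude effect per degree.
#' @param L Latitude in degrees.
#' @param D Duration in years; `D = 0` gives `r = 0`.
#' @return Percentage decline (a number `<= 100`).
#' @export
percent_change <- function(beta0, gamma = 0, L = 0, D = 1) {
  stopifnot(is.finite(beta0), is.finite(gamma), all(is.finite(L)),
            all(is.finite(D)))
  100 * (1 - exp(D * (beta0 + gamma * L)))
}

#' Delta-method SE of the percentage decline
#'
#' First-order propagation of the covariance of `(beta0, gamma)` through
#' [percent_change()]: with `m = beta0 + gamma * L`,
#' `SE(r) = |100 * D * exp(D * m)| * SE(m)` and
#' `SE(m)^2 = Var(beta0) + L^2 Var(gamma) + 2 L Cov(beta0, gamma)`.
#'
#' @param fit A converged hierarchical [trend_fit][fit_hierarchical()].
#' @param L Latitude in degrees.
#' @param D Duration in years.
#' @return SE of the percentage decline, in percentage points.
#' @export
percent_change_se <- function(fit, L, D = 1) {
  stopifnot(inherits(fit, "trend_fit"))
  V <- fit$vcov
  if (!all(c("beta0", "gamma") %in% rownames(V))) {
    stop_arg("fit lacks a (beta0, gamma) covariance")
  }
  m <- unname(fit$coef["beta0"] + fit$coef["gamma"] * L)
  se_m <- sqrt(V["beta0", "beta0"] + L^2 * V["gamma", "gamma"] +
                 2 * L * V["beta0", "gamma"])
  abs(100 * D * exp(D * m)) * se_m
}

#' Flyway-average trend
#'
#' The spatial mean trend over the surveyed range: the equal-weight average
#' over occupied grid cells of the cell mean log-slope `beta0 + gamma * L_q`
#' (each standardized sampling unit counts once), with a delta-method SE, and
#' its expression as annual and whole-window percentage declines.
#'
#' @param fit A converged hierarchical [trend_fit][fit_hierarchical()].
#' @param assignment The [assign_sites()] result used in the fit.
#' @param D Window length in years for the total decline (default 11).
#' @return A list: `log_trend`, `se`, `annual_pct`, `annual_se`,
#'   `total_pct`, `total_se`, `D`.
#' @export
flyway_mean_trend <- function(fit, assignment, D = 11) {
  stopifnot(inherits(fit, "trend_fit"))
  L <- cell_latitudes(assignment)
  Lbar <- mean(L)
  m <- unname(fit$coef["beta0"] + fit$coef["gamma"] * Lbar)
  se_m <- {
    V <- fit$vcov
    sqrt(V["beta0", "beta0"] + Lbar^2 * V["gamma", "gamma"] +
           2 * Lbar * V["beta0", "gamma"])
  }
  list(log_trend = m, se = se_m,
       annual_pct = percent_change(m, D = 1),
       annual_se = abs(100 * exp(m)) * se_m,
       total_pct = percent_change(m, D = D),
       total_se = abs(100 * D * exp(D * m)) * se_m,
       D = D)
}

#' Typical range of annual declines across cells or sites
#'
#' The one-SD range of annual percentage declines implied by the random-slope
#' spread around the mean trend at latitude `L`: with `m = beta0 + gamma * L`
#' and `sigma` the cell-level (`sigma_b`) or site-level (`sigma_d`) slope SD,
#' returns `100 * (1 - exp(m + sigma))` (the milder decline) and
#' `100 * (1 - exp(m - sigma))` (the steeper one).
#'
#' @param object A hierarchical [trend_fit][fit_hierarchical()], or a plain
#'   list with `beta0` (and optionally `gamma`, `sigma_b`, `sigma_d`), so
#'   printed parameter values can be plugged in directly.
#' @param L Latitude in degrees.
#' @param level `"cell"` (spread of cell mean slopes, `sigma_b`) or `"site"`
#'   (spread of site slopes around their cell mean, `sigma_d`).
#' @return Named vector `c(lower, upper)` of annual percentage declines
#'   (lower = milder).
#' @export
typical_range <- function(object, L = 60, level = c("cell", "site")) {
  level <- match.arg(level)
  p <- .trend_pars(object)
  m <- p$beta0 + p$gamma * L
  s <- if (level == "cell") p$sigma_b else p$sigma_d
  if (!is.finite(s)) stop_arg("no %s-level slope SD available", level)
  c(lower = percent_change(m + s), upper = percent_change(m - s))
}

#' Correlation between site intercepts and site slopes
#'
#' Pearson correlation across sites between the fitted intercept
#' `alpha_i` (log mean count at the centering year) and the fitted site
#' slope (`beta0 + d_i`); a value near zero means the rate of decline does
#' not depend on how many animals a site holds.
#'
#' @param fit A converged [trend_fit][fit_hierarchical()].
#' @return The correlation coefficient; with exactly 3 sites or a degenerate
#'   two-site configuration the result carries attribute `degenerate = TRUE`.
#' @export
intercept_slope_correlation <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  if (length(fit$alpha) < 3) stop_arg("need >= 3 sites for a meaningful correlation")
  slopes <- predict_random_effects(fit, se = FALSE)$sites$slope
  if (stats::sd(fit$alpha) == 0 || stats::sd(slopes) == 0) {
    stop_arg("zero variance in intercepts or slopes: correlation undefined")
  }
  stats::cor(as.numeric(fit$alpha), slopes)
}

#' Expected count trajectory with nested interval bands
#'
#' The fitted log-scale trajectory `m * t` at latitude `L` (relative to the
#' centering year, where all bands have zero width), with three nested 95%
#' bands: the Wald band on the mean trend (`SE(m) |t|`), the prediction band
#' for a grid cell (adds the cell slope spread `sigma_b` in quadrature), and
#' the prediction band for a site (adds `sigma_d` as well).
#'
#' @param fit A converged hierarchical [trend_fit][fit_hierarchical()].
#' @param L Latitude in degrees.
#' @param years Calendar years to evaluate.
#' @return data.frame with `year`, `t`, `log_mean`, and `lo`/`hi` columns for
#'   the `mean`, `cell` and `site` bands (log scale, relative to the
#'   centering-year level).
#' @export
expected_trajectory <- function(fit, L, years) {
  stopifnot(inherits(fit, "trend_fit"))
  V <- fit$vcov
  m <- unname(fit$coef["beta0"] + fit$coef["gamma"] * L)
  se_m <- sqrt(V["beta0", "beta0"] + L^2 * V["gamma", "gamma"] +
                 2 * L * V["beta0", "gamma"])
  sb <- unname(fit$sigmas["sigma_b"])
  sd_ <- unname(fit$sigmas["sigma_d"])
  tt <- years - fit$data$center
  hw_mean <- 1.96 * se_m * abs(tt)
  hw_cell <- 1.96 * sqrt(se_m^2 + sb^2) * abs(tt)
  hw_site <- 1.96 * sqrt(se_m^2 + sb^2 + sd_^2) * abs(tt)
  data.frame(year = years, t = tt, log_mean = m * tt,
             mean_lo = m * tt - hw_mean, mean_hi = m * tt + hw_mean,
             cell_lo = m * tt - hw_cell, cell_hi = m * tt + hw_cell,
             site_lo = m * tt - hw_site, site_hi = m * tt + hw_site)
}
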