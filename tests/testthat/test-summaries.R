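test_that("percentage-decline arithmetic reproduces its closed form and limits", {
  expect_equal(percent_change(-0.1, D = 0), 0)
  expect_equal(percent_change(log(0.9), D = 1), 10)
  # monotonicity: steeper trend or longer window, larger decline
  expect_gt(percent_change(-0.2, D = 5), percent_change(-0.1, D = 5))
  expect_gt(percent_change(-0.1, D = 10), percent_change(-0.1, D = 5))
  # round-trip between annual rate and D-year total
  a <- percent_change(-0.07, -0.01, L = 55, D = 1)
  expect_equal(100 * (1 - (1 - a / 100)^9),
               percent_change(-0.07, -0.01, L = 55, D = 9),
               tolerance = 1e-12)
})

test_that("published derived percentages follow from the printed inputs", {
  # 11.6 %/yr at 60 deg over the 11-year window -> 74% total
  expect_equal(percent_change(log(1 - 0.116), D = 11), 74, tolerance = 0.5 / 74)
  # 4.9 %/yr flyway average -> 42.3% total
  expect_equal(percent_change(log(1 - 0.049), D = 11), 42.3,
               tolerance = 0.5 / 42.3)
  # typical one-SD ranges around the 11.6%/yr cell trend
  site <- typical_range(list(beta0 = log(1 - 0.116), sigma_d = 0.073),
                        L = 60, level = "site")
  expect_equal(unname(site[1]), 5, tolerance = 0.5 / 5)
  expect_equal(unname(site[2]), 17.9, tolerance = 0.5 / 17.9)
  cell <- typical_range(list(beta0 = log(1 - 0.116), sigma_b = 0.033),
                        L = 60, level = "cell")
  expect_equal(unname(cell[1]), 8.8, tolerance = 0.5 / 8.8)
  expect_equal(unname(cell[2]), 14.6, tolerance = 0.5 / 14.6)
})

test_that("typical range collapses continuously to the point decline", {
  p0 <- percent_change(log(1 - 0.116))
  for (s in c(0.05, 0.01, 0.001, 0)) {
    r <- typical_range(list(beta0 = log(1 - 0.116), sigma_b = s), level = "cell")
    expect_lte(r[1], p0 + 1e-12)
    expect_gte(r[2], p0 - 1e-12)
    expect_lt(abs(r[2] - r[1]), 250 * s + 1e-9)
  }
  r0 <- typical_range(list(beta0 = log(1 - 0.116), sigma_b = 0), level = "cell")
  expect_equal(unname(r0), c(p0, p0))
})

# a minimal fit-like object for the delta-method and trajectory arithmetic
fake_fit <- function(beta0, gamma, V, sb = 0.03, sdd = 0.07, center = 2007) {
  structure(list(kind = "hierarchical",
                 coef = c(beta0 = beta0, gamma = gamma),
                 sigmas = c(sigma_b = sb, sigma_d = sdd, sigma_e = 1),
                 vcov = V, alpha = numeric(0),
                 data = list(center = center)),
            class = "trend_fit")
}

test_that("delta-method SE matches finite-difference propagation", {
  V <- matrix(c(1e-4, 0, 0, 0, 1e-4, 0, 0, 0, 0), 3, 3,
              dimnames = rep(list(c("beta0", "gamma", "log_sigma_b")), 2))
  fit <- fake_fit(-0.1, 0.0, V)
  got <- percent_change_se(fit, L = 50, D = 1)
  # numeric propagation: sample the quadratic form directly
  f <- function(b0, g) percent_change(b0, g, L = 50, D = 1)
  h <- 1e-6
  gb <- (f(-0.1 + h, 0) - f(-0.1 - h, 0)) / (2 * h)
  gg <- (f(-0.1, h) - f(-0.1, -h)) / (2 * h)
  want <- sqrt(gb^2 * 1e-4 + gg^2 * 1e-4)
  expect_equal(got, want, tolerance = 1e-7)
  # zero covariance, zero SE
  fit0 <- fake_fit(-0.1, 0, V * 0)
  expect_equal(percent_change_se(fit0, L = 50, D = 1), 0)
})

test_that("trajectory bands are zero-width at the centering year and nest", {
  V <- matrix(c(4e-4, -6e-6, 0, -6e-6, 2e-7, 0, 0, 0, 0), 3, 3,
              dimnames = rep(list(c("beta0", "gamma", "log_sigma_b")), 2))
  fit <- fake_fit(0.38, -0.008, V, sb = 0.033, sdd = 0.073)
  tr <- expected_trajectory(fit, L = 60, years = 2002:2012)
  at0 <- tr[tr$year == 2007, ]
  expect_equal(at0$mean_lo, at0$mean_hi)
  expect_equal(at0$site_lo, at0$site_hi)
  expect_true(all(tr$site_lo <= tr$cell_lo & tr$cell_lo <= tr$mean_lo))
  expect_true(all(tr$mean_hi <= tr$cell_hi & tr$cell_hi <= tr$site_hi))
  # hand computation at t = 5
  m <- 0.38 - 0.008 * 60
  se_m <- sqrt(4e-4 + 60^2 * 2e-7 + 2 * 60 * -6e-6)
  row5 <- tr[tr$year == 2012, ]
  expect_equal(row5$log_mean, 5 * m, tolerance = 1e-12)
  expect_equal(row5$mean_hi - row5$log_mean, 1.96 * se_m * 5, tolerance = 1e-12)
  expect_equal(row5$cell_hi - row5$log_mean,
               1.96 * sqrt(se_m^2 + 0.033^2) * 5, tolerance = 1e-12)
  expect_equal(row5$site_hi - row5$log_mean,
               1.96 * sqrt(se_m^2 + 0.033^2 + 0.073^2) * 5, tolerance = 1e-12)
})

test_that("flyway mean trend averages occupied cells with equal weight", {
  land <- generate_landscape(12, sites_per_cell = 2, seed = 101)
  tab <- generate_counts(land, truth_params(), seed = 102)
  asn <- assign_sites(tab, build_grid(tab))
  V <- matrix(1e-4 * diag(3), 3, 3,
              dimnames = rep(list(c("beta0", "gamma", "log_sigma_b")), 2))
  fit <- fake_fit(0.38, -0.008, V)
  fw <- flyway_mean_trend(fit, asn, D = 11)
  expect_equal(fw$log_trend, 0.38 - 0.008 * mean(asn$cells$lat))
  expect_equal(fw$annual_pct, percent_change(fw$log_trend))
  expect_equal(fw$total_pct, percent_change(fw$log_trend, D = 11))
  # identical latitudes: the mean trend is beta0 + gamma * L exactly
  asn$cells$lat <- rep(55, nrow(asn$cells))
  fw2 <- flyway_mean_trend(fit, asn)
  expect_equal(fw2$log_trend, 0.38 - 0.008 * 55)
})

test_that("intercept-slope correlation detects planted dependence and independence", {
  land <- generate_landscape(80, sites_per_cell = 3, seed = 111)
  tab <- filter_by_coverage(generate_counts(land, truth_params(), seed = 112), 7)
  asn <- assign_sites(tab, build_grid(tab))
  fit <- fit_hierarchical(tab, asn)
  # generator draws intercepts independently of slopes
  expect_lt(abs(intercept_slope_correlation(fit)), 0.15)

  # planted signal: slopes tied to intercepts
  truth <- attr(tab, "truth")
  set.seed(113)
  yrs <- 2002:2012
  n <- nrow(tab$sites)
  alpha <- rnorm(n, 3, 1)
  slope <- -0.1 * (alpha - mean(alpha)) + rnorm(n, 0, 0.01)
  recs <- data.frame(site_id = rep(tab$sites$site_id, each = 11),
                     year = rep(yrs, n),
                     count = rpois(n * 11, exp(rep(alpha, each = 11) +
                                                 rep(slope, each = 11) *
                                                   rep(yrs - 2007, n))))
  tabp <- center_years(survey_table(recs, tab$sites), 2007)
  fitp <- fit_hierarchical(tabp, asn)
  expect_lt(intercept_slope_correlation(fitp), -0.8)
})
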