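test_that("preliminary model recovers known generating parameters", {
  land <- generate_landscape(100, sites_per_cell = 3, seed = 51)
  truth <- truth_params(beta0 = -0.05, gamma = 0, sigma_b = 0,
                        sigma_d = 0.07, sigma_e = 1.0)
  tab <- generate_counts(land, truth, missing_frac = 0.1, seed = 52)
  tab <- filter_by_coverage(tab, 7)
  fit <- fit_preliminary(tab)
  expect_true(fit$convergence$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef[["mu"]] - (-0.05)), 2 * se[["mu"]])
  expect_lt(abs(fit$sigmas[["sigma_d"]] - 0.07), 2 * fit$sigma_se[["sigma_d"]])
  expect_lt(abs(fit$sigmas[["sigma_e"]] - 1.0), 2 * fit$sigma_se[["sigma_e"]])
  # predicted site slopes exist for every site
  pred <- predict_random_effects(fit)
  expect_equal(nrow(pred$sites), nrow(tab$sites))
  expect_null(pred$cells)
})

test_that("preliminary fit rejects sites with a single surveyed year", {
  recs <- rbind(data.frame(site_id = "a", year = 2002:2005, count = 3:6),
                data.frame(site_id = "b", year = 2004, count = 2))
  tab <- center_years(survey_table(recs, data.frame(
    site_id = c("a", "b"), lon = 1:2, lat = c(50, 51))), 2007)
  expect_error(fit_preliminary(tab), "b")
})

test_that("hierarchical fit is invariant to latitude shift and relabeling", {
  land <- generate_landscape(24, sites_per_cell = 3, seed = 61)
  tab <- filter_by_coverage(generate_counts(land, truth_params(),
                                            seed = 62), 7)
  asn <- assign_sites(tab, build_grid(tab))
  fit <- fit_hierarchical(tab, asn)
  expect_true(fit$convergence$converged)

  # latitude shifted by +c: gamma and sigmas unchanged, beta0 absorbs -gamma*c
  asn2 <- asn
  asn2$cells$lat <- asn2$cells$lat + 5
  fit2 <- fit_hierarchical(tab, asn2)
  expect_equal(fit2$coef[["gamma"]], fit$coef[["gamma"]], tolerance = 1e-3)
  expect_equal(fit2$coef[["beta0"]],
               fit$coef[["beta0"]] - 5 * fit$coef[["gamma"]],
               tolerance = 1e-3)
  expect_equal(unname(fit2$sigmas), unname(fit$sigmas), tolerance = 1e-3)
  # fitted cell slopes beta0 + b_q unchanged
  expect_equal(predict_random_effects(fit2, se = FALSE)$cells$slope,
               predict_random_effects(fit, se = FALSE)$cells$slope,
               tolerance = 1e-3)

  # relabeling sites/records leaves the likelihood and estimates unchanged
  perm <- rev(seq_len(nrow(tab$records)))
  tab3 <- tab
  tab3$records <- tab$records[perm, ]
  tab3$sites <- tab$sites[rev(seq_len(nrow(tab$sites))), ]
  rownames(tab3$records) <- rownames(tab3$sites) <- NULL
  fit3 <- fit_hierarchical(tab3, asn)
  expect_equal(fit3$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit3$coef, fit$coef, tolerance = 1e-5)
})

test_that("refitting after a different year centering changes nothing but the origin", {
  land <- generate_landscape(16, sites_per_cell = 3, seed = 71)
  tab <- generate_counts(land, truth_params(), seed = 72)
  asn <- assign_sites(tab, build_grid(tab))
  f7 <- fit_hierarchical(center_years(tab, 2007), asn)
  f5 <- fit_hierarchical(center_years(tab, 2005), asn)
  expect_equal(f5$coef[["beta0"]], f7$coef[["beta0"]], tolerance = 5e-3)
  expect_equal(f5$coef[["gamma"]], f7$coef[["gamma"]], tolerance = 5e-3)
  expect_equal(unname(f5$sigmas), unname(f7$sigmas), tolerance = 0.02)
})

test_that("random-effect predictions shrink and center as the penalty dictates", {
  land <- generate_landscape(30, sites_per_cell = 3, seed = 81)
  tab <- filter_by_coverage(generate_counts(land, truth_params(),
                                            seed = 82), 7)
  asn <- assign_sites(tab, build_grid(tab))
  fit <- fit_hierarchical(tab, asn)
  pred <- predict_random_effects(fit)
  expect_true(all(is.finite(pred$cells$se)))
  expect_true(all(pred$cells$se > 0))
  # shrinkage: cell effects predicted with near-zero overall mean
  expect_lt(abs(mean(pred$cells$u)), 2 * sd(pred$cells$u) / sqrt(nrow(pred$cells)) + 1e-3)
  # site deviations v shrink toward zero relative to raw per-site slopes
  raw_dev <- vapply(seq_len(nrow(tab$sites)), function(i) {
    r <- tab$records[tab$records$site_id == tab$sites$site_id[i], ]
    ft <- stats::glm(count ~ t, family = stats::poisson, data = r)
    unname(stats::coef(ft)["t"]) -
      pred$cells$slope[match(pred$sites$cell_id[i], pred$cells$cell_id)]
  }, numeric(1))
  expect_lt(mean(abs(pred$sites$v)), mean(abs(raw_dev)))
})

test_that("residual diagnostics are calibrated under the true model and flag misfit", {
  land <- generate_landscape(40, sites_per_cell = 3, seed = 91)
  tab <- filter_by_coverage(generate_counts(land, truth_params(),
                                            seed = 92), 7)
  asn <- assign_sites(tab, build_grid(tab))
  fit <- fit_hierarchical(tab, asn)
  d <- residual_diagnostics(fit)
  expect_true(all(c("cell", "site") %in% d$normality$level))
  expect_true(all(abs(d$normality$skewness) < 1))
  expect_lte(sum(d$by_year$flag), 2)     # ~5% false-flag rate over 11 years

  # a quadratic true trend must leave a U-shaped residual pattern
  set.seed(93)
  yrs <- 2002:2012
  tt <- rep(yrs - 2007, 30)
  sid <- rep(sprintf("q%02d", 1:30), each = 11)
  lam <- exp(3 + -0.02 * tt + 0.05 * tt^2)
  tabq <- survey_table(data.frame(site_id = sid, year = rep(yrs, 30),
                                  count = rpois(length(tt), lam)),
                       data.frame(site_id = sprintf("q%02d", 1:30),
                                  lon = runif(30, 5, 7),
                                  lat = runif(30, 50, 51)))
  fq <- fit_preliminary(center_years(tabq, 2007))
  dq <- residual_diagnostics(fq)
  expect_gte(sum(dq$by_year$flag), 3)
  # U-pattern: extreme years high, middle years low
  ends <- dq$by_year$mean[dq$by_year$year %in% c(2002, 2012)]
  mid <- dq$by_year$mean[dq$by_year$year %in% 2006:2008]
  expect_gt(min(ends), max(mid))
})
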