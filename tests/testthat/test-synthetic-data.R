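test_that("default truth parameters carry the published hierarchical estimates", {
  tp <- truth_params()
  expect_equal(tp$beta0, 0.38)
  expect_equal(tp$gamma, -0.008)
  expect_equal(tp$sigma_b, 0.033)
  expect_equal(tp$sigma_d, 0.073)
  expect_equal(tp$sigma_e, 1.18)
  expect_error(truth_params(sigma_e = -1), "sigma_e")
})

test_that("landscape generation is deterministic and respects its contract", {
  one <- generate_landscape(1, sites_per_cell = 1, seed = 9)
  expect_equal(nrow(one$cells), 1L)
  expect_equal(nrow(one$sites), 1L)
  expect_equal(one$sites$cell_id, one$cells$cell_id)

  a <- generate_landscape(25, sites_per_cell = c(2, 8), seed = 4)
  b <- generate_landscape(25, sites_per_cell = c(2, 8), seed = 4)
  expect_identical(a, b)
  c2 <- generate_landscape(25, sites_per_cell = c(2, 8), seed = 5)
  expect_false(identical(a$sites$x, c2$sites$x))

  # every cell non-empty; at the survey's published scale the site count
  # lands near 5 per cell
  big <- generate_landscape(193, sites_per_cell = 5, seed = 1)
  expect_equal(nrow(big$cells), 193L)
  expect_equal(nrow(big$sites), 965L)
  expect_true(all(table(big$sites$cell_id) >= 1))
  expect_true(all(big$cells$lat > 44 & big$cells$lat < 62))

  expect_error(generate_landscape(0), "n_cells")
  expect_error(generate_landscape(5, lat_range = c(60, 46)), "lat_range")
  expect_error(generate_landscape(5, sites_per_cell = 0), ">= 1")
})

test_that("counts follow the generative model in the no-signal limit", {
  land <- generate_landscape(4, sites_per_cell = 2, seed = 2)
  tp <- truth_params(beta0 = 0, gamma = 0, sigma_b = 0, sigma_d = 0,
                     sigma_e = 0, alpha_mean = 3, alpha_sd = 0.5)
  tab <- generate_counts(land, tp, years = 1901:2000, missing_frac = 0,
                         center = 1950, seed = 7)
  truth <- attr(tab, "truth")
  expect_equal(truth$d, truth$b[truth$cell_of_site])
  ybar <- tapply(tab$records$count, tab$records$site_id, mean)
  lam <- exp(truth$alpha)
  # site means match exp(alpha_i) within Poisson error (100 years each)
  z <- (as.numeric(ybar[tab$sites$site_id]) - lam) / sqrt(lam / 100)
  expect_true(all(abs(z) < 4))
})

test_that("generator moments recover the declared SDs and means", {
  # 10^4 sites in a compact 200-cell block (so cell latitudes stay in range)
  land <- generate_landscape(200, sites_per_cell = 50, seed = 3)
  tab <- generate_counts(land, truth_params(), years = 2007,
                         missing_frac = 0, seed = 8)
  truth <- attr(tab, "truth")
  expect_equal(length(truth$d), 10000L)
  # site slope deviations around the cell mean have SD sigma_d = 0.073
  dev <- truth$d - truth$b[truth$cell_of_site]
  expect_equal(sd(dev), 0.073, tolerance = 0.02)
  # cell slopes around gamma * L have SD sigma_b (~3 MC SDs at 200 cells)
  expect_equal(sd(truth$b - (-0.008) * truth$cell_lat), 0.033,
               tolerance = 0.15)
  # near latitude 60 the expected cell log-slope is beta0 + gamma*60 = -0.10
  north <- abs(truth$cell_lat - 60) < 1
  expect_gt(sum(north), 4)
  expect_lt(abs(0.38 + mean(truth$b[north]) - (-0.008) * (mean(truth$cell_lat[north]) - 60) + 0.10), 3 * 0.033 / sqrt(sum(north)))
})

test_that("marginal mean at t = 0 matches the lognormal mixing identity", {
  land <- generate_landscape(2, sites_per_cell = 1, seed = 11)
  tp <- truth_params(beta0 = 0, gamma = 0, sigma_b = 0, sigma_d = 0,
                     sigma_e = 1, alpha_mean = 2, alpha_sd = 0)
  nrep <- 4000
  tab <- generate_counts(land, tp, years = seq_len(nrep) + 1000,
                         missing_frac = 0, center = 0, seed = 12)
  # kill the trend dependence: t varies, but beta0 + d = 0 exactly
  m <- mean(tab$records$count)
  target <- exp(2 + 1 / 2)          # E[N] = exp(alpha + sigma_e^2 / 2)
  se <- sd(tab$records$count) / sqrt(nrow(tab$records))
  expect_lt(abs(m - target), 3 * se)
})

test_that("missingness removes the requested fraction of site-years", {
  land <- generate_landscape(20, sites_per_cell = 5, seed = 5)
  tab <- generate_counts(land, truth_params(), missing_frac = 0.15, seed = 6)
  expect_equal(nrow(tab$records), 1100 - floor(0.15 * 1100))
  full <- generate_counts(land, truth_params(), missing_frac = 0, seed = 6)
  expect_equal(nrow(full$records), 1100)
})
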