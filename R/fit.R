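#' Optimizer controls for the trend-model fits
#'
#' @param inner_tol Gradient max-norm tolerance of the inner Newton solver
#'   over the random effects.
#' @param outer_rel_tol Relative tolerance of the outer quasi-Newton
#'   optimization of the Laplace objective.
#' @param outer_iter Maximum outer iterations.
#' @param grad_tol Convergence criterion for the outer problem: the Newton
#'   displacement implied by the finite-difference score at the optimum,
#'   measured in SE units, must stay below this fraction for every outer
#'   parameter.
#' @param sigma_start Initial value for all random-effect SDs; `NULL`
#'   (default) uses method-of-moments starting values derived from the data.
#' @param reml Integrate the site intercepts flat-prior into the Laplace
#'   determinant (REML-type objective, default)? With one intercept per site,
#'   plain ML biases the variance parameters low by a degrees-of-freedom
#'   factor; the REML-type objective removes it.
#' @return A list of class `trend_control`.
#' @export
trend_control <- function(inner_tol = 1e-9, outer_rel_tol = 1e-8,
                          outer_iter = 300L, grad_tol = 0.05,
                          sigma_start = NULL, reml = TRUE) {
  structure(list(inner_tol = inner_tol, outer_rel_tol = outer_rel_tol,
                 outer_iter = as.integer(outer_iter), grad_tol = grad_tol,
                 sigma_start = sigma_start, reml = isTRUE(reml)),
            class = "trend_control")
}

# Shared outer driver: maximizes the Laplace objective over
# (slope coefficients, log SDs), with site intercepts profiled inside the
# inner Newton solver.
.fit_laplace <- function(data, control) {
  k_sig <- 1L + data$use_cell + data$olre
  p <- ncol(data$X)
  sig_names <- c(if (data$use_cell) "log_sigma_b", "log_sigma_d",
                 if (data$olre) "log_sigma_e")

  # starting values: site intercepts at log site means, slopes from a
  # Poisson GLM with a common slope and the intercepts as offset
  ybar <- tapply(data$y, data$site, mean)
  alpha0 <- log(pmax(as.numeric(ybar[as.character(seq_len(data$S))]), 0.05))
  beta0 <- tryCatch(
    stats::glm.fit(data$X, data$y, offset = alpha0[data$site],
                   family = stats::poisson())$coefficients,
    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0

  # method-of-moments starting values for the SDs (they start the outer
  # optimization near the right order of magnitude): lognormal mixing gives
  # Var(y) = lambda + lambda^2 (exp(sigma_e^2) - 1), and the spread of crude
  # per-site log-count slopes bounds the slope SDs
  lam0 <- exp(alpha0[data$site] + as.numeric(data$X %*% beta0))
  cc <- mean((data$y - lam0)^2 - lam0) / mean(lam0^2)
  se0 <- min(max(sqrt(log1p(max(cc, 0.01))), 0.05), 3)
  z <- log(data$y + 0.5)
  slope_i <- vapply(split(seq_len(data$n), data$site), function(ix) {
    tt <- data$t[ix]
    if (length(ix) < 2 || stats::var(tt) == 0) return(NA_real_)
    stats::cov(tt, z[ix]) / stats::var(tt)
  }, numeric(1))
  sl_sd <- stats::sd(slope_i[is.finite(slope_i)])
  sd0 <- min(max(sl_sd / 2, 0.02), 1)
  sb0 <- min(max(sl_sd / 4, 0.01), 0.5)
  sig_start <- log(c(if (data$use_cell) sb0, sd0, if (data$olre) se0))
  if (!is.null(control$sigma_start)) {
    sig_start <- rep(log(control$sigma_start), k_sig)
  }

  state <- new.env(parent = emptyenv())
  state$alpha_start <- alpha0

  unpack <- function(par) {
    beta <- par[seq_len(p)]
    ls <- par[p + seq_len(k_sig)]
    i <- 1L
    sig <- list(b = NA_real_, d = NA_real_, e = NA_real_)
    if (data$use_cell) { sig$b <- exp(ls[i]); i <- i + 1L }
    sig$d <- exp(ls[i]); i <- i + 1L
    if (data$olre) sig$e <- exp(ls[i])
    list(beta = beta, sig = sig)
  }
  nll <- function(par) {
    pp <- unpack(par)
    val <- tryCatch(
      -as.numeric(.laplace_core(data, pp$beta, pp$sig, state,
                                profile_alpha = TRUE,
                                inner_tol = control$inner_tol,
                                alpha_integrate = control$reml)),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  start <- c(beta0, sig_start)
  lower <- c(rep(-Inf, p), rep(log(1e-4), k_sig))
  upper <- c(rep(Inf, p), rep(log(20), k_sig))
  np <- length(start)

  # finite-difference score and observed information of the negative
  # objective (central differences; cheap thanks to warm-started inner
  # solves), plus the scale-free convergence measure: the Newton
  # displacement implied by the score, in SE units, over parameters not
  # pinned at a bound
  fd_curvature <- function(par) {
    # steps sized so the objective change dominates solver noise even for
    # parameters near zero with strong curvature
    h <- 2e-3 * pmax(abs(par), 1)
    f0 <- nll(par)
    fp <- fm <- numeric(np)
    for (i in seq_len(np)) {
      ei <- numeric(np); ei[i] <- h[i]
      fp[i] <- nll(par + ei)
      fm[i] <- nll(par - ei)
    }
    grad <- (fp - fm) / (2 * h)
    Hfd <- matrix(0, np, np)
    for (i in seq_len(np)) {
      Hfd[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
      if (i < np) for (j in seq.int(i + 1L, np)) {
        ei <- numeric(np); ei[i] <- h[i]
        ej <- numeric(np); ej[j] <- h[j]
        Hfd[i, j] <- Hfd[j, i] <-
          (nll(par + ei + ej) - nll(par + ei - ej) -
             nll(par - ei + ej) + nll(par - ei - ej)) / (4 * h[i] * h[j])
      }
    }
    # observed information can be indefinite when a variance parameter sits
    # at its boundary; clip the spectrum so the covariance stays PSD
    vc <- tryCatch({
      v <- solve(Hfd)
      if (any(diag(v) < 0)) stop("indefinite")
      v
    }, error = function(e) {
      ev <- eigen((Hfd + t(Hfd)) / 2, symmetric = TRUE)
      val <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
      ev$vectors %*% diag(1 / val, np) %*% t(ev$vectors)
    })
    disp <- as.numeric(vc %*% grad) / sqrt(pmax(diag(vc), 1e-300))
    free <- par > lower + 1e-7 & par < upper - 1e-7
    list(grad = grad, vcov = vc,
         disp = if (any(free)) max(abs(disp[free])) else 0)
  }

  run_opt <- function(from) {
    stats::nlminb(from, nll, lower = lower, upper = upper,
                  control = list(rel.tol = control$outer_rel_tol,
                                 iter.max = control$outer_iter,
                                 eval.max = 4L * control$outer_iter))
  }
  # quasi-Newton, restarted (clearing its Hessian memory) only while the
  # score check says the endpoint is not stationary: guards against
  # premature "relative convergence" on curved variance-parameter ridges
  opt <- run_opt(start)
  curv <- fd_curvature(opt$par)
  for (restart in 1:2) {
    if (!is.finite(curv$disp) || curv$disp < control$grad_tol) break
    opt2 <- run_opt(opt$par)
    if (opt2$objective <= opt$objective) opt <- opt2
    curv <- fd_curvature(opt$par)
  }
  par <- opt$par
  grad <- curv$grad
  vcov_c <- curv$vcov

  # final converged evaluation to expose the inner state
  pp <- unpack(par)
  ll <- .laplace_core(data, pp$beta, pp$sig, state, profile_alpha = TRUE,
                      inner_tol = control$inner_tol,
                      alpha_integrate = control$reml)
  inner <- attr(ll, "inner")

  # report on the raw-latitude scale (internal design is latitude-centered)
  beta_rep <- pp$beta
  if (data$use_cell) {
    J <- diag(np)
    J[1, 2] <- -data$Lbar
    beta_rep[1] <- pp$beta[1] - pp$beta[2] * data$Lbar
    vcov <- J %*% vcov_c %*% t(J)
  } else {
    vcov <- vcov_c
  }
  coef_names <- if (data$use_cell) c("beta0", "gamma") else "mu"
  dimnames(vcov) <- list(c(coef_names, sig_names), c(coef_names, sig_names))

  grad_norm <- max(abs(grad))
  converged <- is.finite(opt$objective) && is.finite(curv$disp) &&
    curv$disp < control$grad_tol
  sigmas <- exp(par[p + seq_len(k_sig)])
  names(sigmas) <- sub("^log_", "", sig_names)
  sigma_se <- sigmas * sqrt(pmax(diag(vcov)[p + seq_len(k_sig)], 0))

  list(coef = stats::setNames(beta_rep, coef_names),
       sigmas = sigmas, sigma_se = sigma_se,
       alpha = stats::setNames(inner$z[inner$idx$alpha], data$site_ids),
       vcov = vcov, loglik = as.numeric(ll),
       convergence = list(converged = converged, code = opt$convergence,
                          message = opt$message, grad_norm = grad_norm,
                          se_displacement = curv$disp,
                          iterations = opt$iterations),
       inner = inner, data = data, control = control)
}

#' Fit the preliminary site-slope Poisson mixed model
#'
#' The diagnostic model fitted before any gridding: counts are Poisson with
#' `log lambda_it = alpha_i + (mu + s_i) * t + e_it`, where `alpha_i` are
#' site intercepts, `mu` is the mean year slope, `s_i ~ N(0, sigma_s)` are
#' site slope deviations and `e_it ~ N(0, sigma_e)` absorbs overdispersion.
#' The predicted per-site slopes `mu + s_i` are the values whose spatial
#' autocorrelation motivates the grid-standardized hierarchical model.
#'
#' @param table A centered [survey_table()].
#' @param control A [trend_control()] list.
#' @return An object of class `trend_fit` (kind `"preliminary"`), with
#'   elements `coef` (named `mu`), `sigmas` (`sigma_d` = site-slope SD
#'   `sigma_s`, `sigma_e`), `alpha`, `vcov`, `loglik`, `convergence`, and
#'   random-effect predictions via [predict_random_effects()].
#' @export
fit_preliminary <- function(table, control = trend_control()) {
  data <- .arrays_from_table(table, NULL)
  if (data$S < 2) stop_arg("need at least 2 sites")
  nyr <- tapply(data$t, data$site, function(x) length(unique(x)))
  if (any(nyr < 2)) {
    stop_arg("every site needs >= 2 surveyed years (offenders: %s)",
             paste(utils::head(data$site_ids[nyr < 2], 5), collapse = ", "))
  }
  out <- .fit_laplace(data, control)
  out$kind <- "preliminary"
  class(out) <- "trend_fit"
  out
}

#' Fit the hierarchical grid-standardized trend model
#'
#' The main model: counts are Poisson with
#' `log lambda_it = alpha_i + (beta0 + d_i) * t + e_it`, where the site
#' slope deviation `d_i ~ N(b_q(i), sigma_d)` is centered on its grid cell's
#' mean slope effect and `b_q ~ N(gamma * L_q, sigma_b)` follows the cell
#' centroid latitude. Fitting maximizes the Laplace-approximated marginal
#' likelihood (see [laplace_marginal_loglik()]) over the slope coefficients
#' and log-scale SDs, with site intercepts profiled in the inner problem;
#' the covariance of the outer parameters comes from the inverse observed
#' information (finite-difference Hessian).
#'
#' @param table A centered [survey_table()].
#' @param assignment A [assign_sites()] result covering every site.
#' @param control A [trend_control()] list.
#' @return An object of class `trend_fit` (kind `"hierarchical"`) with
#'   `coef` (named `beta0`, `gamma`; raw-latitude scale), `sigmas`
#'   (`sigma_b`, `sigma_d`, `sigma_e`) with delta-method `sigma_se`,
#'   site intercepts `alpha`, `vcov` of (beta0, gamma, log sigmas),
#'   `loglik`, and `convergence`.
#' @export
fit_hierarchical <- function(table, assignment, control = trend_control()) {
  data <- .arrays_from_table(table, assignment)
  out <- .fit_laplace(data, control)
  out$kind <- "hierarchical"
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %s> logLik = %.2f, %s\n", x$kind, x$loglik,
              if (x$convergence$converged) "converged"
              else sprintf("NOT converged (score displacement %.2g SE)",
                           x$convergence$se_displacement)))
  se <- sqrt(pmax(diag(x$vcov)[seq_along(x$coef)], 0))
  tab <- data.frame(estimate = c(x$coef, x$sigmas),
                    se = c(se, x$sigma_se))
  print(round(tab, 4))
  invisible(x)
}

#' @export
logLik.trend_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef) + length(object$sigmas) +
              length(object$alpha), class = "logLik")
}

#' @export
vcov.trend_fit <- function(object, ...) object$vcov

#' @export
coef.trend_fit <- function(object, ...) object$coef

#' Empirical-Bayes random-effect predictions
#'
#' Posterior modes of the random effects at the fitted parameters, with
#' prediction SEs from the inverse of the inner Hessian. For the
#' hierarchical model the cell mean slope effect is
#' `b_q = gamma * L_q + u_q` and the site slope deviation is
#' `d_i = b_q(i) + v_i` (the model-scale effects); the per-cell trend
#' surface `beta0 + b_q` is exposed for mapping.
#'
#' @param fit A converged [fit_hierarchical()] or [fit_preliminary()] result.
#' @param se Compute prediction SEs (solves the inner system per effect)?
#' @return A list with data.frames `cells` (`cell_id`, `L`, `u`, `b`,
#'   `slope`, `se` — hierarchical only), `sites` (`site_id`, `v`, `d`,
#'   `slope`, `se`), and `residuals` (`site_id`, `year`, `t`, `e`, `se`).
#' @export
predict_random_effects <- function(fit, se = TRUE) {
  stopifnot(inherits(fit, "trend_fit"))
  data <- fit$data
  inner <- fit$inner
  u <- if (data$use_cell) inner$z[inner$idx$u] else NULL
  v <- inner$z[inner$idx$v]

  var_u <- var_v <- cov_uv <- NULL
  if (se) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(inner$H), LDL = FALSE,
                           perm = TRUE)
    cols <- c(if (data$use_cell) inner$idx$u, inner$idx$v)
    B <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                              dims = c(ncol(inner$H), length(cols)))
    Vi <- as.matrix(Matrix::solve(ch, B))[cols, , drop = FALSE]
    if (data$use_cell) {
      iu <- seq_len(data$Q)
      iv <- data$Q + seq_len(data$S)
      var_u <- diag(Vi)[iu]
      var_v <- diag(Vi)[iv]
      cov_uv <- Vi[cbind(iu[data$cell], iv)]
    } else {
      var_v <- diag(Vi)
    }
  }

  if (data$use_cell) {
    b <- fit$coef["gamma"] * data$L + u
    cells <- data.frame(cell_id = data$cell_ids, L = data$L,
                        u = u, b = as.numeric(b),
                        slope = as.numeric(fit$coef["beta0"] + b),
                        se = if (se) sqrt(pmax(var_u, 0)) else NA_real_,
                        stringsAsFactors = FALSE)
    d <- b[data$cell] + v
    sites <- data.frame(site_id = data$site_ids,
                        cell_id = data$cell_ids[data$cell],
                        v = v, d = as.numeric(d),
                        slope = as.numeric(fit$coef["beta0"] + d),
                        se = if (se) sqrt(pmax(var_u[data$cell] + var_v +
                                                 2 * cov_uv, 0)) else NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    cells <- NULL
    sites <- data.frame(site_id = data$site_ids, v = v, d = v,
                        slope = as.numeric(fit$coef["mu"] + v),
                        se = if (se) sqrt(pmax(var_v, 0)) else NA_real_,
                        stringsAsFactors = FALSE)
  }
  s2e <- if (data$olre) fit$sigmas[["sigma_e"]]^2 else 0
  residuals <- data.frame(site_id = data$site_ids[data$site],
                          year = data$year %||% rep(NA_integer_, data$n),
                          t = data$t, e = inner$pr$e,
                          se = 1 / sqrt(inner$pr$lam + 1 / max(s2e, 1e-12)),
                          stringsAsFactors = FALSE)
  list(cells = cells, sites = sites, residuals = residuals)
}

#' Post-fit residual and normality diagnostics
#'
#' Checks the two model assumptions the trend summaries lean on: (i) the
#' predicted random slope effects at cell and site level, standardized by
#' their prediction SDs, should look Gaussian (skewness, excess kurtosis,
#' Shapiro-Wilk p-value); (ii) the per-year means of the observation-level
#' residuals should show no trend-vs-year pattern — a year whose mean
#' residual exceeds twice its standard error is flagged as a departure from
#' log-linearity.
#'
#' @param fit A converged [trend_fit][fit_hierarchical()].
#' @return A list of class `trend_diagnostics`: `normality` (one row per
#'   random-effect level) and `by_year` (per-year residual summary with
#'   `flag`).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  pred <- predict_random_effects(fit, se = TRUE)
  std_stats <- function(x) {
    z <- (x - mean(x)) / stats::sd(x)
    n <- length(z)
    p <- if (n >= 3 && n <= 5000) stats::shapiro.test(z)$p.value else NA_real_
    c(skewness = mean(z^3), ex_kurtosis = mean(z^4) - 3, shapiro_p = p)
  }
  rows <- list()
  if (!is.null(pred$cells)) {
    rows$cell <- std_stats(pred$cells$u / pmax(pred$cells$se, 1e-12))
  }
  rows$site <- std_stats(pred$sites$v / pmax(pred$sites$se, 1e-12))
  normality <- data.frame(level = names(rows), do.call(rbind, rows),
                          row.names = NULL)
  r <- pred$residuals
  agg <- do.call(rbind, lapply(split(r$e, r$year), function(e) {
    c(mean = mean(e), sd = stats::sd(e), n = length(e))
  }))
  by_year <- data.frame(year = as.integer(rownames(agg)), agg,
                        row.names = NULL)
  by_year$se <- by_year$sd / sqrt(by_year$n)
  by_year$flag <- abs(by_year$mean) > 2 * by_year$se
  structure(list(normality = normality, by_year = by_year),
            class = "trend_diagnostics")
}

#' @export
print.trend_diagnostics <- function(x, ...) {
  cat("Random-effect normality:\n")
  print(x$normality, digits = 3)
  cat(sprintf("Residual-vs-year: %d of %d years flagged (|mean| > 2 SE)\n",
              sum(x$by_year$flag), nrow(x$by_year)))
  invisible(x)
}
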