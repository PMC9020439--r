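#' Model arrays for the Laplace-fitted Poisson trend models
#'
#' Packs counts and design information into the internal array form consumed
#' by [laplace_marginal_loglik()] and the fitting functions. Two layouts
#' exist: the hierarchical layout (random year slopes at grid-cell and site
#' level, cell means driven by latitude) and the preliminary layout (a single
#' site-level random slope around a common mean slope). Both carry an
#' optional observation-level Gaussian log-scale effect (lognormal
#' overdispersion, making counts Poisson-lognormal).
#'
#' @param y Non-negative integer counts, one per observation.
#' @param t Centered year per observation.
#' @param site Site index (1..S) per observation.
#' @param cell Cell index (1..Q) per *site* (length S), or `NULL` for the
#'   preliminary layout.
#' @param L Cell centroid latitude (degrees), length Q; required with `cell`.
#' @param olre Include the observation-level random effect?
#' @param site_ids,cell_ids Optional identifier vectors for labeling output.
#' @param year Optional calendar year per observation (for diagnostics).
#' @return A list of class `trend_data`.
#' @export
model_arrays <- function(y, t, site, cell = NULL, L = NULL, olre = TRUE,
                         site_ids = NULL, cell_ids = NULL, year = NULL) {
  n <- length(y)
  stopifnot(length(t) == n, length(site) == n)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop_arg("`y` must be non-negative integers")
  }
  site <- as.integer(site)
  S <- max(site)
  if (!setequal(unique(site), seq_len(S))) stop_arg("`site` must index 1..S densely")
  use_cell <- !is.null(cell)
  Q <- 0L
  Lc <- NULL
  if (use_cell) {
    cell <- as.integer(cell)
    if (length(cell) != S) stop_arg("`cell` must map each site (length S) to a cell")
    Q <- max(cell)
    if (is.null(L) || length(L) != Q) stop_arg("`L` must give one latitude per cell")
    Lc <- as.numeric(L)
    # internally latitude-centered design (decorrelates the intercept-slope
    # pair); reported coefficients are transformed back to raw latitude
    Lbar <- mean(Lc[cell][site])
    X <- cbind(beta0 = t, gamma = t * (Lc[cell][site] - Lbar))
  } else {
    Lbar <- 0
    X <- cbind(mu = t)
  }
  olre <- isTRUE(olre)
  A <- Matrix::sparseMatrix(i = seq_len(n), j = site, x = 1, dims = c(n, S))
  Zv <- Matrix::sparseMatrix(i = seq_len(n), j = site, x = t, dims = c(n, S))
  Zu <- if (use_cell) {
    Matrix::sparseMatrix(i = seq_len(n), j = cell[site], x = t, dims = c(n, Q))
  } else NULL
  structure(list(y = as.numeric(y), t = as.numeric(t), site = site,
                 cell = cell, L = Lc, Lbar = Lbar, X = X,
                 n = n, S = S, Q = Q, use_cell = use_cell, olre = olre,
                 A = A, Zu = Zu, Zv = Zv,
                 lgam = sum(lgamma(y + 1)),
                 site_ids = site_ids %||% as.character(seq_len(S)),
                 cell_ids = cell_ids %||%
                   (if (use_cell) as.character(seq_len(Q)) else NULL),
                 year = year),
            class = "trend_data")
}

# Build trend_data from a survey table (+ assignment for the hierarchical
# layout).
.arrays_from_table <- function(table, assignment = NULL, olre = TRUE) {
  stopifnot(inherits(table, "survey_table"))
  if (is.null(table$records$t)) {
    stop_arg("years are not centered; call center_years() first")
  }
  site_ids <- table$sites$site_id
  site <- match(table$records$site_id, site_ids)
  cell <- NULL
  L <- NULL
  cell_ids <- NULL
  if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "cell_assignment"))
    cmap <- match(site_ids, assignment$sites$site_id)
    if (any(is.na(cmap))) {
      stop_arg("site(s) missing from the cell assignment: %s",
               paste(utils::head(site_ids[is.na(cmap)], 5), collapse = ", "))
    }
    cell_ids_all <- assignment$sites$cell_id[cmap]
    cell_ids <- unique(cell_ids_all)
    cell <- match(cell_ids_all, cell_ids)
    L <- assignment$cells$lat[match(cell_ids, assignment$cells$cell_id)]
  }
  out <- model_arrays(table$records$count, table$records$t, site,
                      cell = cell, L = L, olre = olre,
                      site_ids = site_ids, cell_ids = cell_ids,
                      year = table$records$year)
  out$center <- table$center
  out
}

# Profile the observation-level effect e out of the penalized Poisson
# log-likelihood, per observation: maximize y*(m+e) - exp(m+e) - e^2/(2*s2e).
# Returns the profiled contribution h, its curvature weight
# w = lambda/(1 + s2e*lambda), and the maximizers.
.profile_olre <- function(m, y, s2e, e0 = NULL) {
  if (s2e <= 0) {
    lam <- exp(pmin(m, 700))
    return(list(e = numeric(length(m)), lam = lam, h = y * m - lam,
                w = lam))
  }
  e <- e0
  if (is.null(e) || length(e) != length(m)) e <- numeric(length(m))
  inv <- 1 / s2e
  me <- pmin(m + e, 700)
  for (it in 1:60) {
    lam <- exp(me)
    step <- (y - lam - e * inv) / (lam + inv)
    mx <- max(abs(step))
    if (mx > 4) {
      step[step > 4] <- 4
      step[step < -4] <- -4
    }
    e <- e + step
    me <- m + e
    if (max(me) > 700) me <- pmin(me, 700)
    if (mx < 1e-10) break  # scale-free: step is in e units
  }
  lam <- exp(me)
  list(e = e, lam = lam,
       h = y * (m + e) - lam - e^2 * (0.5 * inv),
       w = lam / (1 + s2e * lam))
}

# Inner Newton solver: maximizes the (OLRE-profiled) penalized Poisson
# log-likelihood over z = (alpha?, u?, v) at fixed outer parameters.
# `state` is an environment carrying warm starts across calls.
.inner_newton <- function(data, beta, s2, profile_alpha, state,
                          inner_tol = 1e-9, max_iter = 60L) {
  blocks <- list()
  pen <- numeric(0)
  if (profile_alpha) {
    blocks$alpha <- data$A
    pen <- c(pen, rep.int(0, data$S))
  }
  if (data$use_cell) {
    blocks$u <- data$Zu
    pen <- c(pen, rep.int(1 / s2$b, data$Q))
  }
  blocks$v <- data$Zv
  pen <- c(pen, rep.int(1 / s2$d, data$S))
  M <- do.call(cbind, blocks)
  nz <- ncol(M)

  off <- as.numeric(data$X %*% beta)
  if (!profile_alpha) off <- off + state$alpha_fixed[data$site]

  z <- state$z
  if (is.null(z) || length(z) != nz) {
    z <- numeric(nz)
    if (profile_alpha) z[seq_len(data$S)] <- state$alpha_start
  }
  e_warm <- state$e
  s2e <- if (data$olre) s2$e else 0

  obj <- function(zv, e0) {
    m <- off + as.numeric(M %*% zv)
    pr <- .profile_olre(m, data$y, s2e, e0)
    list(F = sum(pr$h) - 0.5 * sum(pen * zv^2), pr = pr, m = m)
  }
  cur <- obj(z, e_warm)
  grad_norm <- Inf
  H <- NULL
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(Matrix::crossprod(M, data$y - cur$pr$lam)) - pen * z
    grad_norm <- max(abs(grad))
    Ms <- M
    Ms@x <- M@x * sqrt(cur$pr$w)[M@i + 1L]  # row scaling, dgCMatrix layout
    H <- Matrix::forceSymmetric(Matrix::crossprod(Ms) +
                                  Matrix::Diagonal(nz, pen + 1e-12))
    if (grad_norm < inner_tol) break
    if (is.null(state$ch)) {
      state$ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
    } else {
      state$ch <- Matrix::update(state$ch, H)
    }
    step <- as.numeric(Matrix::solve(state$ch, grad))
    lam_ls <- 1
    for (ls in 1:30) {
      cand <- obj(z + lam_ls * step, cur$pr$e)
      if (is.finite(cand$F) && cand$F >= cur$F - 1e-10) break
      lam_ls <- lam_ls / 2
    }
    z <- z + lam_ls * step
    cur <- cand
  }
  if (grad_norm >= max(1e-4, inner_tol * 1e3)) {
    stop(sprintf("inner Newton solver failed to converge (gradient %.3g)",
                 grad_norm), call. = FALSE)
  }
  state$z <- z
  state$e <- cur$pr$e
  idx <- split(seq_len(nz), rep(names(blocks), vapply(blocks, ncol, 1L)))
  list(z = z, idx = idx, m = cur$m, pr = cur$pr, F = cur$F, H = H,
       pen = pen, grad_norm = grad_norm)
}

# Laplace-approximated marginal log-likelihood at given outer parameters.
# The integral runs over the random effects (u, v, e); site intercepts are
# either supplied fixed (profile_alpha = FALSE) or profiled in the inner
# problem (the fitting path). With `alpha_integrate = TRUE` the site
# intercepts enter the Laplace log-determinant as well (flat-prior
# integration, the REML-type treatment): with one intercept per site, plain
# ML shrinks the variance parameters by an O(S/n) degrees-of-freedom factor,
# which the REML-type objective removes.
.laplace_core <- function(data, beta, sig, state, profile_alpha = TRUE,
                          inner_tol = 1e-9, alpha_integrate = TRUE) {
  s2 <- list(b = sig$b^2, d = sig$d^2, e = if (data$olre) sig$e^2 else 0)
  fit <- .inner_newton(data, beta, s2, profile_alpha, state,
                       inner_tol = inner_tol)
  rand <- c(if (profile_alpha && alpha_integrate) fit$idx$alpha,
            if (data$use_cell) fit$idx$u, fit$idx$v)
  Hr <- Matrix::forceSymmetric(fit$H[rand, rand, drop = FALSE])
  if (is.null(state$ch_uv)) {
    state$ch_uv <- Matrix::Cholesky(Hr, LDL = FALSE, perm = TRUE)
  } else {
    state$ch_uv <- Matrix::update(state$ch_uv, Hr)
  }
  ldet_uv <- 2 * Matrix::determinant(state$ch_uv, logarithm = TRUE,
                                     sqrt = TRUE)$modulus
  ll <- fit$F - data$lgam -
    0.5 * (if (data$use_cell) data$Q * log(s2$b) else 0) -
    0.5 * data$S * log(s2$d) -
    0.5 * as.numeric(ldet_uv)
  if (data$olre) ll <- ll - 0.5 * sum(log1p(s2$e * fit$pr$lam))
  attr(ll, "inner") <- fit
  ll
}

#' Laplace-approximated marginal log-likelihood
#'
#' Evaluates the marginal Poisson log-likelihood of the trend model at fixed
#' parameters, integrating the random effects (cell slopes, site slopes, and
#' the observation-level overdispersion effect) by Laplace approximation:
#' the random-effect vector is maximized by sparse Newton iterations on the
#' penalized Poisson log-likelihood, and the Gaussian integral is corrected
#' by half the log-determinant of the inner negative Hessian. The
#' observation-level effect is profiled analytically per observation and its
#' determinant contribution is accounted exactly through the Schur
#' complement, so the result equals the full joint Laplace approximation.
#'
#' @param params List with `alpha` (site intercepts, length S), `beta`
#'   (fixed slope coefficients matching the data layout: `c(beta0, gamma)`
#'   for the hierarchical layout on the *raw*-latitude scale, `mu` for the
#'   preliminary layout), and positive SDs `sigma_b` (hierarchical only),
#'   `sigma_d`, `sigma_e` (when the data include the overdispersion effect).
#' @param data A [model_arrays()] object.
#' @param inner_tol Gradient tolerance of the inner Newton solver.
#' @return The marginal log-likelihood (a single number), deterministic
#'   given the inputs.
#' @export
laplace_marginal_loglik <- function(params, data, inner_tol = 1e-9) {
  stopifnot(inherits(data, "trend_data"))
  alpha <- params$alpha
  if (length(alpha) != data$S) stop_arg("`params$alpha` must have length S = %d", data$S)
  beta <- as.numeric(params$beta)
  if (length(beta) != ncol(data$X)) {
    stop_arg("`params$beta` must have length %d", ncol(data$X))
  }
  if (data$use_cell) {
    # user-facing beta is on the raw latitude scale; internal design is
    # latitude-centered
    beta <- c(beta[1] + beta[2] * data$Lbar, beta[2])
  }
  sig <- list(b = if (data$use_cell) check_number(params$sigma_b, "sigma_b", lower = 1e-12) else NA,
              d = check_number(params$sigma_d, "sigma_d", lower = 1e-12),
              e = if (data$olre) check_number(params$sigma_e, "sigma_e", lower = 1e-12) else NA)
  state <- new.env(parent = emptyenv())
  state$alpha_fixed <- as.numeric(alpha)
  ll <- .laplace_core(data, beta, sig, state, profile_alpha = FALSE,
                      inner_tol = inner_tol)
  attributes(ll) <- NULL
  ll
}
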