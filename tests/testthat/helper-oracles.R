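# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (brute force, dense algebra, numerical
# quadrature) and never call the code paths they check.

# O(n^3) relative neighborhood graph straight from the definition:
# edge (p, q) iff no r has max(d(p,r), d(q,r)) < d(p,q).
rng_brute_force <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  out <- list()
  for (p in seq_len(n - 1)) {
    for (q in seq.int(p + 1, n)) {
      blocked <- FALSE
      for (r in seq_len(n)) {
        if (r != p && r != q && max(D[p, r], D[q, r]) < D[p, q]) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) out[[length(out) + 1L]] <- c(p, q)
    }
  }
  do.call(rbind, out)
}

# Dense-matrix Moran's I.
moran_dense <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  z <- x - mean(x)
  (n / sum(W)) * sum(outer(z, z) * W) / sum(z^2)
}

# Adaptive tensor-product Gauss-Hermite integration of exp(logf(w)) over
# R^k: recenters at the mode, rescales by the Cholesky of the numeric
# Hessian, and accumulates in log space.
agh_log_integral <- function(logf, k, start = rep(0, k), nodes = 50) {
  opt <- stats::optim(start, function(w) -logf(w), method = "BFGS",
                      hessian = TRUE, control = list(reltol = 1e-14))
  R <- chol(opt$hessian)            # H = R'R
  A <- backsolve(R, diag(k))        # so t(A) %*% H %*% A = I
  gh <- pracma::gaussHermite(nodes)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(nodes)), k)))
  X <- matrix(gh$x[idx], ncol = k)
  logw <- rowSums(matrix(log(gh$w)[idx], ncol = k))
  shift <- sqrt(2) * X %*% t(A)
  lv <- vapply(seq_len(nrow(X)),
               function(i) logf(opt$par + shift[i, ]), numeric(1))
  s <- logw + rowSums(X^2) + lv
  m <- max(s)
  m + log(sum(exp(s - m))) + (k / 2) * log(2) - sum(log(diag(R)))
}

# Tiny deterministic survey fixtures built in code.
tiny_table <- function(n_sites = 6, years = 2002:2012, seed = 42,
                       truth = truth_params(beta0 = -0.05, gamma = 0,
                                            sigma_b = 0, sigma_d = 0.05,
                                            sigma_e = 0.3)) {
  land <- generate_landscape(max(2, ceiling(n_sites / 3)),
                             sites_per_cell = 3, seed = seed)
  land$sites <- land$sites[seq_len(n_sites), , drop = FALSE]
  generate_counts(land, truth, years = years, missing_frac = 0, seed = seed)
}
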