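#' Relative neighborhood graph of a point set
#'
#' Joins points p and q iff no third point r is strictly closer to both than
#' they are to each other, i.e. iff no r satisfies
#' `max(d(p,r), d(q,r)) < d(p,q)` (strict inequality: points at exactly the
#' blocking distance do not block, so e.g. an equilateral triangle keeps all
#' three edges). The RNG contains the Euclidean minimum spanning tree, hence
#' is connected, and is a subgraph of the Delaunay triangulation. Coincident
#' points would make the graph ill-defined, so exact duplicates are separated
#' by a small deterministic displacement before construction (with a
#' warning).
#'
#' @param points Matrix or data.frame with two columns of projected
#'   coordinates (meters), optionally with rownames as node ids.
#' @param jitter Displacement scale (meters) applied to duplicated
#'   coordinates.
#' @return A list of class `neighbor_graph`: `coords` (n x 2 matrix),
#'   `edges` (2-column integer matrix, each row an undirected edge i < j),
#'   `ids` (node identifiers).
#' @export
relative_neighborhood_graph <- function(points, jitter = 1) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 2L) stop_arg("need at least 2 points")
  if (any(!is.finite(pts))) stop_arg("coordinates must be finite")
  ids <- rownames(points) %||% as.character(seq_len(n))
  key <- paste(pts[, 1], pts[, 2])
  if (anyDuplicated(key)) {
    warning("duplicated coordinates separated by a deterministic jitter",
            call. = FALSE)
    for (g in split(seq_len(n), key)) {
      if (length(g) > 1L) {
        k <- seq_along(g) - 1L
        ang <- k * 2.39996322972865  # golden angle: spreads duplicates evenly
        pts[g, 1] <- pts[g, 1] + jitter * k * cos(ang)
        pts[g, 2] <- pts[g, 2] + jitter * k * sin(ang)
      }
    }
  }
  D <- as.matrix(stats::dist(pts))
  edges <- vector("list", n)
  for (p in seq_len(n - 1L)) {
    dp <- D[p, ]
    for_q <- seq.int(p + 1L, n)
    keep <- logical(length(for_q))
    for (k in seq_along(for_q)) {
      q <- for_q[k]
      dpq <- dp[q]
      blk <- dp < dpq & D[q, ] < dpq
      blk[c(p, q)] <- FALSE
      keep[k] <- !any(blk)
    }
    if (any(keep)) edges[[p]] <- cbind(p, for_q[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  dimnames(edges) <- NULL
  structure(list(coords = pts, edges = edges, ids = ids),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges\n",
              nrow(x$coords), nrow(x$edges)))
  invisible(x)
}

#' Spatial weight matrix from a neighbor graph
#'
#' @param graph A [relative_neighborhood_graph()] result.
#' @param style `"binary"` (w_ij = 1 iff edge) or `"row"` (row-standardized:
#'   each node's weights divided by its degree; rows of isolated nodes stay
#'   zero, with a warning).
#' @return A list of class `spatial_weights`: sparse matrix `W` (zero
#'   diagonal), `style`, `ids`.
#' @export
to_weights <- function(graph, style = c("row", "binary")) {
  stopifnot(inherits(graph, "neighbor_graph"))
  style <- match.arg(style)
  n <- nrow(graph$coords)
  e <- graph$edges
  W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  if (style == "row") {
    deg <- Matrix::rowSums(W)
    if (any(deg == 0)) {
      warning("isolated node(s): row left zero under row-standardization",
              call. = FALSE)
    }
    W <- Matrix::Diagonal(n, x = ifelse(deg > 0, 1 / deg, 0)) %*% W
  }
  structure(list(W = methods::as(W, "generalMatrix"), style = style,
                 ids = graph$ids),
            class = "spatial_weights")
}

#' Moran's I statistic
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0 = sum_ij w_ij`. Undefined when the values have zero variance.
#'
#' @param values Numeric vector, one value per node.
#' @param weights A [to_weights()] result (or a plain matrix).
#' @return Moran's I (a single number).
#' @export
morans_i <- function(values, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  n <- length(values)
  if (nrow(W) != n) stop_arg("length(values) != weight-matrix dimension")
  if (any(!is.finite(values))) stop_arg("values must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop_arg("Moran's I undefined: values have zero variance")
  S0 <- sum(W)
  as.numeric((n / S0) * (z %*% (W %*% z)) / ss)
}

#' Moran's I test for spatial autocorrelation
#'
#' Gaussian test of `I` against its null expectation `E[I] = -1/(n-1)`, with
#' the Cliff-Ord closed-form variance under either the randomization null
#' (default; conditions on the empirical value distribution via its kurtosis)
#' or the normality null.
#'
#' @inheritParams morans_i
#' @param null `"randomization"` or `"normality"`.
#' @param alternative `"greater"` (positive autocorrelation; default),
#'   `"two.sided"`, or `"less"`.
#' @return A list of class `moran_test`: `I`, `expected`, `variance`, `z`,
#'   `p.value`, `null`, `alternative`, `n`.
#' @export
morans_test <- function(values, weights,
                        null = c("randomization", "normality"),
                        alternative = c("greater", "two.sided", "less")) {
  null <- match.arg(null)
  alternative <- match.arg(alternative)
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  n <- length(values)
  if (n < 4L) stop_arg("Moran's test needs n >= 4")
  I <- morans_i(values, W)
  Wd <- as.matrix(W)
  S0 <- sum(Wd)
  S1 <- sum((Wd + t(Wd))^2) / 2
  S2 <- sum((rowSums(Wd) + colSums(Wd))^2)
  EI <- -1 / (n - 1)
  if (null == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    z <- values - mean(values)
    b2 <- n * sum(z^4) / sum(z^2)^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  zscore <- (I - EI) / sqrt(VI)
  p <- switch(alternative,
              greater = stats::pnorm(zscore, lower.tail = FALSE),
              less = stats::pnorm(zscore),
              two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE))
  structure(list(I = I, expected = EI, variance = VI, z = zscore,
                 p.value = min(1, p), null = null,
                 alternative = alternative, n = n),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, sd = %.4f), z = %.2f, p = %.4g [%s null, %s]\n",
              x$I, x$expected, sqrt(x$variance), x$z, x$p.value,
              x$null, x$alternative))
  invisible(x)
}
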