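test_that("relative neighborhood graph follows the strict-blocker definition", {
  # two points: always one edge
  g2 <- relative_neighborhood_graph(cbind(c(0, 1), c(0, 0)))
  expect_equal(nrow(g2$edges), 1L)
  expect_error(relative_neighborhood_graph(cbind(1, 1)), "at least 2")

  # exact distance ties do not block (strict inequality): the triangle
  # (0,0), (5,0), (3,4) has two sides of exactly 5 (integer Pythagoras, so
  # the tie is exact in floating point) and keeps all three edges
  tri <- cbind(c(0, 5, 3), c(0, 0, 4))
  g3 <- relative_neighborhood_graph(tri)
  expect_equal(nrow(g3$edges), 3L)

  # a point midway on the segment blocks it
  g4 <- relative_neighborhood_graph(cbind(c(0, 2, 1), c(0, 0, 0.1)))
  expect_false(any(g4$edges[, 1] == 1 & g4$edges[, 2] == 2))
})

test_that("RNG equals the brute-force construction on random point sets", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- c(30, 50, 60)[seed]
    pts <- cbind(runif(n) * 1e5, runif(n) * 1e5)
    got <- relative_neighborhood_graph(pts)$edges
    want <- rng_brute_force(pts)
    expect_equal(got[order(got[, 1], got[, 2]), ],
                 want[order(want[, 1], want[, 2]), ])
  }
})

test_that("RNG contains the minimum spanning tree and is connected", {
  skip_if_not_installed("igraph")
  set.seed(9)
  pts <- cbind(runif(80), runif(80))
  g <- relative_neighborhood_graph(pts)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  expect_true(igraph::is_connected(ig))
  full <- igraph::graph_from_adjacency_matrix(as.matrix(dist(pts)),
                                              mode = "undirected",
                                              weighted = TRUE)
  mst <- igraph::as_edgelist(igraph::mst(full), names = FALSE)
  mst <- cbind(pmin(mst[, 1], mst[, 2]), pmax(mst[, 1], mst[, 2]))
  key <- paste(g$edges[, 1], g$edges[, 2])
  expect_true(all(paste(mst[, 1], mst[, 2]) %in% key))
})

test_that("duplicate coordinates are separated deterministically", {
  pts <- cbind(c(0, 0, 1), c(0, 0, 0))
  expect_warning(g <- relative_neighborhood_graph(pts), "jitter")
  expect_warning(h <- relative_neighborhood_graph(pts), "jitter")
  expect_identical(g$coords, h$coords)
  expect_false(any(duplicated(g$coords)))
})

test_that("weight styles behave as documented", {
  path3 <- relative_neighborhood_graph(cbind(c(0, 1, 2), c(0, 0, 0)))
  w <- to_weights(path3, "row")
  expect_equal(w$W[2, 1], 0.5)
  expect_equal(w$W[2, 3], 0.5)
  expect_equal(unname(Matrix::rowSums(w$W)), c(1, 1, 1))
  wb <- to_weights(path3, "binary")
  expect_true(Matrix::isSymmetric(wb$W))
  expect_equal(unname(Matrix::diag(wb$W)), rep(0, 3))
})

test_that("Moran's I matches the dense formula and its exact special cases", {
  # 4-cycle with alternating values: perfect negative autocorrelation
  sq <- relative_neighborhood_graph(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  wb <- to_weights(sq, "binary")
  expect_equal(morans_i(c(1, -1, 1, -1), wb), -1)

  expect_error(morans_i(rep(2, 4), wb), "zero variance")

  set.seed(12)
  pts <- cbind(runif(40), runif(40))
  g <- relative_neighborhood_graph(pts)
  for (style in c("row", "binary")) {
    w <- to_weights(g, style)
    x <- rnorm(40)
    expect_equal(morans_i(x, w), moran_dense(x, w$W), tolerance = 1e-12)
    # affine invariance
    expect_equal(morans_i(3 * x - 7, w), morans_i(x, w), tolerance = 1e-12)
  }
})

test_that("Moran test expectation, randomization variance and p-values are exact", {
  skip_if_not_installed("ape")
  set.seed(13)
  pts <- cbind(runif(25), runif(25))
  w <- to_weights(relative_neighborhood_graph(pts), "row")
  x <- rnorm(25)
  got <- morans_test(x, w, null = "randomization", alternative = "two.sided")
  expect_equal(got$expected, -1 / 24)
  ref <- ape::Moran.I(x, as.matrix(w$W))  # Cliff-Ord randomization variance
  expect_equal(got$I, ref$observed, tolerance = 1e-12)
  expect_equal(sqrt(got$variance), ref$sd, tolerance = 1e-10)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  # normality-null variance differs from the randomization one only through
  # the kurtosis correction, and both stay positive
  gn <- morans_test(x, w, null = "normality", alternative = "two.sided")
  expect_gt(gn$variance, 0)
  expect_equal(gn$variance, got$variance, tolerance = 0.05)
  expect_error(morans_test(x[1:3], w$W[1:3, 1:3]), "n >= 4")
})

test_that("randomization test holds its nominal size under permutation", {
  set.seed(14)
  pts <- cbind(runif(40), runif(40))
  w <- to_weights(relative_neighborhood_graph(pts), "row")
  x <- rnorm(40)
  rej <- vapply(seq_len(2000), function(i) {
    morans_test(sample(x), w, null = "randomization",
                alternative = "greater")$p.value < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.3)   # within ~3 binomial SDs
})

test_that("Moran's I respects the eigenvalue bounds of the symmetrized weights", {
  set.seed(15)
  pts <- cbind(runif(20), runif(20))
  w <- to_weights(relative_neighborhood_graph(pts), "row")
  Ws <- as.matrix(w$W + Matrix::t(w$W)) / 2
  n <- 20
  ev <- eigen((n / sum(Ws)) * Ws, symmetric = TRUE, only.values = TRUE)$values
  for (i in 1:20) {
    I <- morans_i(rnorm(n), w)
    expect_gte(I, min(ev) - 1e-10)
    expect_lte(I, max(ev) + 1e-10)
  }
})
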