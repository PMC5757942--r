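test_that("box_cox evaluates the power family with a log branch at 0", {
  expect_equal(box_cox(0.3, 1), -0.7)
  expect_equal(box_cox(1, 0), 0)
  expect_equal(box_cox(0.25, 0.5), -1)
  expect_error(box_cox(0, 1))
  # strictly increasing in y for every lambda
  y <- seq(0.001, 1, length.out = 200)
  for (lam in c(-1, -0.25, 0, 0.25, 1, 2)) {
    expect_true(all(diff(box_cox(y, lam)) > 0))
  }
  # continuity in lambda at 0
  expect_lt(max(abs(box_cox(y, 1e-8) - log(y))), 1e-6)
})

test_that("transform_distance_matrix normalizes to [0, 1] and preserves rank order", {
  set.seed(30)
  K <- 5
  y <- matrix(1, K, K)
  v <- runif(K * (K - 1) / 2, 0.001, 0.9)
  y[upper.tri(y)] <- v
  y <- pmin(y, t(y))
  td <- transform_distance_matrix(y, lambda = 0.3)
  off <- upper.tri(td$dist)
  expect_equal(min(td$dist[off]), 0)
  expect_equal(max(td$dist[off]), 1)
  expect_equal(diag(td$dist), rep(0, K), ignore_attr = TRUE)
  expect_equal(td$dist, t(td$dist))
  expect_equal(rank(td$dist[off]), rank(y[upper.tri(y)]))

  # degenerate: identical off-diagonal p-values
  flat <- matrix(0.5, 3, 3); diag(flat) <- 1
  expect_error(transform_distance_matrix(flat, 0),
               class = "pleiomap_invalid_argument")
})

test_that("decreasing lambda expands normalized distances among small p-values", {
  y <- matrix(1, 4, 4)
  y[1, 2] <- y[2, 1] <- 0.001
  y[1, 3] <- y[3, 1] <- 0.01
  y[2, 3] <- y[3, 2] <- 0.5
  y[1, 4] <- y[4, 1] <- 0.3
  y[2, 4] <- y[4, 2] <- 0.7
  y[3, 4] <- y[4, 3] <- 0.9
  # normalized distance of the second-smallest pair (y = 0.01) grows as the
  # zoom-out transform stretches the region near zero
  mids <- vapply(c(0.5, 0.25, 0, -0.25, -0.5), function(lam) {
    transform_distance_matrix(y, lam)$dist[1, 3]
  }, 0)
  expect_true(all(diff(mids) > 0))
})

test_that("epsilon graph connects by distance threshold and detects fragmentation", {
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[2, 3] <- d[3, 2] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  g <- epsilon_graph(as_td(d), 0.15)
  # path graph: consecutive edges only
  expect_true(all(is.finite(diag(g$adjacency[-1, ]))))
  expect_false(is.finite(g$adjacency[1, 3]))
  expect_false(is.finite(g$adjacency[1, 4]))

  # complete graph at epsilon = 1
  gc <- epsilon_graph(as_td(d), 1)
  expect_true(all(is.finite(gc$adjacency)))

  # epsilon below the smallest off-diagonal distance: fragmented data
  expect_error(epsilon_graph(as_td(d), 0.05),
               class = "pleiomap_fragmented_data")
  expect_error(epsilon_graph(as_td(d), 0.05), "fragmented")
})

test_that("shortest paths match direct edges and chain sums", {
  # complete graph already satisfying the triangle inequality: unchanged
  d <- matrix(c(0, 1, 1.5, 1, 0, 1, 1.5, 1, 0), 3, 3)
  g <- epsilon_graph(as_td(d), 2)
  expect_equal(shortest_path_distances(g), g$adjacency, ignore_attr = TRUE)
  # path A-B = 1, B-C = 1, no A-C edge: geodesic A-C = 2
  adj <- matrix(Inf, 3, 3); diag(adj) <- 0
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  expect_equal(shortest_path_distances(adj)[1, 3], 2)
})

test_that("Floyd-Warshall agrees with exhaustive simple-path enumeration", {
  set.seed(77)
  for (rep in 1:10) {
    adj <- random_connected_graph(6)
    expect_equal(shortest_path_distances(adj), oracle_shortest_paths(adj),
                 tolerance = 1e-12)
  }
})

test_that("classical MDS reproduces Euclidean-realizable configurations", {
  # equilateral triangle with side 1
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  mtri <- classical_mds(tri, 2)
  expect_lt(max(abs(as.matrix(dist(mtri$coords)) - tri)), 1e-9)
  expect_lt(max(abs(colMeans(mtri$coords))), 1e-9)

  # collinear points at 0, 1, 3: one informative axis only
  lin <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)
  expect_warning(mlin <- classical_mds(lin, 2), "positive eigenvalue")
  expect_equal(mlin$coords[, 2], rep(0, 3), ignore_attr = TRUE)
  gaps <- abs(diff(mlin$coords[, 1]))
  expect_equal(sort(gaps), c(1, 2), tolerance = 1e-9)

  # random 5-point Euclidean configuration round-trips through its distances
  set.seed(41)
  X <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(X))
  m <- classical_mds(D, 2)
  expect_lt(max(abs(as.matrix(dist(m$coords)) - D)), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  # agrees with stats::cmdscale up to per-axis sign
  ref <- stats::cmdscale(D, k = 2)
  for (a in 1:2) {
    expect_lt(min(max(abs(m$coords[, a] - ref[, a])),
                  max(abs(m$coords[, a] + ref[, a]))), 1e-8)
  }
})

test_that("isomap with a complete graph is classical MDS, and epsilon can be auto", {
  # metric input (Euclidean distances scaled to [0, 1]): with a complete
  # graph the geodesics equal the direct distances, so isomap reduces exactly
  # to classical MDS. (Non-metric p-value distances can be shortcut by
  # multi-hop paths even on a complete graph, so the equivalence is stated
  # for metric inputs.)
  set.seed(52)
  X <- matrix(rnorm(10), 5, 2)
  td <- as_td(as.matrix(dist(X)) / max(dist(X)))
  map <- isomap_embed(td, embedding_config(epsilon = 1, ndim = 2))
  ref <- classical_mds(td$dist, 2)
  expect_equal(map$coords, ref$coords, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(map$graph_distances, td$dist, ignore_attr = TRUE)

  # auto epsilon: smallest grid value that connects; one step less fragments
  y <- matrix(1, 5, 5)
  v <- runif(10, 0.001, 0.9)
  y[upper.tri(y)] <- v
  y <- pmin(y, t(y))
  td <- transform_distance_matrix(y, 0)
  eps <- auto_epsilon(td, grid_step = 0.01)
  expect_true(graph_connects <- inherits(epsilon_graph(td, eps), "pleio_graph"))
  if (eps > 0.01) {
    expect_error(epsilon_graph(td, eps - 0.01),
                 class = "pleiomap_fragmented_data")
  }
  amap <- isomap_embed(td, embedding_config(epsilon = "auto"))
  expect_equal(amap$config$epsilon, eps)

  # chain: links at 0.1, everything else far
  d <- matrix(0.9, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1; d[2, 3] <- d[3, 2] <- 0.1; d[3, 4] <- d[4, 3] <- 0.1
  expect_equal(auto_epsilon(as_td(d), grid_step = 0.05), 0.1)
})

test_that("embedding is invariant to phenotype column order", {
  set.seed(63)
  y <- matrix(1, 5, 5)
  v <- runif(10, 0.01, 0.9)
  y[upper.tri(y)] <- v
  y <- pmin(y, t(y))
  rownames(y) <- colnames(y) <- paste0("P", 1:5)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- isomap_embed(transform_distance_matrix(y, 0),
                     embedding_config(epsilon = "auto"))
  m2 <- isomap_embed(transform_distance_matrix(y[perm, perm], 0),
                     embedding_config(epsilon = "auto"))
  expect_equal(m2$coords[match(rownames(y), rownames(m2$coords)), ],
               m1$coords, tolerance = 1e-9)
})
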