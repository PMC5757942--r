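#' Box-Cox transformation of a pleiotropy p-value
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for `lambda = 0`.
#' Strictly increasing in `y` for every `lambda`, so rank order is preserved;
#' smaller `lambda` expands the region near zero (zoom-out), larger `lambda`
#' compresses it (zoom-in; `lambda = 1` is the identity up to an affine map).
#' The natural log is used at `lambda = 0`; any base differs only by a
#' positive factor that the downstream min-max normalization cancels.
#'
#' @param y p-value(s) in (0, 1].
#' @param lambda real tuning parameter.
#' @return transformed value(s).
#' @export
box_cox <- function(y, lambda) {
  if (any(y <= 0)) stop("y must be positive", call. = FALSE)
  stopifnot(length(lambda) == 1L, is.finite(lambda))
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Transform a pleiotropy p-value matrix into normalized distances
#'
#' Applies [box_cox()] elementwise to the off-diagonal pleiotropy p-values,
#' then min-max rescales the off-diagonal values to \\[0, 1\\] (the raw Box-Cox
#' values are negative and unbounded below; normalization puts them on the
#' absolute scale on which the default `epsilon = 0.15` neighborhood radius is
#' meaningful). The diagonal is 0, and rank order matches the raw p-values:
#' smaller pleiotropy p-value, smaller distance.
#'
#' @param pm a `pleio_matrix` from [pairwise_pleiotropy()], or a symmetric
#'   numeric K x K matrix of p-values with unit diagonal.
#' @param lambda Box-Cox tuning parameter (default 0, the log transform).
#' @return object of class `transformed_dist`: `dist` (K x K in \\[0, 1\\]),
#'   `lambda`, `raw_range` (min and max of the pre-normalization values),
#'   `phenotype_names`.
#' @export
transform_distance_matrix <- function(pm, lambda = 0) {
  y <- if (inherits(pm, "pleio_matrix")) pm$pvalues else pm
  if (!is.matrix(y) || nrow(y) != ncol(y)) stop_invalid("need a square p-value matrix")
  K <- nrow(y)
  if (K < 3L) stop_invalid("at least 3 phenotypes are required")
  off <- upper.tri(y) | lower.tri(y)
  if (any(y[off] <= 0) || any(y[off] > 1)) {
    stop_invalid("off-diagonal p-values must lie in (0, 1]")
  }
  s <- matrix(0, K, K, dimnames = dimnames(y))
  s[off] <- box_cox(y[off], lambda)
  rng <- range(s[off])
  if (rng[1] == rng[2]) {
    stop_invalid("all off-diagonal p-values are identical; min-max normalization is undefined")
  }
  d <- matrix(0, K, K, dimnames = dimnames(y))
  d[off] <- (s[off] - rng[1]) / (rng[2] - rng[1])
  structure(list(dist = d, lambda = lambda, raw_range = rng,
                 phenotype_names = rownames(y) %||% sprintf("GWAS_%d", seq_len(K))),
            class = "transformed_dist")
}

#' Embedding configuration
#'
#' @param epsilon neighborhood radius on the normalized distance scale, or
#'   `"auto"` to pick the smallest connecting radius via [auto_epsilon()].
#'   Default 0.15.
#' @param ndim output dimension (default 2).
#' @param lambda Box-Cox parameter recorded with the map.
#' @param grid_step grid used by `"auto"` epsilon selection.
#' @return a list of class `embedding_config`.
#' @export
embedding_config <- function(epsilon = 0.15, ndim = 2L, lambda = 0,
                             grid_step = 0.01) {
  if (!identical(epsilon, "auto")) {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  }
  stopifnot(ndim >= 1L, grid_step > 0)
  structure(list(epsilon = epsilon, ndim = as.integer(ndim), lambda = lambda,
                 grid_step = grid_step),
            class = "embedding_config")
}

ensure_td <- function(td) {
  if (inherits(td, "transformed_dist")) return(td)
  stopifnot(is.matrix(td), nrow(td) == ncol(td))
  structure(list(dist = td, lambda = NA_real_, raw_range = c(NA_real_, NA_real_),
                 phenotype_names = rownames(td) %||% sprintf("GWAS_%d", seq_len(nrow(td)))),
            class = "transformed_dist")
}

# adjacency of the epsilon-ball graph: weight for edges, Inf otherwise
epsilon_adjacency <- function(d, epsilon) {
  adj <- ifelse(d <= epsilon, d, Inf)
  diag(adj) <- 0
  adj
}

graph_is_connected <- function(adj) {
  K <- nrow(adj)
  seen <- logical(K)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(is.finite(adj[v, ]) & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Build the epsilon-neighborhood graph
#'
#' Connects phenotypes i and j iff their normalized transformed distance is at
#' most `epsilon`, with edge weight equal to that distance. A disconnected
#' graph raises a "fragmented data" error (condition class
#' `pleiomap_fragmented_data`).
#'
#' @param td a `transformed_dist` (or a plain distance matrix).
#' @param epsilon neighborhood radius, > 0.
#' @return object of class `pleio_graph`: `adjacency` (K x K, `Inf` where no
#'   edge), `epsilon`, `phenotype_names`.
#' @export
epsilon_graph <- function(td, epsilon) {
  td <- ensure_td(td)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  adj <- epsilon_adjacency(td$dist, epsilon)
  if (!graph_is_connected(adj)) stop_fragmented(epsilon)
  structure(list(adjacency = adj, epsilon = epsilon,
                 phenotype_names = td$phenotype_names),
            class = "pleio_graph")
}

#' Geodesic (shortest-path) distances over the neighborhood graph
#'
#' Floyd-Warshall relaxation: for each intermediate node k, every entry
#' `d(i, j)` is replaced by `min(d(i, j), d(i, k) + d(k, j))`, starting from
#' the edge weights (`Inf` off-edge). The result is symmetric, has a zero
#' diagonal and satisfies the triangle inequality.
#'
#' @param graph a `pleio_graph` from [epsilon_graph()].
#' @return K x K matrix of shortest-path distances.
#' @export
shortest_path_distances <- function(graph) {
  adj <- if (inherits(graph, "pleio_graph")) graph$adjacency else graph
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  d <- adj
  K <- nrow(d)
  for (k in seq_len(K)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  if (any(!is.finite(d))) {
    stop_fragmented(if (inherits(graph, "pleio_graph")) graph$epsilon else NA)
  }
  d
}

#' Classical multidimensional scaling
#'
#' Converts a distance matrix to inner products with the tau operator
#' `tau(D) = -1/2 * H (D o D) H` (H the centering operator, `o` elementwise
#' product), then takes the top `ndim` eigenvectors scaled by the square roots
#' of their eigenvalues as coordinates. This minimizes
#' `E = || tau(D_G) - tau(D_X) ||_L2` over `ndim`-dimensional configurations.
#'
#' Axes with non-positive eigenvalues are padded with zero coordinates (with a
#' warning). The sign of each axis is fixed by requiring its largest-magnitude
#' loading to be positive, so repeated runs and column permutations cannot
#' flip the map.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param ndim number of output dimensions.
#' @return list with `coords` (K x ndim) and `eigenvalues` (the `ndim` leading
#'   eigenvalues of `tau(D)`, non-increasing).
#' @export
classical_mds <- function(D, ndim = 2L) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop_invalid("distance matrix must be symmetric")
  K <- nrow(D)
  ndim <- as.integer(ndim)
  if (ndim < 1L || ndim >= K) stop_invalid("ndim must satisfy 1 <= ndim < K")
  H <- diag(K) - matrix(1 / K, K, K)
  B <- -0.5 * H %*% (D * D) %*% H
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values[seq_len(ndim)]
  coords <- matrix(0, K, ndim)
  pos <- vals > max(vals[1], 0) * 1e-12 & vals > 0
  if (any(!pos)) {
    warning("only ", sum(pos), " positive eigenvalue(s); remaining axes set to 0")
  }
  for (a in which(pos)) {
    v <- eg$vectors[, a] * sqrt(vals[a])
    if (v[which.max(abs(v))] < 0) v <- -v   # deterministic sign convention
    coords[, a] <- v
  }
  rownames(coords) <- rownames(D)
  list(coords = coords, eigenvalues = vals)
}

#' Smallest connecting neighborhood radius
#'
#' Scans the grid `grid_step, 2 * grid_step, ..., 1` and returns the smallest
#' epsilon for which the epsilon-ball graph is connected (no "fragmented
#' data"). On a normalized distance matrix `epsilon = 1` always connects.
#'
#' @param td a `transformed_dist` (or distance matrix).
#' @param grid_step grid resolution, > 0 (default 0.01).
#' @return the selected epsilon.
#' @export
auto_epsilon <- function(td, grid_step = 0.01) {
  td <- ensure_td(td)
  stopifnot(grid_step > 0)
  for (eps in seq(grid_step, 1, by = grid_step)) {
    if (graph_is_connected(epsilon_adjacency(td$dist, eps))) return(eps)
  }
  1
}

#' Embed phenotypes in low dimension with isomap
#'
#' Composition of [epsilon_graph()], [shortest_path_distances()] and
#' [classical_mds()]: geodesic distances over the epsilon-neighborhood graph
#' are embedded by classical MDS. Deterministic given its input.
#'
#' @param td a `transformed_dist` from [transform_distance_matrix()].
#' @param config an [embedding_config()].
#' @return object of class `phenotype_map`: `coords` (K x ndim),
#'   `eigenvalues`, `config` (with the resolved epsilon), `graph_distances`
#'   (D_G), `phenotype_names`, `cluster` (NULL until
#'   [cluster_phenotypes()] is applied).
#' @export
isomap_embed <- function(td, config = embedding_config()) {
  td <- ensure_td(td)
  stopifnot(inherits(config, "embedding_config"))
  eps <- config$epsilon
  if (identical(eps, "auto")) eps <- auto_epsilon(td, config$grid_step)
  g <- epsilon_graph(td, eps)
  dg <- shortest_path_distances(g)
  mds <- classical_mds(dg, config$ndim)
  cfg <- config
  cfg$epsilon <- eps
  structure(list(coords = mds$coords, eigenvalues = mds$eigenvalues,
                 config = cfg, graph_distances = dg,
                 phenotype_names = td$phenotype_names, cluster = NULL),
            class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat(sprintf("Phenotype map: %d phenotypes in %d dimensions (epsilon = %g, lambda = %g)\n",
              nrow(x$coords), ncol(x$coords), x$config$epsilon, x$config$lambda))
  df <- data.frame(x$coords)
  names(df) <- paste0("dim", seq_len(ncol(x$coords)))
  rownames(df) <- x$phenotype_names
  if (!is.null(x$cluster)) df$cluster <- x$cluster$labels
  print(df)
  invisible(x)
}

#' Plot a phenotype map
#'
#' Scatter plot of the embedded coordinates with phenotype labels; clusters
#' (if assigned) are shown by both color and point shape so the plot stays
#' readable in gray scale.
#'
#' @param x a `phenotype_map`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.phenotype_map <- function(x, main = "Phenotype map", ...) {
  co <- x$coords
  labels <- x$cluster$labels %||% rep(1L, nrow(co))
  pad <- 0.1 * max(apply(co, 2, function(v) diff(range(v))), 1e-6)
  graphics::plot(co[, 1], co[, 2],
                 col = labels, pch = labels,
                 xlim = range(co[, 1]) + c(-pad, pad),
                 ylim = range(co[, 2]) + c(-pad, pad),
                 xlab = "dimension 1", ylab = "dimension 2", main = main, ...)
  graphics::text(co[, 1], co[, 2], labels = x$phenotype_names, pos = 3,
                 cex = 0.8)
  invisible(x)
}

#' Write phenotype-map coordinates (and cluster labels) to TSV
#'
#' @param map a `phenotype_map`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_phenotype_map <- function(map, path) {
  stopifnot(inherits(map, "phenotype_map"))
  df <- data.table::data.table(phenotype = map$phenotype_names)
  for (a in seq_len(ncol(map$coords))) df[[paste0("dim", a)]] <- map$coords[, a]
  if (!is.null(map$cluster)) df$cluster <- map$cluster$labels
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
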