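#' Cluster phenotypes on their embedded coordinates
#'
#' Partitions the isomap coordinates into `n_clusters` groups by k-means
#' (seeded, `nstart` restarts, best within-cluster sum of squares kept) or by
#' agglomerative hierarchical clustering of the Euclidean coordinate
#' distances (complete linkage by default, tree cut at `n_clusters`). Labels
#' are renumbered canonically by first occurrence, so equal partitions get
#' equal label vectors regardless of method.
#'
#' @param map a `phenotype_map` from [isomap_embed()].
#' @param n_clusters number of clusters, `1 <= n_clusters <= K`.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed RNG seed for k-means restarts (ignored for hierarchical).
#' @param nstart number of k-means restarts.
#' @param linkage hierarchical agglomeration method passed to
#'   [stats::hclust()] (`"complete"`, `"average"`, `"single"`, `"ward.D2"`).
#' @return the `phenotype_map` with a `cluster` element of class
#'   `cluster_result` (`labels`, `method`, `n_clusters`, `seed`).
#' @export
cluster_phenotypes <- function(map, n_clusters, method = c("kmeans", "hierarchical"),
                               seed = 1L, nstart = 10L, linkage = "complete") {
  stopifnot(inherits(map, "phenotype_map"))
  method <- match.arg(method)
  K <- nrow(map$coords)
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 1L || n_clusters > K) {
    stop_invalid("n_clusters must lie in 1..K (K = ", K, ")")
  }
  labels <- if (n_clusters == K) {
    seq_len(K)
  } else if (method == "kmeans") {
    with_seed(seed, stats::kmeans(map$coords, centers = n_clusters,
                                  nstart = nstart)$cluster)
  } else {
    stats::cutree(stats::hclust(stats::dist(map$coords), method = linkage),
                  k = n_clusters)
  }
  labels <- canonical_labels(labels)
  map$cluster <- structure(
    list(labels = labels, method = method, n_clusters = n_clusters,
         seed = if (method == "kmeans") as.integer(seed) else NA_integer_),
    class = "cluster_result"
  )
  map
}

# renumber labels by order of first occurrence (1, 2, ...)
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' Rand index between two partitions
#'
#' Co-membership agreement between two label vectors: fraction of item pairs
#' on which the partitions agree (same cluster in both, or different in
#' both). 1 means identical partitions up to label permutation.
#'
#' @param a,b integer label vectors of equal length.
#' @return Rand index in \\[0, 1\\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  pairs <- utils::combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
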