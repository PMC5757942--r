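# Independent oracles used to cross-check the implementation.

# Direct 4-term Bayes rule for the four-group mixture, written against
# stats::dbeta rather than the package's log-space code path.
oracle_posterior <- function(pi, alpha1, alpha2, p1, p2) {
  f1 <- stats::dbeta(p1, alpha1, 1)
  f2 <- stats::dbeta(p2, alpha2, 1)
  num <- cbind(pi[1], pi[2] * f1, pi[3] * f2, pi[4] * f1 * f2)
  num / rowSums(num)
}

# Exhaustive enumeration of all simple paths (feasible for K <= 6 nodes).
oracle_shortest_paths <- function(adj) {
  K <- nrow(adj)
  best <- matrix(Inf, K, K)
  diag(best) <- 0
  rec <- function(path, len) {
    v <- path[length(path)]
    s <- path[1]
    if (len < best[s, v]) best[s, v] <<- len
    for (u in seq_len(K)) {
      if (!(u %in% path) && is.finite(adj[v, u]) && u != v) {
        rec(c(path, u), len + adj[v, u])
      }
    }
  }
  for (s in seq_len(K)) rec(s, 0)
  best
}

# Random connected weighted graph on K nodes: a random spanning path plus
# random extra edges, weights U(0.1, 1).
random_connected_graph <- function(K, extra = K) {
  adj <- matrix(Inf, K, K)
  diag(adj) <- 0
  ord <- sample(K)
  for (i in seq_len(K - 1)) {
    w <- stats::runif(1, 0.1, 1)
    adj[ord[i], ord[i + 1]] <- adj[ord[i + 1], ord[i]] <- w
  }
  for (e in seq_len(extra)) {
    ij <- sample(K, 2)
    w <- stats::runif(1, 0.1, 1)
    adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- w
  }
  adj
}

# A bare four-group fit object with chosen parameters (bypasses EM).
manual_fit <- function(pi, alpha1, alpha2) {
  structure(list(pi = pi, alpha1 = alpha1, alpha2 = alpha2,
                 loglik = NA_real_, n_iter = 0L, converged = TRUE),
            class = "gpa_pair_fit")
}

# Simulated two-trait pair with independent signals (null of the LRT).
null_pair <- function(M, q = 0.2, alpha = 0.4, seed = 1) {
  sc <- sim_scenario(n_snps = M, n_pheno = 2L, signal_prop = q,
                     overlap_pairs = list(), beta_shape = alpha, seed = seed)
  res <- simulate_gwas(sc)
  pair_data(res$pvalues[, 1], res$pvalues[, 2], rownames(res$pvalues))
}

# Distance matrix wrapper accepted by the phenomap functions.
as_td <- function(d) {
  dimnames(d) <- dimnames(d) %||% list(sprintf("P%d", seq_len(nrow(d))),
                                       sprintf("P%d", seq_len(nrow(d))))
  structure(list(dist = d, lambda = 0, raw_range = c(NA_real_, NA_real_),
                 phenotype_names = rownames(d)),
            class = "transformed_dist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
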