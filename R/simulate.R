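#' Define a simulation scenario for GWAS summary statistics
#'
#' A scenario describes the latent association structure from which synthetic
#' GWAS p-values are drawn: each of `n_pheno` phenotypes has a marginal
#' proportion `signal_prop[k]` of truly associated SNPs; designated phenotype
#' pairs share an "extra overlap" fraction `rho` of their association signals
#' beyond what independence would produce; associated p-values follow
#' `Beta(beta_shape[k], 1)` and null p-values are Uniform(0, 1).
#'
#' The overlap convention is marginal-preserving: for a pair `(i, j, rho)` the
#' joint association probability is
#' `p11 = q_i * q_j + rho * (min(q_i, q_j) - q_i * q_j)`,
#' which equals the chance overlap `q_i * q_j` at `rho = 0` and full sharing of
#' the smaller signal set at `rho = 1`, while both marginals stay exactly
#' `q_i` and `q_j`.
#'
#' @param n_snps number of SNPs (rows) M.
#' @param n_pheno number of phenotypes (columns) K.
#' @param signal_prop per-phenotype signal proportions q_k in (0,1); recycled
#'   to length K.
#' @param overlap_pairs list of `c(i, j, rho)` triples; each phenotype may
#'   appear in at most one pair.
#' @param beta_shape per-phenotype Beta shape alpha_k in (0,1); recycled.
#' @param seed integer RNG seed, stored with the scenario.
#' @return an object of class `sim_scenario`.
#' @seealso [scenario_preset()], [simulate_gwas()]
#' @export
sim_scenario <- function(n_snps = 20000L, n_pheno = 5L, signal_prop = 0.2,
                         overlap_pairs = list(), beta_shape = 0.4, seed = 1L) {
  n_snps <- as.integer(n_snps)
  n_pheno <- as.integer(n_pheno)
  if (is.na(n_snps) || n_snps < 1L) stop_invalid("n_snps must be a positive integer")
  if (is.na(n_pheno) || n_pheno < 1L) stop_invalid("n_pheno must be a positive integer")
  signal_prop <- rep_len(as.numeric(signal_prop), n_pheno)
  beta_shape <- rep_len(as.numeric(beta_shape), n_pheno)
  if (any(signal_prop <= 0 | signal_prop >= 1)) {
    stop_invalid("signal_prop entries must lie in (0, 1)")
  }
  if (any(beta_shape <= 0 | beta_shape >= 1)) {
    stop_invalid("beta_shape entries must lie in (0, 1)")
  }
  seen <- integer(0)
  overlap_pairs <- lapply(overlap_pairs, function(pr) {
    pr <- as.numeric(pr)
    if (length(pr) != 3L) stop_invalid("each overlap pair must be c(i, j, rho)")
    i <- as.integer(pr[1]); j <- as.integer(pr[2]); rho <- pr[3]
    if (i < 1L || j < 1L || i > n_pheno || j > n_pheno || i == j) {
      stop_invalid("overlap pair indices must be distinct phenotypes in 1..K")
    }
    if (rho < 0 || rho > 1) stop_invalid("rho must lie in [0, 1]")
    if (any(c(i, j) %in% seen)) {
      stop_invalid("each phenotype may appear in at most one overlap pair")
    }
    seen <<- c(seen, i, j)
    list(i = i, j = j, rho = rho)
  })
  structure(
    list(n_snps = n_snps, n_pheno = n_pheno, signal_prop = signal_prop,
         overlap_pairs = overlap_pairs, beta_shape = beta_shape,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Preset simulation scenarios A-D
#'
#' Four canonical five-phenotype designs used throughout the test-bench:
#' \describe{
#'   \item{A}{20\% associated SNPs for every phenotype; pairs (1,2) and (3,4)
#'     each with 75\% extra overlap.}
#'   \item{B}{as A but 25\% extra overlap for both pairs.}
#'   \item{C}{mixed overlap: 25\% for (1,2), 75\% for (3,4).}
#'   \item{D}{75\% overlap for both pairs but only 5\% associated SNPs for
#'     phenotypes 3 and 4 (20\% elsewhere).}
#' }
#' Phenotype 5 is always an unpaired negative control, and associated p-values
#' are always drawn from Beta(0.4, 1).
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param n_snps number of SNPs; default 20000.
#' @param seed RNG seed stored in the scenario.
#' @return a [sim_scenario()] object.
#' @export
scenario_preset <- function(name, n_snps = 20000L, seed = 1L) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("A", "B", "C", "D")) {
    stop_invalid("unknown scenario preset; must be one of \"A\", \"B\", \"C\", \"D\"")
  }
  q <- switch(name,
    A = rep(0.2, 5), B = rep(0.2, 5), C = rep(0.2, 5),
    D = c(0.2, 0.2, 0.05, 0.05, 0.2)
  )
  rho <- switch(name,
    A = c(0.75, 0.75), B = c(0.25, 0.25), C = c(0.25, 0.75), D = c(0.75, 0.75)
  )
  sim_scenario(
    n_snps = n_snps, n_pheno = 5L, signal_prop = q,
    overlap_pairs = list(c(1, 2, rho[1]), c(3, 4, rho[2])),
    beta_shape = 0.4, seed = seed
  )
}

#' Simulate latent association indicators
#'
#' Draws the M x K binary matrix of true SNP-phenotype associations under a
#' scenario's marginal proportions and pairwise extra overlaps (see
#' [sim_scenario()] for the overlap convention). Uses the scenario seed unless
#' overridden.
#'
#' @param scenario a [sim_scenario()] object.
#' @param seed optional seed overriding `scenario$seed`.
#' @return integer matrix (0/1) with SNP ids as rownames and phenotype names
#'   (`GWAS_1`, ...) as colnames.
#' @export
simulate_latent <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  M <- scenario$n_snps; K <- scenario$n_pheno
  q <- scenario$signal_prop
  paired <- rep(FALSE, K)
  for (pr in scenario$overlap_pairs) paired[c(pr$i, pr$j)] <- TRUE
  z <- with_seed(seed %||% scenario$seed, {
    z <- matrix(0L, nrow = M, ncol = K)
    # pairs first (fixed draw order keeps the stream deterministic)
    for (pr in scenario$overlap_pairs) {
      qi <- q[pr$i]; qj <- q[pr$j]
      p11 <- qi * qj + pr$rho * (min(qi, qj) - qi * qj)
      zi <- stats::rbinom(M, 1L, qi)
      pj_given <- ifelse(zi == 1L, p11 / qi, (qj - p11) / (1 - qi))
      z[, pr$i] <- zi
      z[, pr$j] <- stats::rbinom(M, 1L, pj_given)
    }
    for (k in seq_len(K)) {
      if (!paired[k]) z[, k] <- stats::rbinom(M, 1L, q[k])
    }
    z
  })
  dimnames(z) <- list(
    sprintf("snp_%0*d", nchar(M), seq_len(M)),
    sprintf("GWAS_%d", seq_len(K))
  )
  z
}

#' Simulate GWAS p-values from latent association states
#'
#' Associated entries (indicator 1) are drawn from `Beta(alpha_k, 1)` via the
#' inverse-CDF form `u^(1/alpha_k)`; null entries are Uniform(0, 1). All
#' entries lie in (0, 1].
#'
#' @param latent 0/1 matrix from [simulate_latent()].
#' @param scenario the generating [sim_scenario()].
#' @param seed optional seed overriding `scenario$seed + 1` (the p-value stream
#'   is decoupled from the latent-state stream).
#' @return an object of class `sim_result` with elements `latent`, `pvalues`
#'   (M x K numeric matrix) and `scenario`.
#' @export
simulate_pvalues <- function(latent, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.matrix(latent) || nrow(latent) != scenario$n_snps ||
      ncol(latent) != scenario$n_pheno) {
    stop_invalid("latent matrix dimensions do not match the scenario")
  }
  M <- nrow(latent); K <- ncol(latent)
  p <- with_seed(seed %||% (scenario$seed + 1L), {
    p <- matrix(stats::runif(M * K), nrow = M, ncol = K)
    for (k in seq_len(K)) {
      idx <- latent[, k] == 1L
      # Beta(alpha,1) via inverse CDF: F^{-1}(u) = u^(1/alpha)
      p[idx, k] <- p[idx, k]^(1 / scenario$beta_shape[k])
    }
    p
  })
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  dimnames(p) <- dimnames(latent)
  structure(list(latent = latent, pvalues = p, scenario = scenario),
            class = "sim_result")
}

#' Simulate a full synthetic GWAS summary-statistics dataset
#'
#' Convenience wrapper running [simulate_latent()] then [simulate_pvalues()].
#'
#' @inheritParams simulate_latent
#' @return a `sim_result` object.
#' @examples
#' res <- simulate_gwas(scenario_preset("A", n_snps = 1000))
#' colMeans(res$latent)
#' @export
simulate_gwas <- function(scenario, seed = NULL) {
  seed <- seed %||% scenario$seed
  latent <- simulate_latent(scenario, seed = seed)
  simulate_pvalues(latent, scenario, seed = seed + 1L)
}

#' Write a simulation result to plain-text files
#'
#' Writes `<prefix>_pvalues.tsv` (SNP id column + one column per phenotype),
#' `<prefix>_latent.tsv` (same shape, 0/1) and `<prefix>_scenario.json`.
#'
#' @param result a `sim_result`.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the three file paths.
#' @export
write_sim_result <- function(result, prefix) {
  stopifnot(inherits(result, "sim_result"))
  paths <- c(
    pvalues = paste0(prefix, "_pvalues.tsv"),
    latent = paste0(prefix, "_latent.tsv"),
    scenario = paste0(prefix, "_scenario.json")
  )
  write_pvalue_matrix(result$pvalues, paths[["pvalues"]])
  lat <- data.table::as.data.table(result$latent, keep.rownames = "snp_id")
  data.table::fwrite(lat, paths[["latent"]], sep = "\t")
  sc <- result$scenario
  jsonlite::write_json(
    list(n_snps = sc$n_snps, n_pheno = sc$n_pheno,
         signal_prop = sc$signal_prop,
         overlap_pairs = lapply(sc$overlap_pairs, unlist),
         beta_shape = sc$beta_shape, seed = sc$seed),
    paths[["scenario"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d SNPs x %d phenotypes (seed %d)\n",
              x$n_snps, x$n_pheno, x$seed))
  cat("  signal proportions:", paste(format(x$signal_prop), collapse = ", "), "\n")
  cat("  Beta shapes:       ", paste(format(x$beta_shape), collapse = ", "), "\n")
  if (length(x$overlap_pairs)) {
    for (pr in x$overlap_pairs) {
      cat(sprintf("  extra overlap: (%d, %d) rho = %g\n", pr$i, pr$j, pr$rho))
    }
  } else cat("  no overlap pairs (all phenotypes independent)\n")
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulated GWAS p-values: %d SNPs x %d phenotypes\n",
              nrow(x$pvalues), ncol(x$pvalues)))
  cat("  realized signal fractions:",
      paste(format(round(colMeans(x$latent), 4)), collapse = ", "), "\n")
  invisible(x)
}
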