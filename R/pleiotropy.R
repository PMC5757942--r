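#' Likelihood-ratio test of pleiotropy for one phenotype pair
#'
#' Tests the null hypothesis that association signals of the two traits are
#' independent, i.e. `pi11 = (pi10 + pi11) * (pi01 + pi11)`. Under this null
#' the joint likelihood factorizes exactly into the product of the two
#' marginal two-group mixtures, so the null log-likelihood is the sum of two
#' [fit_marginal_em()] fits. The statistic is
#' `T = max(0, 2 * (loglik_alt - loglik_null))` and the p-value comes from the
#' upper tail of the chi-squared distribution with 1 degree of freedom
#' (alternative: 5 free parameters; null: 4).
#'
#' The alternative fit is multi-started from the default initialization and
#' from an independence-informed start built from the marginal fits, keeping
#' the higher log-likelihood; this makes negative statistics (a local-optimum
#' artifact) rare.
#'
#' @param data a [pair_data()] object.
#' @param control an [em_control()] list.
#' @return list of class `pleio_test` with `statistic`, `pvalue`, `alt_fit`,
#'   `null_fits` (the two marginal fits) and `converged`.
#' @export
lrt_pleiotropy <- function(data, control = em_control()) {
  stopifnot(inherits(data, "pair_data"))
  m1 <- fit_marginal_em(data$p1, control)
  m2 <- fit_marginal_em(data$p2, control)
  # independence start: pi_c = product of marginal masses, shapes from marginals
  ind_init <- list(
    pi = c((1 - m1$pi1) * (1 - m2$pi1), m1$pi1 * (1 - m2$pi1),
           (1 - m1$pi1) * m2$pi1, m1$pi1 * m2$pi1),
    alpha1 = m1$alpha, alpha2 = m2$alpha
  )
  alt <- fit_pair_em(data, control, extra_inits = list(ind_init))
  ll_null <- m1$loglik + m2$loglik
  t_raw <- 2 * (alt$loglik - ll_null)
  if (t_raw < -1e-6) {
    warning(sprintf("negative LRT statistic (%.3g) clamped to 0; EM likely hit a local optimum", t_raw))
  }
  statistic <- max(0, t_raw)
  structure(list(
    statistic = statistic,
    pvalue = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    alt_fit = alt,
    null_fits = list(m1, m2),
    converged = alt$converged && m1$converged && m2$converged
  ), class = "pleio_test")
}

#' All-pairs pleiotropy test matrix
#'
#' Runs [lrt_pleiotropy()] on every one of the `K * (K - 1) / 2` phenotype
#' pairs of a p-value matrix, producing the symmetric matrix of pleiotropy
#' p-values `y_ij` that feeds the phenotype map. The diagonal is fixed at 1
#' (self-pleiotropy is undefined and excluded downstream).
#'
#' The chi-squared null is asymptotic; with fewer than ~200K SNPs the
#' calibration caveat is reported when `verbose = TRUE`.
#'
#' @param pmat numeric M x K matrix of p-values (K >= 3), phenotype names in
#'   `colnames`.
#' @param control an [em_control()] list.
#' @param verbose print per-pair progress and convergence information.
#' @return object of class `pleio_matrix`: `pvalues` and `statistics`
#'   (symmetric K x K), `phenotype_names`, `pair_fits` (named `"i:j"`),
#'   `converged` (logical K x K), `n_snps`.
#' @export
pairwise_pleiotropy <- function(pmat, control = em_control(), verbose = FALSE) {
  if (inherits(pmat, "sim_result")) pmat <- pmat$pvalues
  if (!is.matrix(pmat) || !is.numeric(pmat)) stop_invalid("pmat must be a numeric matrix")
  K <- ncol(pmat)
  if (K < 3L) stop_invalid("at least 3 phenotypes are required (K >= 3)")
  M <- nrow(pmat)
  if (verbose && M < 200000) {
    message("note: ", M, " SNPs; the chi-squared(1) null is asymptotic and ",
            "typically quoted for 200K or more SNPs")
  }
  phen <- colnames(pmat) %||% sprintf("GWAS_%d", seq_len(K))
  snp_ids <- rownames(pmat) %||% sprintf("snp_%d", seq_len(M))
  pv <- matrix(1, K, K, dimnames = list(phen, phen))
  st <- matrix(0, K, K, dimnames = list(phen, phen))
  cvg <- matrix(TRUE, K, K, dimnames = list(phen, phen))
  fits <- list()
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      test <- lrt_pleiotropy(pair_data(pmat[, i], pmat[, j], snp_ids), control)
      pv[i, j] <- pv[j, i] <- test$pvalue
      st[i, j] <- st[j, i] <- test$statistic
      cvg[i, j] <- cvg[j, i] <- test$converged
      fits[[paste0(i, ":", j)]] <- test$alt_fit
      if (verbose) {
        message(sprintf("  %s ~ %s: T = %.3f, p = %.3g (EM iters %d, converged %s)",
                        phen[i], phen[j], test$statistic, test$pvalue,
                        test$alt_fit$n_iter, test$converged))
      }
    }
  }
  structure(list(pvalues = pv, statistics = st, phenotype_names = phen,
                 pair_fits = fits, converged = cvg, n_snps = M),
            class = "pleio_matrix")
}

#' Write a pleiotropy matrix to TSV and JSON
#'
#' @param pm a `pleio_matrix`.
#' @param tsv_path path for the square p-value matrix (phenotype header row
#'   and column).
#' @param json_path optional path for per-pair statistics, p-values and
#'   convergence flags.
#' @return invisibly, the paths written.
#' @export
write_pleio_matrix <- function(pm, tsv_path, json_path = NULL) {
  stopifnot(inherits(pm, "pleio_matrix"))
  dt <- data.table::as.data.table(pm$pvalues, keep.rownames = "phenotype")
  data.table::fwrite(dt, tsv_path, sep = "\t")
  if (!is.null(json_path)) {
    K <- length(pm$phenotype_names)
    pairs <- list()
    for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
      fit <- pm$pair_fits[[paste0(i, ":", j)]]
      pairs[[length(pairs) + 1L]] <- list(
        phenotype_1 = pm$phenotype_names[i], phenotype_2 = pm$phenotype_names[j],
        statistic = pm$statistics[i, j], pvalue = pm$pvalues[i, j],
        pi = as.list(fit$pi), alpha1 = fit$alpha1, alpha2 = fit$alpha2,
        loglik = fit$loglik, n_iter = fit$n_iter,
        converged = pm$converged[i, j]
      )
    }
    jsonlite::write_json(pairs, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}

#' @export
print.pleio_matrix <- function(x, ...) {
  cat(sprintf("Pairwise pleiotropy tests: %d phenotypes, %d SNPs\n",
              length(x$phenotype_names), x$n_snps))
  print(signif(x$pvalues, 3))
  invisible(x)
}
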