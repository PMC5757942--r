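test_that("beta_log_density evaluates log(alpha * p^(alpha - 1)) with domain checks", {
  # density of Beta(0.5, 1) at 0.25 is 0.5 * 0.25^-0.5 = 1, so log = 0
  expect_equal(beta_log_density(0.25, 0.5), 0)
  # hand evaluation: ln(0.4) - 0.6 * ln(0.01) = 1.8468...
  expect_equal(beta_log_density(0.01, 0.4), log(0.4) - 0.6 * log(0.01))
  expect_equal(beta_log_density(0.01, 0.4), 1.8468, tolerance = 1e-4)
  # alpha -> 1 approaches the Uniform density (log = 0) for any p
  expect_lt(max(abs(beta_log_density(c(0.01, 0.5, 1), 1 - 1e-10))), 1e-7)
  # agrees with stats::dbeta on a grid
  p <- seq(0.01, 1, by = 0.01)
  expect_equal(beta_log_density(p, 0.3), stats::dbeta(p, 0.3, 1, log = TRUE))
  expect_error(beta_log_density(0, 0.5))
  expect_error(beta_log_density(0.5, 1.2))
})

test_that("complete-data shape MLE matches its closed form", {
  # all-signal memberships with every p = e^-2: alpha-hat = -n / sum(log p) = 0.5
  expect_equal(pleiomap:::alpha_mle(rep(1, 50), rep(-2, 50), 1e-4), 0.5)
  # weights scale out: alpha depends on the weighted mean of log p only
  w <- runif(20)
  lp <- log(runif(20))
  expect_equal(pleiomap:::alpha_mle(w, lp, 1e-4),
               min(max(-sum(w) / sum(w * lp), 1e-4), 1 - 1e-4))
})

test_that("marginal EM recovers two-group mixture parameters", {
  sc <- sim_scenario(n_snps = 10000L, n_pheno = 1L, signal_prop = 0.2,
                     beta_shape = 0.4, seed = 21)
  res <- simulate_gwas(sc)
  fit <- fit_marginal_em(res$pvalues[, 1])
  expect_true(fit$converged)
  expect_lt(abs(fit$pi1 - 0.2), 0.03)
  expect_lt(abs(fit$alpha - 0.4), 0.05)

  # pure Uniform input: pi1 and alpha are jointly unidentifiable (alpha -> 1
  # makes the signal component uniform), so assert the identifiable quantity:
  # the effective signal mass pi1 * (1 - alpha) vanishes and the fitted
  # density is indistinguishable from Uniform(0, 1)
  unif <- with(list(), {set.seed(4); runif(10000)})
  fit0 <- fit_marginal_em(unif)
  expect_lt(fit0$pi1 * (1 - fit0$alpha), 0.01)
  grid <- seq(0.01, 1, by = 0.01)
  dens <- fit0$pi1 * fit0$alpha * grid^(fit0$alpha - 1) + (1 - fit0$pi1)
  expect_lt(max(abs(dens - 1)), 0.05)

  expect_error(fit_marginal_em(c(0.1, NA, 0.5)))
})

test_that("pair EM fits the four-group model and is trait-symmetric", {
  res <- simulate_gwas(scenario_preset("A", n_snps = 20000, seed = 1))
  pd <- pair_data(res$pvalues[, 1], res$pvalues[, 2], rownames(res$pvalues))
  fit <- fit_pair_em(pd, em_control(keep_trace = TRUE))
  expect_true(fit$converged)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  expect_lt(abs(fit$alpha1 - 0.4), 0.05)
  expect_lt(abs(fit$alpha2 - 0.4), 0.05)
  # design joint-association mass: 0.04 + 0.75 * 0.16 = 0.16
  expect_lt(abs(fit$pi[["11"]] - 0.16), 0.03)
  # EM monotonicity: log-likelihood non-decreasing every iteration
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  # posterior rows sum to one
  expect_lt(max(abs(rowSums(fit$posteriors) - 1)), 1e-12)

  # exchanging the two traits swaps pi10/pi01 and alpha1/alpha2
  swap <- fit_pair_em(pair_data(pd$p2, pd$p1, pd$snp_ids))
  expect_equal(unname(swap$pi[c("00", "01", "10", "11")]), unname(fit$pi),
               tolerance = 1e-4)
  expect_equal(swap$alpha1, fit$alpha2, tolerance = 1e-4)
  expect_equal(swap$alpha2, fit$alpha1, tolerance = 1e-4)
})

test_that("stronger generating signal yields smaller estimated alpha", {
  alphas <- c(0.2, 0.4, 0.6)
  est <- vapply(alphas, function(a) {
    sc <- sim_scenario(n_snps = 20000L, n_pheno = 2L, signal_prop = 0.2,
                       overlap_pairs = list(c(1, 2, 0.75)), beta_shape = a,
                       seed = 31)
    res <- simulate_gwas(sc)
    fit_pair_em(pair_data(res$pvalues[, 1], res$pvalues[, 2]))$alpha1
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("posterior_z matches the direct 4-term Bayes oracle", {
  set.seed(8)
  for (rep in 1:5) {
    pi <- as.vector(stats::rgamma(4, 1)); pi <- pi / sum(pi)
    a1 <- runif(1, 0.1, 0.9); a2 <- runif(1, 0.1, 0.9)
    p1 <- runif(5); p2 <- runif(5)
    fit <- manual_fit(pi, a1, a2)
    got <- posterior_z(fit, pair_data(p1, p2))
    expect_lt(max(abs(got - oracle_posterior(pi, a1, a2, p1, p2))), 1e-12)
  }
})

test_that("posterior_z limiting and symmetry cases", {
  pd <- pair_data(c(0.01, 0.2, 0.9), c(0.01, 0.2, 0.9))
  # uniform-limit emissions carry no information: posteriors = prior
  flat <- posterior_z(manual_fit(rep(0.25, 4), 1 - 1e-9, 1 - 1e-9), pd)
  expect_lt(max(abs(flat - 0.25)), 1e-6)
  # symmetric model + identical p-values: 10 and 01 posteriors coincide
  sym <- posterior_z(manual_fit(c(0.4, 0.2, 0.2, 0.2), 0.3, 0.3), pd)
  expect_equal(sym[, "10"], sym[, "01"])
})

test_that("local_fdr_11 is one minus the joint posterior", {
  set.seed(12)
  pd <- pair_data(runif(20), runif(20))
  fit <- manual_fit(c(0.5, 0.2, 0.2, 0.1), 0.3, 0.5)
  lf <- local_fdr_11(fit, pd)
  expect_lt(max(abs(lf - (1 - oracle_posterior(fit$pi, 0.3, 0.5,
                                               pd$p1, pd$p2)[, 4]))), 1e-12)
  expect_true(all(lf >= 0 & lf <= 1))
  # zero prior mass on the shared component forces local FDR = 1
  lf0 <- local_fdr_11(manual_fit(c(0.6, 0.2, 0.2 - 1e-12, 1e-12), 0.3, 0.5), pd)
  expect_true(all(lf0 > 1 - 1e-6))
})
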