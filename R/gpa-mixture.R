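#' EM control settings
#'
#' Settings shared by the marginal and pairwise mixture fits.
#'
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param alpha_min Beta shapes are clamped into `[alpha_min, 1 - alpha_min]`.
#' @param p_floor p-values are clipped to `[p_floor, 1]` before taking logs.
#' @param init_pi length-4 initial mixing proportions (00, 10, 01, 11).
#' @param init_alpha initial Beta shape for both traits.
#' @param keep_trace store the per-iteration log-likelihood trace in the fit.
#' @return a list of class `em_control`.
#' @export
em_control <- function(tol = 1e-6, max_iter = 2000L, alpha_min = 1e-4,
                       p_floor = 1e-30, init_pi = c(0.7, 0.1, 0.1, 0.1),
                       init_alpha = 0.5, keep_trace = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, alpha_min > 0, alpha_min < 0.5,
            length(init_pi) == 4L, all(init_pi > 0),
            init_alpha > 0, init_alpha < 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 alpha_min = alpha_min, p_floor = p_floor,
                 init_pi = init_pi / sum(init_pi), init_alpha = init_alpha,
                 keep_trace = isTRUE(keep_trace)),
            class = "em_control")
}

#' Pair of p-value vectors for two traits
#'
#' @param p1,p2 numeric p-value vectors of equal length, entries in (0, 1]
#'   (values below the clip floor are raised to it at fit time).
#' @param snp_ids optional SNP identifiers; autogenerated when missing.
#' @return a list of class `pair_data`.
#' @export
pair_data <- function(p1, p2, snp_ids = NULL) {
  if (length(p1) != length(p2)) stop_invalid("p1 and p2 must have equal length")
  if (length(p1) < 2L) stop_invalid("need at least 2 SNPs")
  if (anyNA(p1) || anyNA(p2) || any(!is.finite(p1)) || any(!is.finite(p2))) {
    stop("p-values must be finite and non-missing", call. = FALSE)
  }
  if (any(p1 <= 0) || any(p2 <= 0) || any(p1 > 1) || any(p2 > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  snp_ids <- snp_ids %||% names(p1) %||% sprintf("snp_%d", seq_along(p1))
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 snp_ids = as.character(snp_ids)),
            class = "pair_data")
}

#' Log density of the Beta(alpha, 1) distribution
#'
#' The signal emission density for associated p-values:
#' `log(alpha * p^(alpha - 1)) = log(alpha) + (alpha - 1) * log(p)`.
#' With `0 < alpha < 1` the density decreases monotonically on (0, 1] and
#' concentrates mass near zero; `alpha -> 1` recovers the Uniform null.
#'
#' @param p p-value(s) in (0, 1].
#' @param alpha shape in (0, 1).
#' @return log density, vectorized over `p`.
#' @export
beta_log_density <- function(p, alpha) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  log(alpha) + (alpha - 1) * log(p)
}

# Complete-data MLE of the Beta(alpha,1) shape given membership weights w:
# alpha = -sum(w) / sum(w * log p). Clamped into (alpha_min, 1 - alpha_min).
alpha_mle <- function(w, logp, alpha_min) {
  denom <- sum(w * logp)
  if (!is.finite(denom) || denom >= 0 || sum(w) <= 0) return(1 - alpha_min)
  min(max(-sum(w) / denom, alpha_min), 1 - alpha_min)
}

#' Fit the two-group Beta-Uniform mixture to one p-value vector
#'
#' EM for `pi1 * Beta(alpha, 1) + (1 - pi1) * Uniform(0, 1)`, the marginal
#' model for a single trait. Two such fits multiply to give the factorized
#' null of the pleiotropy likelihood-ratio test (see [lrt_pleiotropy()]).
#'
#' @param p numeric p-value vector (length >= 2).
#' @param control an [em_control()] list.
#' @return list of class `marginal_fit` with `pi1`, `alpha`, `loglik`,
#'   `posterior` (signal membership probabilities), `n_iter`, `converged`,
#'   and `loglik_trace` if requested.
#' @export
fit_marginal_em <- function(p, control = em_control()) {
  if (length(p) < 2L) stop_invalid("need at least 2 p-values")
  p <- clip_pvalues(p, control$p_floor)
  lp <- log(p)
  pi1 <- sum(control$init_pi[-1]) # mass off the null component
  alpha <- control$init_alpha
  ll_old <- -Inf
  trace <- if (control$keep_trace) numeric(control$max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  w <- numeric(length(p))
  repeat {
    iter <- iter + 1L
    ls <- log(pi1) + log(alpha) + (alpha - 1) * lp   # signal component
    ln <- log1p(-pi1)                                 # uniform component
    m <- pmax(ls, ln)
    lse <- m + log(exp(ls - m) + exp(ln - m))
    ll <- sum(lse)
    if (!is.null(trace)) trace[iter] <- ll
    w <- exp(ls - lse)
    if (abs(ll - ll_old) < control$tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
    ll_old <- ll
    pi1 <- min(max(mean(w), 1e-8), 1 - 1e-8)  # boundary guard
    alpha <- alpha_mle(w, lp, control$alpha_min)
  }
  structure(list(pi1 = pi1, alpha = alpha, loglik = ll, posterior = w,
                 n_iter = iter, converged = converged,
                 loglik_trace = if (!is.null(trace)) trace[seq_len(iter)]),
            class = "marginal_fit")
}

# component log densities for the four-group model, as an M x 4 matrix of
# log(pi_c) + log f_c(p1) + log g_c(p2); columns ordered (00, 10, 01, 11)
pair_log_components <- function(lp1, lp2, pi, alpha1, alpha2) {
  lb1 <- log(alpha1) + (alpha1 - 1) * lp1
  lb2 <- log(alpha2) + (alpha2 - 1) * lp2
  cbind(log(pi[1]), log(pi[2]) + lb1, log(pi[3]) + lb2, log(pi[4]) + lb1 + lb2)
}

row_logsumexp <- function(lc) {
  m <- pmax(lc[, 1], lc[, 2], lc[, 3], lc[, 4])
  m + log(exp(lc[, 1] - m) + exp(lc[, 2] - m) +
          exp(lc[, 3] - m) + exp(lc[, 4] - m))
}

#' Fit the four-group Beta-Uniform mixture for a phenotype pair
#'
#' EM for the two-trait model with latent states (00, 10, 01, 11): under state
#' 10 trait 1's p-value follows `Beta(alpha1, 1)` and trait 2's is Uniform,
#' under 11 both are Beta, and so on, with product emissions throughout.
#' The E-step weights are `w_mc \\propto pi_c f_c(p_m1) g_c(p_m2)`; the M-step
#' sets `pi` to the mean weights and each shape to its complete-data MLE over
#' the components where that trait is associated.
#'
#' @param data a [pair_data()] object.
#' @param control an [em_control()] list. `init` may also be supplied via
#'   `init_pi` / `init_alpha`; `extra_inits` (a list of
#'   `list(pi =, alpha1 =, alpha2 =)`) adds multi-start candidates, keeping
#'   the best log-likelihood.
#' @param extra_inits optional list of additional starting points.
#' @return list of class `gpa_pair_fit` with `pi` (length 4, named), `alpha1`,
#'   `alpha2`, `loglik`, `posteriors` (M x 4), `n_iter`, `converged`,
#'   `snp_ids`, and `loglik_trace` if requested.
#' @export
fit_pair_em <- function(data, control = em_control(), extra_inits = NULL) {
  stopifnot(inherits(data, "pair_data"))
  p1 <- clip_pvalues(data$p1, control$p_floor)
  p2 <- clip_pvalues(data$p2, control$p_floor)
  lp1 <- log(p1); lp2 <- log(p2)
  starts <- c(
    list(list(pi = control$init_pi, alpha1 = control$init_alpha,
              alpha2 = control$init_alpha)),
    extra_inits %||% list()
  )
  best <- NULL
  for (st in starts) {
    fit <- pair_em_once(lp1, lp2, st$pi, st$alpha1, st$alpha2, control)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("pair EM did not converge within ", control$max_iter, " iterations")
  }
  best$snp_ids <- data$snp_ids
  dimnames(best$posteriors) <- list(data$snp_ids, c("00", "10", "01", "11"))
  names(best$pi) <- c("00", "10", "01", "11")
  class(best) <- "gpa_pair_fit"
  best
}

pair_em_once <- function(lp1, lp2, pi, alpha1, alpha2, control) {
  pi <- pi / sum(pi)
  ll_old <- -Inf
  trace <- if (control$keep_trace) numeric(control$max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  w <- NULL
  repeat {
    iter <- iter + 1L
    lc <- pair_log_components(lp1, lp2, pi, alpha1, alpha2)
    lse <- row_logsumexp(lc)
    ll <- sum(lse)
    if (!is.null(trace)) trace[iter] <- ll
    w <- exp(lc - lse)
    if (abs(ll - ll_old) < control$tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
    ll_old <- ll
    pi <- pmin(pmax(colMeans(w), 1e-12), 1)
    pi <- pi / sum(pi)
    alpha1 <- alpha_mle(w[, 2] + w[, 4], lp1, control$alpha_min)
    alpha2 <- alpha_mle(w[, 3] + w[, 4], lp2, control$alpha_min)
  }
  list(pi = pi, alpha1 = alpha1, alpha2 = alpha2, loglik = ll,
       posteriors = w, n_iter = iter, converged = converged,
       loglik_trace = if (!is.null(trace)) trace[seq_len(iter)])
}

#' Posterior membership probabilities for the four latent states
#'
#' Applies Bayes' rule with the fitted mixing proportions and emission
#' densities to fresh data: `Pr(Z_mc = 1 | p_m1, p_m2)`, rows summing to 1.
#'
#' @param fit a `gpa_pair_fit`.
#' @param data a [pair_data()] object.
#' @param p_floor clip floor applied before logs.
#' @return M x 4 matrix with columns `00`, `10`, `01`, `11`.
#' @export
posterior_z <- function(fit, data, p_floor = 1e-30) {
  stopifnot(inherits(fit, "gpa_pair_fit"), inherits(data, "pair_data"))
  lp1 <- log(clip_pvalues(data$p1, p_floor))
  lp2 <- log(clip_pvalues(data$p2, p_floor))
  lc <- pair_log_components(lp1, lp2, fit$pi, fit$alpha1, fit$alpha2)
  w <- exp(lc - row_logsumexp(lc))
  dimnames(w) <- list(data$snp_ids, c("00", "10", "01", "11"))
  w
}

#' Local false discovery rate of joint association
#'
#' `locfdr_m = 1 - Pr(Z_m11 = 1 | p_m1, p_m2)`: the posterior probability that
#' SNP m is NOT shared between the two traits.
#'
#' @inheritParams posterior_z
#' @return numeric vector of length M in \\[0, 1\\], named by SNP id.
#' @export
local_fdr_11 <- function(fit, data, p_floor = 1e-30) {
  w <- posterior_z(fit, data, p_floor = p_floor)
  1 - w[, "11"]
}

#' @export
print.gpa_pair_fit <- function(x, ...) {
  cat("Four-group Beta-Uniform mixture fit\n")
  cat("  pi (00,10,01,11):", paste(format(round(x$pi, 4)), collapse = ", "), "\n")
  cat(sprintf("  alpha1 = %.4f, alpha2 = %.4f\n", x$alpha1, x$alpha2))
  cat(sprintf("  loglik = %.3f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat(sprintf("Two-group Beta-Uniform fit: pi1 = %.4f, alpha = %.4f, loglik = %.3f\n",
              x$pi1, x$alpha, x$loglik))
  invisible(x)
}
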