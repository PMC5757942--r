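#' Joint association mapping for a phenotype pair
#'
#' Selects the SNPs assigned to a joint association pattern at a user global
#' false discovery rate. Each SNP's local FDR is one minus its posterior
#' probability of the pattern component (pattern `"11"`: shared by both
#' traits). SNPs are sorted by ascending local FDR and the largest prefix
#' whose running mean local FDR stays at or below `global_fdr` is returned
#' (the direct posterior probability rule: the mean local FDR of the selected
#' set estimates its global FDR).
#'
#' @param fit a `gpa_pair_fit` from [fit_pair_em()].
#' @param data the [pair_data()] the fit was computed on.
#' @param global_fdr target global FDR level in (0, 1).
#' @param pattern joint association pattern, one of `"11"`, `"10"`, `"01"`,
#'   `"00"` (default `"11"`).
#' @return object of class `assoc_table`: a `data.frame` with columns
#'   `snp_id` and `local_fdr` (ascending, possibly zero rows), plus
#'   attributes `pattern` and `global_fdr_level`.
#' @export
joint_assoc <- function(fit, data, global_fdr = 0.05, pattern = "11") {
  stopifnot(inherits(fit, "gpa_pair_fit"))
  if (!is.numeric(global_fdr) || length(global_fdr) != 1L ||
      global_fdr <= 0 || global_fdr >= 1) {
    stop_invalid("global_fdr must lie in (0, 1)")
  }
  if (!is.character(pattern) || length(pattern) != 1L ||
      !pattern %in% c("00", "10", "01", "11")) {
    stop_invalid("pattern must be one of \"00\", \"10\", \"01\", \"11\"")
  }
  if (!fit$converged) {
    warning("EM fit did not converge; association table may be unreliable")
  }
  w <- posterior_z(fit, data)
  locfdr <- 1 - w[, pattern]
  ord <- order(locfdr)  # stable: ties keep input order
  sorted <- locfdr[ord]
  keep <- cumsum(sorted) / seq_along(sorted) <= global_fdr
  n_sel <- if (any(keep)) max(which(keep)) else 0L
  idx <- ord[seq_len(n_sel)]
  tab <- data.frame(snp_id = data$snp_ids[idx],
                    local_fdr = unname(locfdr[idx]),
                    stringsAsFactors = FALSE)
  structure(tab, pattern = pattern, global_fdr_level = global_fdr,
            class = c("assoc_table", "data.frame"))
}

#' Write an association table to CSV
#'
#' @param table an `assoc_table` from [joint_assoc()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_assoc_table <- function(table, path) {
  stopifnot(inherits(table, "assoc_table"))
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Joint association table: %d SNP(s) at global FDR %.3g (pattern \"%s\")\n",
              nrow(x), attr(x, "global_fdr_level"), attr(x, "pattern")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
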