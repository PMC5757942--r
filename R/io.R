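#' Read a p-value matrix from delimited text
#'
#' Expects a rectangular table with a header row of phenotype names and a
#' first column of SNP identifiers (both auto-detected; missing labels are
#' generated with a warning). Values must be numeric and lie in \\[0, 1\\]:
#' values above 1 or below 0 are rejected with the offending cell named;
#' zeros are raised to `clip_floor` when `clip = TRUE` (logged) and rejected
#' otherwise. Rows containing missing values are dropped with a logged count.
#'
#' @param path input file.
#' @param delimiter field separator; `NULL` (default) auto-detects from the
#'   extension (`.csv` is comma, everything else tab).
#' @param clip raise zero p-values to `clip_floor` instead of erroring.
#' @param clip_floor lower clip bound (default 1e-30).
#' @return numeric M x K matrix with SNP ids as rownames and phenotype names
#'   as colnames.
#' @export
read_pvalue_matrix <- function(path, delimiter = NULL, clip = TRUE,
                               clip_floor = 1e-30) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  sep <- delimiter %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # check the raw header: fread would silently de-duplicate repeated names
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr)) stop_invalid("phenotype names must be unique")
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2L) stop_invalid("expected a SNP id column plus phenotype columns")
  snp_ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  phen <- colnames(vals)
  if (is.null(phen) || any(phen == "") || any(grepl("^V\\d+$", phen))) {
    warning("missing phenotype names in header; generating GWAS_1..GWAS_K")
    phen <- sprintf("GWAS_%d", seq_len(ncol(vals)))
  }
  if (anyDuplicated(phen)) stop_invalid("phenotype names must be unique")
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      stop_invalid(sprintf("non-numeric p-value at row %d, column '%s'",
                           bad %||% 1L, phen[j]))
    }
  }
  m <- as.matrix(vals)
  drop_rows <- apply(m, 1, anyNA)
  if (any(drop_rows)) {
    message("dropped ", sum(drop_rows), " row(s) with missing values")
    m <- m[!drop_rows, , drop = FALSE]
    snp_ids <- snp_ids[!drop_rows]
  }
  if (nrow(m) == 0L) stop_invalid("no rows left after filtering")
  bad <- which(m > 1 | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid(sprintf("p-value %g out of [0, 1] at row %d (SNP '%s'), column '%s'",
                         m[bad[1, 1], bad[1, 2]], bad[1, 1],
                         snp_ids[bad[1, 1]], phen[bad[1, 2]]))
  }
  zeros <- m < clip_floor
  if (any(zeros)) {
    if (!clip) {
      idx <- which(zeros, arr.ind = TRUE)
      stop_invalid(sprintf("p-value below clip floor at row %d, column '%s' (set clip = TRUE to clip)",
                           idx[1, 1], phen[idx[1, 2]]))
    }
    message("clipped ", sum(zeros), " p-value(s) up to the floor ", clip_floor)
    m[zeros] <- clip_floor
  }
  dimnames(m) <- list(snp_ids, phen)
  m
}

#' Write a p-value matrix to TSV
#'
#' @param pmat numeric matrix with SNP rownames and phenotype colnames.
#' @param path output path (tab-separated; use a `.csv` extension and
#'   `sep = ","` for CSV).
#' @param sep field separator.
#' @return invisibly, the path.
#' @export
write_pvalue_matrix <- function(pmat, path, sep = "\t") {
  stopifnot(is.matrix(pmat), is.numeric(pmat))
  dt <- data.table::as.data.table(pmat, keep.rownames = "snp_id")
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunables of the full fit -> transform -> embed -> cluster ->
#' assoc pipeline.
#'
#' @param lambda Box-Cox parameter (default 0, the log transform).
#' @param epsilon neighborhood radius or `"auto"` (default `"auto"`).
#' @param ndim embedding dimension.
#' @param n_clusters number of clusters; `NULL` skips clustering.
#' @param cluster_method `"kmeans"` or `"hierarchical"`.
#' @param global_fdr global FDR level for association tables.
#' @param assoc_pairs list of `c(i, j)` phenotype index pairs for which to
#'   produce association tables (default none).
#' @param em an [em_control()] list.
#' @param seed seed for the clustering stage.
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param write_plot also export the map as PDF and PNG (PDF output embeds a
#'   creation timestamp, so plots are excluded from byte-identity guarantees).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(lambda = 0, epsilon = "auto", ndim = 2L,
                            n_clusters = NULL, cluster_method = "kmeans",
                            global_fdr = 0.05, assoc_pairs = list(),
                            em = em_control(), seed = 1L, out_dir = NULL,
                            write_plot = FALSE) {
  structure(list(lambda = lambda, epsilon = epsilon, ndim = as.integer(ndim),
                 n_clusters = n_clusters, cluster_method = cluster_method,
                 global_fdr = global_fdr, assoc_pairs = assoc_pairs,
                 em = em, seed = as.integer(seed), out_dir = out_dir,
                 write_plot = isTRUE(write_plot)),
            class = "pipeline_config")
}

#' Run the full pleiotropy-mapping pipeline
#'
#' Orchestrates [pairwise_pleiotropy()], [transform_distance_matrix()],
#' [isomap_embed()], optional [cluster_phenotypes()] and optional
#' [joint_assoc()] for requested pairs. When `config$out_dir` is set, all
#' results are written there (TSV/CSV/JSON) together with a JSON run manifest
#' recording package version, configuration, seed and timestamp. Given the
#' same input, configuration and seed, all data outputs are byte-identical
#' across runs (the manifest timestamp and plot files are informational).
#'
#' @param pmat numeric p-value matrix (or a `sim_result`).
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return object of class `pleiomap_run`: `pleio` (`pleio_matrix`),
#'   `transformed` (`transformed_dist`), `map` (`phenotype_map`, with
#'   clusters if requested), `assoc` (named list of `assoc_table`s),
#'   `manifest`.
#' @export
run_pipeline <- function(pmat, config = pipeline_config(), verbose = FALSE) {
  if (inherits(pmat, "sim_result")) pmat <- pmat$pvalues
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("pipeline stage '%s' failed: %s",
                                  name, conditionMessage(e)),
                          class = c("pleiomap_pipeline_error", "error")))
    })
  }
  pleio <- stage("fit", pairwise_pleiotropy(pmat, config$em, verbose = verbose))
  td <- stage("transform", transform_distance_matrix(pleio, config$lambda))
  map <- stage("embed", isomap_embed(td, embedding_config(
    epsilon = config$epsilon, ndim = config$ndim, lambda = config$lambda)))
  if (!is.null(config$n_clusters)) {
    map <- stage("cluster", cluster_phenotypes(
      map, config$n_clusters, method = config$cluster_method, seed = config$seed))
  }
  assoc <- list()
  for (pr in config$assoc_pairs) {
    i <- pr[1]; j <- pr[2]
    key <- paste0(pleio$phenotype_names[i], ":", pleio$phenotype_names[j])
    assoc[[key]] <- stage(paste0("assoc ", key), joint_assoc(
      pleio$pair_fits[[paste0(min(i, j), ":", max(i, j))]],
      pair_data(pmat[, min(i, j)], pmat[, max(i, j)],
                rownames(pmat) %||% sprintf("snp_%d", seq_len(nrow(pmat)))),
      global_fdr = config$global_fdr))
  }
  manifest <- list(
    package = "pleiomap",
    version = as.character(utils::packageVersion("pleiomap")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_snps = nrow(pmat), n_pheno = ncol(pmat),
    phenotypes = pleio$phenotype_names,
    n_pair_fits = length(pleio$pair_fits),
    config = list(lambda = config$lambda, epsilon = map$config$epsilon,
                  ndim = config$ndim, n_clusters = config$n_clusters,
                  cluster_method = config$cluster_method,
                  global_fdr = config$global_fdr, seed = config$seed),
    em = list(tol = config$em$tol, max_iter = config$em$max_iter),
    pair_convergence = lapply(pleio$pair_fits, function(f)
      list(n_iter = f$n_iter, converged = f$converged))
  )
  out <- structure(list(pleio = pleio, transformed = td, map = map,
                        assoc = assoc, manifest = manifest),
                   class = "pleiomap_run")
  if (!is.null(config$out_dir)) write_run(out, config)
  out
}

write_run <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  write_pleio_matrix(run$pleio, pth("pleiotropy_pvalues.tsv"), pth("pair_fits.json"))
  write_phenotype_map(run$map, pth("coordinates.tsv"))
  for (key in names(run$assoc)) {
    fname <- paste0("assoc_", gsub("[^A-Za-z0-9_.-]", "_", key), ".csv")
    write_assoc_table(run$assoc[[key]], pth(fname))
  }
  jsonlite::write_json(run$manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (config$write_plot) {
    title <- "pleiomap"
    grDevices::pdf(pth(paste0(title, "-Shinyplot.pdf")), width = 7, height = 7)
    plot(run$map)
    grDevices::dev.off()
    grDevices::png(pth(paste0(title, "-Shinyplot.png")), width = 700, height = 700)
    plot(run$map)
    grDevices::dev.off()
  }
  invisible(config$out_dir)
}

#' @export
print.pleiomap_run <- function(x, ...) {
  cat("pleiomap pipeline run\n")
  cat(sprintf("  %d SNPs x %d phenotypes, %d pair fits\n",
              x$manifest$n_snps, x$manifest$n_pheno, x$manifest$n_pair_fits))
  print(x$map)
  invisible(x)
}
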