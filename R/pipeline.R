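#' Configuration for a pipeline run
#'
#' Collects the effective parameters of a command-line or scripted run so
#' that every output can be traced back to its inputs, seed and settings.
#'
#' @param command one of `"estimate"`, `"simulate"`, `"permute-null"`,
#'   `"diff"`, `"eval"`.
#' @param input character vector of input paths (format-dependent).
#' @param format count format, `"tsv"` or `"mtx-dir"`.
#' @param out_prefix path prefix for all output files.
#' @param seed integer seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param tol,max_iter IRLS settings.
#' @param alpha significance threshold for downstream module steps.
#' @param top_genes optional; restrict to this many top expressed genes.
#' @param B permutations for the differential test.
#' @return a `"run_config"` list.
#' @export
run_config <- function(command, input, out_prefix, format = "tsv",
                       seed = 1L, tol = 0.05, max_iter = 10, alpha = 0.05,
                       top_genes = NULL, B = 100) {
  if (tol <= 0) stop("tol must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(command = command, input = input, out_prefix = out_prefix,
                 format = format, seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter), alpha = alpha,
                 top_genes = top_genes, B = as.integer(B)),
            class = "run_config")
}

.write_manifest <- function(cfg, extra, path) {
  manifest <- c(
    list(package = "umicoex",
         version = as.character(utils::packageVersion("umicoex"))),
    unclass(cfg), extra
  )
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Estimate a co-expression network from files on disk
#'
#' Reads counts, optionally restricts to the top expressed genes, estimates
#' the network, and writes rho/p/q matrices, a long edge list, a per-gene
#' flag report, and a JSON run manifest recording the seed, settings,
#' convergence trace and diagnostic counts.
#'
#' @param cfg a [run_config()] with `command = "estimate"` and a single
#'   input path.
#' @return invisibly, the `coexp_result`.
#' @export
run_estimate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  cm <- read_counts(cfg$input[1], format = cfg$format)
  if (!is.null(cfg$top_genes)) cm <- top_expressed_genes(cm, cfg$top_genes)
  res <- estimate_network(cm, tol = cfg$tol, max_iter = cfg$max_iter)
  paths <- write_network(res, cfg$out_prefix)
  .write_manifest(cfg, list(
    n_cells = nrow(cm$counts), n_genes = ncol(cm$counts),
    theta = res$est$theta, iterations = res$est$iterations,
    converged = res$est$converged, delta_trace = res$est$delta_trace,
    n_flagged = sum(res$flags != "OK"), n_clipped = res$n_clipped,
    outputs = as.list(paths)
  ), paste0(cfg$out_prefix, "_manifest.json"))
  invisible(res)
}

#' Differential co-expression between two count files
#'
#' Reads both groups, balances cell numbers, runs the label-permutation
#' differential test, extracts modules from the significant differential
#' network, and writes an edge list (`delta`, `p`, `q`), a module membership
#' table and a JSON manifest.
#'
#' @param cfg a [run_config()] with `command = "diff"` and two input paths.
#' @param k number of modules to cut (default 4).
#' @return invisibly, the `differential_result`.
#' @export
run_diff <- function(cfg, k = 4) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(cfg$input) != 2) stop("diff needs exactly two input paths")
  cm1 <- read_counts(cfg$input[1], format = cfg$format)
  cm2 <- read_counts(cfg$input[2], format = cfg$format)
  if (!is.null(cfg$top_genes)) {
    cm1 <- top_expressed_genes(cm1, cfg$top_genes)
    cm2 <- top_expressed_genes(cm2, cfg$top_genes)
  }
  bal <- subsample_balance(cm1, cm2, seed = cfg$seed)
  res <- differential_test(bal$cm1, bal$cm2, B = cfg$B, seed = cfg$seed,
                           tol = cfg$tol, max_iter = cfg$max_iter)
  ut <- upper.tri(res$delta_rho)
  idx <- which(ut, arr.ind = TRUE)
  edges <- data.frame(
    gene_i = rownames(res$delta_rho)[idx[, 1]],
    gene_j = colnames(res$delta_rho)[idx[, 2]],
    delta_rho = res$delta_rho[ut],
    pval = res$perm_pval[ut],
    qval = res$qval[ut]
  )
  utils::write.table(edges, paste0(cfg$out_prefix, "_diff_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  modules <- extract_modules(res$delta_rho,
                             significant = res$qval < cfg$alpha, k = k)
  utils::write.table(
    data.frame(gene = names(modules), module = unname(modules)),
    paste0(cfg$out_prefix, "_modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  .write_manifest(cfg, list(
    n_cells_per_group = nrow(bal$cm1$counts),
    n_genes = ncol(bal$cm1$counts),
    n_significant = sum(res$qval[ut] < cfg$alpha, na.rm = TRUE),
    k = k
  ), paste0(cfg$out_prefix, "_manifest.json"))
  invisible(res)
}
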