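#' Read a UMI count matrix from disk
#'
#' Two plain-text layouts are supported:
#'
#' * `"mtx-dir"`: a directory holding a Matrix Market file (`matrix.mtx`)
#'   plus annotation TSVs for genes (`genes.tsv`, or `features.tsv`) and
#'   cells (`barcodes.tsv`), following the 10x triplet convention. By default
#'   the matrix is stored genes x cells and is transposed on read; set
#'   `orientation = "cells-by-genes"` for the other dialect. An optional
#'   `depths.tsv` (one depth per cell) preserves full-transcriptome depths
#'   for matrices that were subset to a gene panel.
#' * `"tsv"`: a dense tab-separated table with a header row of gene
#'   identifiers, a first column `cell_id`, and an optional second column
#'   `depth`; remaining columns are counts.
#'
#' @param path file (tsv) or directory (mtx-dir) to read.
#' @param format `"mtx-dir"` or `"tsv"`.
#' @param orientation for `"mtx-dir"`, how the stored matrix is laid out.
#' @return a [count_matrix()]; depths come from the depth annotation when
#'   present, otherwise from row sums.
#' @export
read_counts <- function(path, format = c("mtx-dir", "tsv"),
                        orientation = c("genes-by-cells", "cells-by-genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx-dir") {
    if (!dir.exists(path)) stop("not a directory: ", path)
    mtx_file <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx_file)) stop("missing matrix.mtx in ", path)
    gene_file <- file.path(path, "genes.tsv")
    if (!file.exists(gene_file)) gene_file <- file.path(path, "features.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    if (!file.exists(gene_file) || !file.exists(bc_file)) {
      stop("missing gene/barcode annotation TSVs in ", path)
    }
    m <- as.matrix(Matrix::readMM(mtx_file))
    if (orientation == "genes-by-cells") m <- t(m)
    genes <- utils::read.delim(gene_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bc_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != ncol(m) || length(cells) != nrow(m)) {
      stop("annotation dimensions do not match the matrix")
    }
    depth_file <- file.path(path, "depths.tsv")
    depths <- NULL
    if (file.exists(depth_file)) {
      depths <- utils::read.delim(depth_file, header = FALSE)[[1]]
    }
    count_matrix(m, gene_ids = genes, cell_ids = cells, depths = depths)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty count table: ", path)
    if (colnames(tab)[1] != "cell_id") {
      stop("dense TSV must have a leading cell_id column")
    }
    cells <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
    depths <- NULL
    if (ncol(tab) > 0 && colnames(tab)[1] == "depth") {
      depths <- as.numeric(tab[[1]])
      tab <- tab[, -1, drop = FALSE]
    }
    if (ncol(tab) == 0L) stop("count table has no gene columns")
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric entries in count table")
    count_matrix(m, gene_ids = colnames(tab), cell_ids = cells,
                 depths = depths)
  }
}

#' Write a UMI count matrix to disk
#'
#' Inverse of [read_counts()]: serialization is lossless, including depths
#' (written even when they equal row sums, so that gene-subset matrices
#' round-trip exactly).
#'
#' @param cm a [count_matrix()].
#' @param path output file (tsv) or directory (mtx-dir; created if absent).
#' @param format `"mtx-dir"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
write_counts <- function(cm, path, format = c("mtx-dir", "tsv")) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx-dir") {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create directory: ", path)
    }
    # stored genes x cells, the 10x convention
    m <- Matrix::Matrix(t(cm$counts), sparse = TRUE)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(cm), file.path(path, "genes.tsv"))
    writeLines(cell_ids(cm), file.path(path, "barcodes.tsv"))
    writeLines(format(cm$depths, scientific = FALSE, trim = TRUE),
               file.path(path, "depths.tsv"))
  } else {
    dir_ok <- dir.exists(dirname(path))
    if (!dir_ok) stop("cannot write to: ", path)
    tab <- data.frame(cell_id = cell_ids(cm), depth = cm$depths,
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(cm$counts, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a co-expression network as matrix and edge-list TSVs
#'
#' @param res a `coexp_result` from [estimate_network()].
#' @param prefix output path prefix; files `<prefix>_rho.tsv`,
#'   `<prefix>_pval.tsv`, `<prefix>_qval.tsv`, `<prefix>_edges.tsv` and
#'   `<prefix>_flags.tsv` are written.
#' @return invisibly, the vector of file paths written.
#' @export
write_network <- function(res, prefix) {
  stopifnot(inherits(res, "coexp_result"))
  paths <- c(
    rho = paste0(prefix, "_rho.tsv"),
    pval = paste0(prefix, "_pval.tsv"),
    qval = paste0(prefix, "_qval.tsv"),
    edges = paste0(prefix, "_edges.tsv"),
    flags = paste0(prefix, "_flags.tsv")
  )
  write_mat <- function(m, f) {
    utils::write.table(
      data.frame(gene = rownames(m), m, check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  write_mat(res$rho, paths[["rho"]])
  write_mat(res$pval, paths[["pval"]])
  write_mat(res$qval, paths[["qval"]])
  utils::write.table(as_edge_list(res), paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(res$flags), flag = unname(res$flags)),
    paths[["flags"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}

#' Long-format edge list of a co-expression network
#'
#' @param res a `coexp_result`.
#' @return data.frame with columns `gene_i`, `gene_j`, `rho`, `tstat`,
#'   `pval`, `qval`, one row per unordered gene pair.
#' @export
as_edge_list <- function(res) {
  stopifnot(inherits(res, "coexp_result"))
  ut <- upper.tri(res$rho)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(
    gene_i = rownames(res$rho)[idx[, 1]],
    gene_j = colnames(res$rho)[idx[, 2]],
    rho = res$rho[ut],
    tstat = res$tstat[ut],
    pval = res$pval[ut],
    qval = res$qval[ut]
  )
}
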