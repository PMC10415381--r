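#' Cell-by-gene UMI count matrix with sequencing depths
#'
#' The basic data container of the package: an `n x p` matrix of non-negative
#' integer UMI counts (cells in rows, genes in columns) together with per-cell
#' sequencing depths `s_i`. The depth of a cell is the total UMI count of that
#' cell over *all* genes profiled in the experiment; when counts are subset to
#' a gene panel the depths must still reflect the full-transcriptome totals,
#' which is why they are carried alongside the matrix rather than recomputed.
#'
#' @param counts numeric matrix of non-negative integers, cells x genes.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(counts)` or `"g1".."gp"`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `rownames(counts)` or `"c1".."cn"`).
#' @param depths optional positive numeric vector of per-cell sequencing
#'   depths. If omitted, row sums of `counts` are used (appropriate when
#'   `counts` holds the full gene set).
#'
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (integer matrix with dimnames), `depths`, and `meta` (a list
#'   for provenance such as permutation target depths).
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                         depths = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) {
    stop("count matrix is empty")
  }
  if (any(is.na(counts))) {
    stop("count matrix contains missing values")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  p <- ncol(counts)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(n))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != p) stop("gene_ids length does not match ncol(counts)")
  if (length(cell_ids) != n) stop("cell_ids length does not match nrow(counts)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(depths)) {
    depths <- rowSums(counts)
    if (any(depths <= 0)) {
      stop("cells with zero total counts: supply depths or drop these cells")
    }
  } else {
    depths <- as.numeric(depths)
    if (length(depths) != n) stop("depths length does not match number of cells")
    if (any(!is.finite(depths)) || any(depths <= 0)) {
      stop("depths must be positive and finite")
    }
  }
  structure(
    list(counts = counts, depths = unname(depths), meta = list()),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d cells x %d genes; depth median %s (range %s-%s)\n",
    nrow(x$counts), ncol(x$counts),
    format(stats::median(x$depths)), format(min(x$depths)),
    format(max(x$depths))
  ))
  nz <- zero_genes(x)
  if (any(nz)) cat(sprintf("  %d gene(s) with all-zero counts\n", sum(nz)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene and cell identifiers of a count matrix
#' @param cm a [count_matrix()].
#' @return character vector of identifiers.
#' @export
gene_ids <- function(cm) colnames(cm$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(cm) rownames(cm$counts)

#' Genes with zero counts in every cell
#'
#' Such genes carry no information about latent expression and their moment
#' estimates are degenerate; estimation routines flag and exclude them.
#'
#' @param cm a [count_matrix()].
#' @return logical vector, length `p`.
#' @export
zero_genes <- function(cm) {
  colSums(cm$counts > 0) == 0
}

#' Keep the most highly expressed genes
#'
#' Ranks genes by mean depth-normalized expression (`mean over cells of
#' x_ij / s_i`) and keeps the top `k`. Sequencing depths are *not* recomputed:
#' they remain the full-matrix depths, matching the definition of depth as the
#' total molecule count of the cell.
#'
#' @param cm a [count_matrix()].
#' @param k positive integer, number of genes to keep (`k <= p`).
#' @return a [count_matrix()] with `k` genes and unchanged depths.
#' @export
top_expressed_genes <- function(cm, k) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(k) != 1L || !is.finite(k) || k <= 0 || k != round(k)) {
    stop("k must be a positive integer")
  }
  p <- ncol(cm$counts)
  if (k > p) stop("k exceeds the number of genes")
  mean_norm <- colMeans(cm$counts / cm$depths)
  keep <- order(mean_norm, decreasing = TRUE)[seq_len(k)]
  keep <- sort(keep)  # preserve original gene order among the selected
  out <- cm
  out$counts <- cm$counts[, keep, drop = FALSE]
  out
}

#' Subset cells of a count matrix
#'
#' @param cm a [count_matrix()].
#' @param idx integer or logical index over cells.
#' @return a [count_matrix()] with the selected cells and their depths.
#' @export
subset_cells <- function(cm, idx) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- cm
  out$counts <- cm$counts[idx, , drop = FALSE]
  out$depths <- cm$depths[idx]
  out
}
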