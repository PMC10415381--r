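#' Balance two cell groups by downsampling the larger one
#'
#' Co-expression estimates from groups of very different sizes have unequal
#' precision; before differencing them, the larger group is downsampled
#' without replacement to the size of the smaller.
#'
#' @param cm1,cm2 [count_matrix()] objects over the same gene panel.
#' @param seed optional integer seed.
#' @return list with elements `cm1`, `cm2`, both of the smaller size.
#' @export
subsample_balance <- function(cm1, cm2, seed = NULL) {
  stopifnot(inherits(cm1, "count_matrix"), inherits(cm2, "count_matrix"))
  if (!identical(gene_ids(cm1), gene_ids(cm2))) {
    stop("the two groups must share the same gene panel")
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- nrow(cm1$counts)
  n2 <- nrow(cm2$counts)
  m <- min(n1, n2)
  if (n1 > m) cm1 <- subset_cells(cm1, sort(sample.int(n1, m)))
  if (n2 > m) cm2 <- subset_cells(cm2, sort(sample.int(n2, m)))
  list(cm1 = cm1, cm2 = cm2)
}

#' Two-group differential co-expression with a label-permutation test
#'
#' Estimates a co-expression network in each group, takes the pairwise
#' difference `delta_rho = rho_1 - rho_2`, and assesses significance by
#' permutation: cells are pooled and randomly re-split into two pseudo-groups
#' of the original (balanced) sizes `B` times, the full network estimate is
#' recomputed on each pseudo-group, and the two-sided empirical p value of a
#' pair is `(1 + #{b : |delta^(b)| >= |delta|}) / (1 + B)` (the add-one
#' estimator, so p is never exactly zero). Benjamini-Hochberg adjustment is
#' applied across all tested pairs.
#'
#' Inputs should be balanced (see [subsample_balance()]); a warning is
#' issued otherwise. Pairs involving a gene flagged in either group's
#' estimate are excluded from testing and report `p = q = 1`.
#'
#' @param cm1,cm2 [count_matrix()] objects over the same gene panel.
#' @param B number of label permutations (default 100).
#' @param seed optional integer seed governing all permutations.
#' @param tol,max_iter passed to [estimate_network()].
#' @return an object of class `"differential_result"`: list with matrices
#'   `delta_rho`, `perm_pval`, `qval`, the per-group `coexp_result`s, the
#'   combined per-gene `flags`, `n_permutations` and `seed`.
#' @export
differential_test <- function(cm1, cm2, B = 100, seed = NULL,
                              tol = 0.05, max_iter = 10) {
  stopifnot(inherits(cm1, "count_matrix"), inherits(cm2, "count_matrix"))
  if (B < 1) stop("B must be at least 1")
  if (!identical(gene_ids(cm1), gene_ids(cm2))) {
    stop("the two groups must share the same gene panel")
  }
  n1 <- nrow(cm1$counts)
  n2 <- nrow(cm2$counts)
  if (n1 != n2) {
    warning("groups are unbalanced (", n1, " vs ", n2,
            "); consider subsample_balance()")
  }
  if (!is.null(seed)) set.seed(seed)
  net1 <- estimate_network(cm1, tol = tol, max_iter = max_iter, tests = FALSE)
  net2 <- estimate_network(cm2, tol = tol, max_iter = max_iter, tests = FALSE)
  delta <- net1$rho - net2$rho
  p <- ncol(delta)
  genes <- colnames(delta)
  ok <- net1$flags == "OK" & net2$flags == "OK"

  pooled <- rbind(cm1$counts, cm2$counts)
  pooled_depths <- c(cm1$depths, cm2$depths)
  rownames(pooled) <- paste0("cell", seq_len(nrow(pooled)))
  ntot <- nrow(pooled)
  ut <- upper.tri(delta)
  obs <- abs(delta[ut])
  exceed <- integer(length(obs))
  for (b in seq_len(B)) {
    idx <- sample.int(ntot, n1)
    cma <- count_matrix(pooled[idx, , drop = FALSE],
                        depths = pooled_depths[idx])
    cmb <- count_matrix(pooled[-idx, , drop = FALSE],
                        depths = pooled_depths[-idx])
    neta <- suppressWarnings(
      estimate_network(cma, tol = tol, max_iter = max_iter, tests = FALSE))
    netb <- suppressWarnings(
      estimate_network(cmb, tol = tol, max_iter = max_iter, tests = FALSE))
    db <- abs((neta$rho - netb$rho)[ut])
    exceed <- exceed + (db >= obs)
  }
  pv <- (1 + exceed) / (1 + B)
  perm_pval <- matrix(1, p, p, dimnames = list(genes, genes))
  perm_pval[ut] <- pv
  perm_pval[lower.tri(perm_pval)] <- t(perm_pval)[lower.tri(perm_pval)]
  diag(perm_pval) <- NA_real_
  perm_pval[!ok, ] <- 1
  perm_pval[, !ok] <- 1

  qval <- matrix(1, p, p, dimnames = list(genes, genes))
  tested <- ut & outer(ok, ok, "&")
  qval[tested] <- bh_adjust(perm_pval[tested])
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(qval) <- NA_real_

  flags <- ifelse(ok, "OK", "FLAGGED")
  names(flags) <- genes
  structure(
    list(delta_rho = delta, perm_pval = perm_pval, qval = qval,
         net1 = net1, net2 = net2, flags = flags,
         n_permutations = as.integer(B), seed = seed),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  p <- ncol(x$delta_rho)
  ut <- upper.tri(x$qval)
  cat(sprintf(
    "differential_result: %d genes, %d permutations; %d pair(s) with q < 0.05\n",
    p, x$n_permutations, sum(x$qval[ut] < 0.05, na.rm = TRUE)
  ))
  invisible(x)
}

#' Extract gene modules from a weighted network
#'
#' Builds an adjacency matrix as the absolute edge weights (soft-threshold
#' power 1), optionally masked to significant pairs, and applies
#' average-linkage hierarchical clustering. The default dissimilarity is one
#' minus the topological overlap of the adjacency — the standard
#' co-expression module measure, which scores two genes as close when they
#' share neighbors and is therefore much less sensitive to noise in any
#' single edge than the raw adjacency (`dissimilarity = "adjacency"` uses
#' `1 - adjacency` directly). The tree is cut either to `k` clusters or at
#' height `h`. Genes with no edges (flagged genes, or genes whose every pair
#' is non-significant) are left unassigned (`NA`, the conventional "grey"
#' module) rather than consuming clusters.
#'
#' @param weights symmetric `p x p` weight matrix (e.g. co-expression or
#'   differential co-expression estimates).
#' @param significant optional logical mask of the same shape; edges outside
#'   the mask are set to 0. If the mask is empty a single trivial module is
#'   returned with a warning.
#' @param k desired number of modules (used if `h` is `NULL`).
#' @param h cut height on the dendrogram, in `[0, 1]`.
#' @param dissimilarity `"tom"` (topological overlap, default) or
#'   `"adjacency"`.
#' @param strong_only if `TRUE`, restrict to genes whose total absolute
#'   weight over significant edges exceeds the median (a "strong signal"
#'   node filter); other genes get label `NA`.
#' @return integer module labels named by gene, with attribute `"sizes"`.
#' @export
extract_modules <- function(weights, significant = NULL, k = NULL, h = NULL,
                            dissimilarity = c("tom", "adjacency"),
                            strong_only = FALSE) {
  dissimilarity <- match.arg(dissimilarity)
  W <- as.matrix(weights)
  p <- ncol(W)
  if (max(abs(W - t(W)), na.rm = TRUE) > 1e-8) stop("weights must be symmetric")
  genes <- colnames(W)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  A <- abs(W)
  A[is.na(A)] <- 0
  if (!is.null(significant)) {
    A[!significant] <- 0
  }
  diag(A) <- 0
  keep <- rep(TRUE, p)
  if (strong_only) {
    strength <- rowSums(A)
    keep <- strength > stats::median(strength)
    if (!any(keep)) keep <- rep(TRUE, p)
    A <- A[keep, keep, drop = FALSE]
  }
  if (all(A == 0)) {
    warning("no significant edges; returning a single trivial module")
    labels <- stats::setNames(rep(NA_integer_, p), genes)
    labels[keep] <- 1L
    attr(labels, "sizes") <- table(labels)
    return(labels)
  }
  # genes with no edges at all (flagged or entirely non-significant) stay
  # unassigned rather than consuming clusters -- the "grey module"
  # convention of co-expression analysis
  conn <- rowSums(A) > 0
  keep[keep] <- conn
  A <- pmin(A[conn, conn, drop = FALSE], 1)
  D <- if (dissimilarity == "tom") .tom_dissimilarity(A) else 1 - A
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cut <- if (!is.null(h)) stats::cutree(hc, h = h)
  else stats::cutree(hc, k = if (is.null(k)) 2 else k)
  labels <- stats::setNames(rep(NA_integer_, p), genes)
  labels[keep] <- cut
  attr(labels, "sizes") <- table(labels)
  labels
}

# 1 - topological overlap: omega_jj' = (sum_u a_ju a_uj' + a_jj') /
# (min(k_j, k_j') + 1 - a_jj'), with k the connectivity (row sum)
.tom_dissimilarity <- function(A) {
  diag(A) <- 0
  k <- rowSums(A)
  shared <- A %*% A
  W <- (shared + A) / (outer(k, k, pmin) + 1 - A)
  diag(W) <- 1
  1 - W
}
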