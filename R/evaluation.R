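#' Attenuation factor of count-based correlations
#'
#' Measuring co-expression from raw counts shrinks the latent correlation of
#' a pair toward zero by the product of per-gene attenuation factors
#' \deqn{a = \sqrt{\frac{s\,\mathrm{CV}^2}{1/\mu + s\,\mathrm{CV}^2}},}
#' where `s` is the sequencing depth, `mu` the latent expression level and
#' `CV` its coefficient of variation (`sqrt(sigma_jj)/mu`). The factor lies
#' in (0, 1), is strictly increasing in each argument, and approaches 1 for
#' highly expressed genes — the origin of the mean-correlation bias.
#'
#' @param s,mu,cv strictly positive numerics (vectorized).
#' @return attenuation factor(s) in (0, 1).
#' @export
attenuation_factor <- function(s, mu, cv) {
  if (any(s <= 0) || any(mu <= 0) || any(cv <= 0)) {
    stop("s, mu and cv must be strictly positive")
  }
  sqrt(s * cv^2 / (1 / mu + s * cv^2))
}

#' Per-gene average co-expression
#'
#' The mean of a gene's co-expressions with all other genes (off-diagonal
#' entries of its row). On null data this profile should center at zero for
#' every expression level.
#'
#' @param rho symmetric `p x p` co-expression matrix.
#' @return numeric vector of length `p`, named as `rho`'s columns.
#' @export
average_coexpression <- function(rho) {
  rho <- as.matrix(rho)
  p <- ncol(rho)
  if (p < 2) stop("need at least two genes")
  if (max(abs(rho - t(rho)), na.rm = TRUE) > 1e-8) stop("rho must be symmetric")
  out <- (rowSums(rho, na.rm = FALSE) - diag(rho)) / (p - 1)
  stats::setNames(out, colnames(rho))
}

#' Precision-recall curve and area for pair classification
#'
#' Sweeps a threshold over pair scores and reports precision and recall at
#' every cut, plus the area under the curve by the trapezoid rule over
#' recall. Scores may be p values (smaller = more significant,
#' `ordering = "pvalue_asc"`) or absolute estimates
#' (`ordering = "abs_desc"`).
#'
#' @param scores numeric vector of pair scores.
#' @param truth logical vector, `TRUE` for truly co-expressed pairs.
#' @param ordering `"pvalue_asc"` or `"abs_desc"`.
#' @return list with `curve` (data.frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
precision_recall <- function(scores, truth,
                             ordering = c("pvalue_asc", "abs_desc")) {
  ordering <- match.arg(ordering)
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  truth <- as.logical(truth)
  P <- sum(truth)
  if (P == 0) stop("no positive pairs; precision-recall undefined")
  key <- if (ordering == "abs_desc") -abs(scores) else scores
  ord <- order(key)
  key <- key[ord]
  truth <- truth[ord]
  tp <- cumsum(truth)
  k <- seq_along(truth)
  # evaluate at the last index of each tied score block
  last <- which(c(diff(key) != 0, TRUE))
  recall <- tp[last] / P
  precision <- tp[last] / k[last]
  # prepend the (0, precision of first block) anchor for the trapezoid
  r <- c(0, recall)
  pr <- c(precision[1], precision)
  auc <- sum(diff(r) * (utils::head(pr, -1) + utils::tail(pr, -1)) / 2)
  list(
    curve = data.frame(threshold = scores[ord][last],
                       recall = recall, precision = precision),
    auc = auc
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized distance between two linear subspaces
#'
#' For `p x k` matrices with orthonormal columns, returns
#' `||U U' - V V'||_F / sqrt(2k)`, which is 0 iff the spans coincide and 1
#' for orthogonal subspaces; equivalently `sqrt(mean(sin^2 theta_i))` over
#' the principal angles. Invariant to right-rotation of either basis.
#'
#' @param U,V `p x k` matrices with orthonormal columns.
#' @return scalar in `[0, 1]`.
#' @export
subspace_distance <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (!all(dim(U) == dim(V))) stop("U and V must have the same dimensions")
  k <- ncol(U)
  if (max(abs(crossprod(U) - diag(k))) > 1e-6 ||
      max(abs(crossprod(V) - diag(k))) > 1e-6) {
    stop("columns must be orthonormal")
  }
  norm(U %*% t(U) - V %*% t(V), type = "F") / sqrt(2 * k)
}

#' Mean-correlation bias diagnostic
#'
#' Spearman correlation between per-gene mean expression and per-gene
#' average estimated co-expression. Large positive values indicate that
#' highly expressed genes spuriously appear more co-expressed.
#'
#' @param mu per-gene expression levels.
#' @param rho symmetric co-expression matrix.
#' @return the scalar Spearman correlation.
#' @export
mean_correlation_bias <- function(mu, rho) {
  avg <- average_coexpression(rho)
  stats::cor(mu, avg, method = "spearman")
}
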