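#' Depth-normalize a count matrix
#'
#' The two standard single-cell normalizations: `"scaled"` values are
#' `scale_factor * x_ij / s_i` and `"lognorm"` values are
#' `log(scale_factor * x_ij / s_i + 1)` (natural log). These transforms do
#' not remove the confounding effect of depth variation on correlations —
#' they are provided as the comparison baselines whose artifacts the
#' model-based estimator avoids.
#'
#' @param cm a [count_matrix()].
#' @param scheme `"lognorm"` or `"scaled"`.
#' @param scale_factor multiplier applied before the transform (default 1e4).
#' @return an object of class `"normalized_matrix"`: list with `values`
#'   (cells x genes), `scheme`, `scale_factor`.
#' @export
normalize_counts <- function(cm, scheme = c("lognorm", "scaled"),
                             scale_factor = 1e4) {
  stopifnot(inherits(cm, "count_matrix"))
  scheme <- match.arg(scheme)
  if (any(cm$depths <= 0)) stop("depths must be positive")
  v <- scale_factor * cm$counts / cm$depths
  if (scheme == "lognorm") v <- log(v + 1)
  structure(list(values = v, scheme = scheme, scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Pairwise correlation of normalized expression with a normal-theory test
#'
#' Computes all pairwise Pearson or Spearman correlations of the normalized
#' values, the statistic `t = r * sqrt((n - 2) / (1 - r^2))`, and two-sided
#' p values evaluated under the standard normal distribution (the
#' conventional choice for these baselines in single-cell co-expression
#' comparisons; note it is not the exact t reference). Spearman uses average
#' ranks for ties. Genes with zero variance get `r = NaN`, `p = 1`; pairs
#' with `|r| = 1` sit at the pole of the statistic and report `p = 0` with
#' an infinite `t`.
#'
#' @param nm a [normalize_counts()] result (or any list with a numeric
#'   `values` matrix).
#' @param method `"pearson"` or `"spearman"`.
#' @return an object of class `"baseline_result"`: list with matrices `rho`,
#'   `tstat`, `pval`, `qval`, per-gene `flags`, and the `method` tag.
#' @export
correlation_test <- function(nm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- as.matrix(nm$values)
  n <- nrow(v)
  if (n < 3) stop("need at least 3 cells")
  p <- ncol(v)
  genes <- colnames(v)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  if (method == "spearman") {
    v <- apply(v, 2, rank)  # average ranks for ties
  }
  sds <- apply(v, 2, stats::sd)
  ok <- sds > 0
  flags <- stats::setNames(ifelse(ok, "OK", "ZERO_VARIANCE"), genes)
  r <- matrix(NaN, p, p, dimnames = list(genes, genes))
  if (any(ok)) {
    r[ok, ok] <- stats::cor(v[, ok, drop = FALSE])
  }
  diag(r)[ok] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  pval <- 2 * stats::pnorm(-abs(tstat))
  pval[is.infinite(tstat)] <- 0
  pval[is.na(r)] <- 1
  diag(pval) <- NA_real_
  qval <- matrix(1, p, p, dimnames = list(genes, genes))
  ut <- upper.tri(pval) & outer(ok, ok, "&")
  qval[ut] <- bh_adjust(pval[ut])
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(qval) <- NA_real_
  structure(list(rho = r, tstat = tstat, pval = pval, qval = qval,
                 flags = flags, method = method),
            class = "baseline_result")
}
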