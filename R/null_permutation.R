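#' Generate null count data by permutation and Poisson resampling
#'
#' Destroys all cross-gene dependence in a count matrix while preserving
#' per-gene expression profiles: normalized expressions `y_ij = x_ij / s_i`
#' are permuted independently within each gene across cells, then new counts
#' are drawn from `Poisson(t_i * y^p_ij)`, where `t_i` is the target
#' sequencing depth of cell `i`. With `depth_mode = "observed"` the observed
#' depths are kept (varying-depth null); `"constant-median"` sets every
#' `t_i` to the median observed depth (constant-depth null); `"custom"`
#' uses a supplied vector.
#'
#' Cells whose resampled row is entirely zero are dropped (with a message):
#' a real experiment would never report a cell with no molecules.
#'
#' Depths of the returned matrix are the targets `t_i` by default
#' (`depths_as = "target"`). A sequencing depth is a full-transcriptome
#' total; when the matrix at hand is a gene panel rather than a whole
#' transcriptome, its row sum carries a per-cell compositional factor (the
#' summed permuted profile of the panel) that is shared across genes and
#' would re-introduce spurious correlation into data constructed to have
#' none. `depths_as = "realized"` uses the row sums instead, appropriate
#' when the panel covers the full gene set; the targets are always kept in
#' `meta$target_depths`.
#'
#' @param cm a [count_matrix()].
#' @param depth_mode `"observed"`, `"constant-median"` or `"custom"`.
#' @param target_depths positive vector of length `n`, required for
#'   `"custom"`.
#' @param depths_as `"target"` (default) or `"realized"`; see Details.
#' @param seed optional integer seed; the whole null matrix is reproducible
#'   from one seed.
#' @return a [count_matrix()] of null counts.
#' @export
permute_null_counts <- function(cm,
                                depth_mode = c("observed", "constant-median",
                                               "custom"),
                                target_depths = NULL,
                                depths_as = c("target", "realized"),
                                seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  depth_mode <- match.arg(depth_mode)
  depths_as <- match.arg(depths_as)
  if (!is.null(seed)) set.seed(seed)
  X <- cm$counts
  s <- cm$depths
  n <- nrow(X)
  p <- ncol(X)
  t_i <- switch(depth_mode,
    "observed" = s,
    "constant-median" = rep(stats::median(s), n),
    "custom" = {
      if (is.null(target_depths) || length(target_depths) != n ||
          any(target_depths <= 0)) {
        stop("custom depth_mode needs a positive target_depths vector of length n")
      }
      target_depths
    }
  )
  Y <- X / s
  # permute each gene's normalized profile independently, in fixed gene order
  for (j in seq_len(p)) {
    Y[, j] <- Y[sample.int(n), j]
  }
  Xp <- matrix(stats::rpois(n * p, lambda = as.vector(t_i * Y)), n, p,
               dimnames = dimnames(X))
  keep <- rowSums(Xp) > 0
  if (!all(keep)) {
    message(sum(!keep), " cell(s) with zero resampled counts dropped")
    Xp <- Xp[keep, , drop = FALSE]
    t_i <- t_i[keep]
  }
  out <- count_matrix(Xp, depths = if (depths_as == "target") t_i else NULL)
  out$meta$target_depths <- t_i
  out$meta$depth_mode <- depth_mode
  out
}
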