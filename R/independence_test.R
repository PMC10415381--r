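#' Plug-in quantities for the pairwise independence test
#'
#' Bundles the moment estimates and data needed to evaluate the test
#' statistic for any gene pair.
#'
#' @param mu vector of relative expression estimates.
#' @param sigma_jj vector of latent variance estimates.
#' @param theta regularized over-dispersion scalar.
#' @param counts cells x genes count matrix.
#' @param depths positive depth vector.
#' @return an object of class `"test_inputs"`.
#' @export
test_inputs <- function(mu, sigma_jj, theta, counts, depths) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (length(mu) != p || length(sigma_jj) != p) {
    stop("mu / sigma_jj length must match the number of genes")
  }
  if (length(depths) != nrow(counts)) {
    stop("depths length must match the number of cells")
  }
  if (any(depths <= 0)) stop("depths must be positive")
  structure(list(mu = mu, sigma_jj = sigma_jj, theta = theta,
                 counts = counts, depths = depths),
            class = "test_inputs")
}

#' Independence test statistic for one gene pair
#'
#' Under the null hypothesis that the latent expressions of genes `j` and
#' `jp` are independent, the standardized weighted covariance estimate
#' \deqn{T = \frac{\sum_i s_i^2 e_{ij} e_{ij'} g_{ijj'}}
#'   {\sqrt{\sum_i s_i^4 (s_i \mu_j + s_i^2 \sigma_{jj})
#'   (s_i \mu_{j'} + s_i^2 \sigma_{j'j'}) g_{ijj'}^2}}}
#' is asymptotically standard normal, with residuals `e_ij = x_ij - s_i mu_j`
#' and pair weights `g_ijj' = w_ij w_ij'` built from the regularized
#' per-gene variances. With `regularized_var = TRUE` the variance factors in
#' the denominator are the same regularized variances `1 / w`, so the
#' denominator simplifies to `sqrt(sum_i s_i^4 g_ijj')`.
#'
#' @param j,jp gene indices.
#' @param ti a [test_inputs()] object.
#' @param regularized_var as in [estimate_network()].
#' @return the scalar statistic, or `NaN` when either gene has a
#'   non-positive variance term.
#' @export
test_statistic <- function(j, jp, ti, regularized_var = TRUE) {
  stopifnot(inherits(ti, "test_inputs"))
  s <- ti$depths
  s2 <- s^2
  mu_j <- ti$mu[j]; mu_jp <- ti$mu[jp]
  if (mu_j <= 0 || mu_jp <= 0) return(NaN)
  v_j <- s * mu_j + s2 * mu_j^2 * ti$theta
  v_jp <- s * mu_jp + s2 * mu_jp^2 * ti$theta
  g <- 1 / (v_j * v_jp)
  e_j <- ti$counts[, j] - s * mu_j
  e_jp <- ti$counts[, jp] - s * mu_jp
  num <- sum(s2 * e_j * e_jp * g)
  if (regularized_var) {
    den <- sum(s2^2 * g)
  } else {
    f_j <- s * mu_j + s2 * ti$sigma_jj[j]
    f_jp <- s * mu_jp + s2 * ti$sigma_jj[jp]
    if (any(f_j <= 0) || any(f_jp <= 0)) return(NaN)
    den <- sum(s2^2 * f_j * f_jp * g^2)
  }
  num / sqrt(den)
}

#' Two-sided normal p values for a matrix of test statistics
#'
#' @param T symmetric matrix of test statistics (diagonal ignored).
#' @return symmetric matrix of `2 * pnorm(-|T|)` with `NaN` diagonal;
#'   entries with undefined statistics get `p = 1`.
#' @export
p_values <- function(T) {
  T <- as.matrix(T)
  p <- 2 * stats::pnorm(-abs(T))
  p[is.na(T)] <- 1
  if (nrow(p) == ncol(p)) diag(p) <- NA_real_
  p
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up false discovery rate adjustment with monotonicity
#' enforcement, capped at 1.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return vector of adjusted q values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
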