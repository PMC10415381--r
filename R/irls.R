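#' Weighted least squares estimate of a gene's relative expression
#'
#' Under the measurement model `E(x_i) = s_i * mu`, the mean parameter is the
#' minimizer of `sum_i w_i (x_i - s_i mu)^2`, which has the closed form
#' `mu_hat = sum(w s x) / sum(w s^2)`.
#'
#' @param x UMI counts of one gene across cells.
#' @param s positive sequencing depths.
#' @param w positive weights.
#' @return the scalar weighted least squares estimate.
#' @export
wls_mean <- function(x, s, w) {
  .check_wls_args(x, s, w)
  sum(w * s * x) / sum(w * s^2)
}

#' Weighted least squares estimate of a gene's latent expression variance
#'
#' The squared residual `(x_i - s_i mu)^2` has expectation
#' `s_i mu + s_i^2 sigma_jj` under the model, so `sigma_jj` is estimated by
#' minimizing `sum_i h_i [(x_i - s_i mu)^2 - s_i mu - s_i^2 sigma]^2`, giving
#' `sigma_hat = sum(h s^2 ((x - s mu)^2 - s mu)) / sum(h s^4)`. The moment
#' estimate can be negative; callers must flag such genes.
#'
#' @param x,s as in [wls_mean()].
#' @param mu_hat estimated relative expression of the gene.
#' @param h positive weights.
#' @return the scalar variance estimate (possibly negative).
#' @export
wls_variance <- function(x, s, mu_hat, h) {
  .check_wls_args(x, s, h)
  r2 <- (x - s * mu_hat)^2 - s * mu_hat
  sum(h * s^2 * r2) / sum(h * s^4)
}

#' Weighted least squares estimate of a latent expression covariance
#'
#' The residual cross-product of two genes has expectation
#' `s_i^2 sigma_jj'`; minimizing the weighted squared deviation yields
#' `sigma_hat = sum(g s^2 e_j e_j') / sum(g s^4)` with
#' `e_j = x_j - s mu_j`.
#'
#' @param x_j,x_jp counts of the two genes.
#' @param s depths.
#' @param mu_j,mu_jp estimated relative expressions.
#' @param g positive weights.
#' @return the scalar covariance estimate.
#' @export
wls_covariance <- function(x_j, x_jp, s, mu_j, mu_jp, g) {
  .check_wls_args(x_j, s, g)
  if (length(x_jp) != length(x_j)) stop("gene count vectors differ in length")
  e_j <- x_j - s * mu_j
  e_jp <- x_jp - s * mu_jp
  sum(g * s^2 * e_j * e_jp) / sum(g * s^4)
}

.check_wls_args <- function(x, s, w) {
  if (length(x) == 0L) stop("zero-length input")
  if (length(s) != length(x) || length(w) != length(x)) {
    stop("inputs differ in length")
  }
  if (any(s <= 0)) stop("depths must be positive")
  if (any(w <= 0)) stop("weights must be positive")
  invisible(TRUE)
}

#' Cross-gene regularized over-dispersion
#'
#' Per-gene over-dispersion `theta_j = sigma_jj / mu_j^2` is noisy; the IRLS
#' weights instead use a single value regularized across genes as the median
#' of `sigma_jj / mu_j^2`, excluding genes with `mu_j = 0`.
#'
#' @param mu vector of estimated relative expressions.
#' @param sigma_jj vector of estimated latent variances.
#' @return the scalar median over-dispersion.
#' @export
regularize_theta <- function(mu, sigma_jj) {
  if (length(mu) != length(sigma_jj)) stop("inputs differ in length")
  ok <- is.finite(mu) & mu > 0 & is.finite(sigma_jj)
  if (!any(ok)) stop("no gene with positive mean available for regularization")
  stats::median(sigma_jj[ok] / mu[ok]^2)
}

# One weighted update sweep over all genes, vectorized.
# X: n x p, s: n, W: n x p weights for the mean, H: n x p for the variance.
.wls_sweep <- function(X, s, W, H) {
  s2 <- s^2
  mu <- colSums(W * (s * X)) / colSums(W * s2)
  E <- X - outer(s, mu)
  A <- E^2 - outer(s, mu)
  sigma <- colSums(H * (s2 * A)) / colSums(H * s2^2)
  list(mu = mu, sigma = sigma)
}

#' Iteratively re-weighted least squares moment estimation
#'
#' Estimates per-gene relative expression `mu_j` and latent variance
#' `sigma_jj` under the Poisson measurement model. The procedure initializes
#' with ordinary (unit-weight) least squares, then iterates: regularize the
#' over-dispersion `theta` as the cross-gene median of `sigma_jj / mu_j^2`,
#' set weights `w_ij = 1 / (s_i mu_j + s_i^2 mu_j^2 theta)` (the inverse
#' variance of the count residual with regularized variance), update `mu_j`
#' with weights `w`, update `sigma_jj` with weights `h = w^2`, and stop when
#' the maximum absolute change of `log sigma_jj` across genes falls below
#' `tol`. Genes with all-zero counts are flagged `ZERO_GENE` and excluded;
#' genes whose variance estimate is non-positive are excluded from the
#' convergence criterion for that iteration.
#'
#' @param cm a [count_matrix()].
#' @param tol convergence threshold on the max absolute change in
#'   `log sigma_jj` (default 0.05).
#' @param max_iter maximum number of re-weighted iterations (default 10).
#' @return an object of class `"moment_estimates"`: list with `mu`,
#'   `sigma_jj` (named by gene), `theta`, `iterations`, `converged`,
#'   `delta_trace`, and per-gene `flags` (`"OK"`, `"ZERO_GENE"` or
#'   `"NEGATIVE_VARIANCE"`).
#' @export
run_irls <- function(cm, tol = 0.05, max_iter = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (tol <= 0) stop("tol must be positive")
  if (max_iter < 1) stop("max_iter must be at least 1")
  X_all <- cm$counts
  s <- cm$depths
  p_all <- ncol(X_all)
  genes <- colnames(X_all)
  flags <- stats::setNames(rep("OK", p_all), genes)
  zero <- zero_genes(cm)
  flags[zero] <- "ZERO_GENE"
  if (all(zero)) stop("all genes have zero counts; nothing to estimate")
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero counts excluded from estimation")
  }
  X <- X_all[, !zero, drop = FALSE]
  s2 <- s^2

  # OLS initialization (unit weights)
  ones <- matrix(1, nrow(X), ncol(X))
  fit <- .wls_sweep(X, s, ones, ones)
  mu <- fit$mu
  sigma <- fit$sigma

  delta_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  theta <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- regularize_theta(mu, sigma)
    if (!is.finite(theta) || theta < 0) theta <- 0  # fall back to Poisson noise
    denom <- outer(s, mu) + outer(s2, mu^2 * theta)
    W <- 1 / denom
    mu_new <- colSums(W * (s * X)) / colSums(W * s2)
    denom2 <- outer(s, mu_new) + outer(s2, mu_new^2 * theta)
    H <- 1 / denom2^2
    E <- X - outer(s, mu_new)
    A <- E^2 - outer(s, mu_new)
    sigma_new <- colSums(H * (s2 * A)) / colSums(H * s2^2)

    ok <- sigma > 0 & sigma_new > 0
    delta <- if (any(ok)) {
      max(abs(log(sigma_new[ok]) - log(sigma[ok])))
    } else 0
    delta_trace <- c(delta_trace, delta)
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IRLS did not reach tolerance ", tol, " within ", max_iter,
            " iterations (last delta = ", signif(delta_trace[iter], 3), ")")
  }

  mu_full <- stats::setNames(rep(0, p_all), genes)
  sigma_full <- stats::setNames(rep(NA_real_, p_all), genes)
  mu_full[!zero] <- mu
  sigma_full[!zero] <- sigma
  flags[!zero][sigma <= 0] <- "NEGATIVE_VARIANCE"

  structure(
    list(mu = mu_full, sigma_jj = sigma_full, theta = theta,
         iterations = iter, converged = converged,
         delta_trace = delta_trace, flags = flags),
    class = "moment_estimates"
  )
}

#' @export
print.moment_estimates <- function(x, ...) {
  cat(sprintf(
    "moment_estimates: %d genes, theta = %.4g, %d iteration(s), %s\n",
    length(x$mu), x$theta, x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  nf <- sum(x$flags != "OK")
  if (nf > 0) cat(sprintf("  %d flagged gene(s)\n", nf))
  invisible(x)
}

#' Estimate a cell-type-specific co-expression network
#'
#' Runs [run_irls()] to obtain moment estimates, then estimates all pairwise
#' latent covariances by weighted least squares with pair weights
#' `g_ijj' = w_ij * w_ij'` (product of the per-gene regularized inverse
#' variances), converts to correlations
#' `rho_jj' = sigma_jj' / sqrt(sigma_jj sigma_j'j')`, clips to `[-1, 1]`,
#' and computes the pairwise independence test statistic, p values and
#' Benjamini-Hochberg q values. Genes flagged by the IRLS step
#' (all-zero counts or non-positive variance estimate) are zeroed out of the
#' network and report `p = q = 1`.
#'
#' @param cm a [count_matrix()].
#' @param tol,max_iter passed to [run_irls()].
#' @param regularized_var logical; if `TRUE` (default) the variance factors
#'   in the test statistic's denominator use the regularized variances
#'   `s mu + s^2 mu^2 theta` (the same quantities as the weights), otherwise
#'   the raw IRLS variance estimates `sigma_jj` are plugged in.
#' @param tests logical; compute test statistics / p values (default `TRUE`).
#'   Skipping them speeds up permutation loops that only need `rho`.
#' @return an object of class `"coexp_result"`: list with `p x p` matrices
#'   `rho`, `sigma`, `tstat`, `pval`, `qval`, per-gene `flags`, the
#'   `moment_estimates` as `est`, and `n_clipped`, the number of off-diagonal
#'   entries clipped into `[-1, 1]`.
#' @export
estimate_network <- function(cm, tol = 0.05, max_iter = 10,
                             regularized_var = TRUE, tests = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  est <- run_irls(cm, tol = tol, max_iter = max_iter)
  X <- cm$counts
  s <- cm$depths
  s2 <- s^2
  p <- ncol(X)
  genes <- colnames(X)
  ok <- est$flags == "OK"

  mu <- est$mu
  sigma_jj <- est$sigma_jj
  theta <- est$theta

  # weighted cross-products over all pairs at once:
  #   sigma_jj' = sum_i s^2 e_j e_j' w_j w_j' / sum_i s^4 w_j w_j'
  # with w the per-gene regularized inverse variances.
  W <- matrix(0, nrow(X), p)
  W[, ok] <- 1 / (outer(s, mu[ok]) + outer(s2, mu[ok]^2 * theta))
  E <- X - outer(s, mu)
  B <- E * W * s          # rows scaled by s_i
  C <- W * s2
  num <- crossprod(B)     # sum_i s^2 e_j e_j' w_j w_j'
  den <- crossprod(C)     # sum_i s^4 w_j w_j'

  sigma <- matrix(0, p, p, dimnames = list(genes, genes))
  sigma[ok, ok] <- num[ok, ok] / den[ok, ok]
  diag(sigma)[ok] <- sigma_jj[ok]

  sd_ok <- sqrt(pmax(sigma_jj, 0))
  rho <- matrix(0, p, p, dimnames = list(genes, genes))
  rho[ok, ok] <- sigma[ok, ok] / outer(sd_ok[ok], sd_ok[ok])
  diag(rho)[ok] <- 1
  over <- abs(rho) > 1
  n_clipped <- sum(over[upper.tri(over)])
  rho[over] <- sign(rho[over])

  tstat <- matrix(NA_real_, p, p, dimnames = list(genes, genes))
  pval <- matrix(1, p, p, dimnames = list(genes, genes))
  qval <- matrix(1, p, p, dimnames = list(genes, genes))
  if (tests) {
    if (regularized_var) {
      den_t <- den
    } else {
      f <- matrix(0, nrow(X), p)
      f[, ok] <- outer(s, mu[ok]) + outer(s2, sigma_jj[ok])
      D <- f * W^2 * s2
      den_t <- crossprod(D)  # sum_i s^4 f_j f_j' w_j^2 w_j'^2
    }
    tmat <- num / sqrt(den_t)
    tstat[ok, ok] <- tmat[ok, ok]
    diag(tstat) <- NA_real_
    pv <- p_values(tstat)
    pval[ok, ok] <- pv[ok, ok]
    diag(pval) <- NA_real_
    pval[!ok, ] <- 1
    pval[, !ok] <- 1
    # BH across tested (unflagged) off-diagonal pairs only
    ut <- upper.tri(pval) & outer(ok, ok, "&")
    qv <- bh_adjust(pval[ut])
    qval[ut] <- qv
    qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
    diag(qval) <- NA_real_
    qval[!ok, ] <- 1
    qval[, !ok] <- 1
  }

  structure(
    list(rho = rho, sigma = sigma, tstat = tstat, pval = pval, qval = qval,
         flags = est$flags, est = est, n_clipped = n_clipped),
    class = "coexp_result"
  )
}

#' @export
print.coexp_result <- function(x, ...) {
  p <- ncol(x$rho)
  cat(sprintf("coexp_result: %d genes (%d pairs)\n", p, p * (p - 1) / 2))
  cat(sprintf("  theta = %.4g; %d flagged gene(s); %d clipped correlation(s)\n",
              x$est$theta, sum(x$flags != "OK"), x$n_clipped))
  if (!all(is.na(x$qval))) {
    ut <- upper.tri(x$qval)
    cat(sprintf("  %d pair(s) with q < 0.05\n",
                sum(x$qval[ut] < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
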