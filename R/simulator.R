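#' Specification of a Gamma-Poisson copula count simulation
#'
#' Latent expression for gene `j` is marginally `Gamma(alpha_j, beta_j)` with
#' `mu_j = alpha_j beta_j` and `sigma_jj = alpha_j beta_j^2`; genes are
#' coupled through a Gaussian copula with correlation matrix `R`. Conditional
#' on the latent level `z_ij` and the cell's depth `s_i`, the observed UMI
#' count is `Poisson(s_i z_ij)`. Marginally each gene is therefore negative
#' binomial.
#'
#' @param mu positive vector of marginal latent means (length `p`).
#' @param sigma_jj positive vector of marginal latent variances.
#' @param R `p x p` copula correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite; see `repair_R`).
#' @param depths either a positive numeric vector of length `n_cells` or a
#'   depth model list as accepted by [sample_depths()] (e.g.
#'   `list(model = "lognormal", median = 5000, sdlog = 0.5)`).
#' @param n_cells number of cells to simulate.
#' @param seed integer seed; the simulation is deterministic given the spec.
#' @param repair_R if `TRUE`, a non-PSD `R` is repaired by clipping negative
#'   eigenvalues at zero and rescaling to unit diagonal; never done silently.
#' @return an object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(mu, sigma_jj, R, depths, n_cells, seed = 1L,
                            repair_R = FALSE) {
  p <- length(mu)
  if (length(sigma_jj) != p) stop("mu and sigma_jj differ in length")
  if (any(mu <= 0) || any(sigma_jj <= 0)) {
    stop("marginal means and variances must be positive")
  }
  R <- as.matrix(R)
  if (nrow(R) != p || ncol(R) != p) stop("R must be p x p")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (!repair_R) {
      stop("R is not positive semi-definite; set repair_R = TRUE to repair")
    }
    R <- nearest_pd(R)
    message("copula correlation matrix repaired to nearest PSD")
  }
  if (is.numeric(depths)) {
    if (length(depths) != n_cells) stop("depth vector length != n_cells")
    if (any(depths <= 0)) stop("depths must be positive")
  } else if (!is.list(depths)) {
    stop("depths must be a numeric vector or a depth model list")
  }
  structure(list(mu = mu, sigma_jj = sigma_jj, R = R, depths = depths,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping at zero followed by rescaling to unit diagonal.
#'
#' @param R symmetric matrix.
#' @return a PSD matrix with unit diagonal.
#' @export
nearest_pd <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(M))
  d[d == 0] <- 1
  M <- M / outer(d, d)
  (M + t(M)) / 2
}

#' Sample per-cell sequencing depths
#'
#' The `"constant"` model returns the same depth for every cell; the
#' `"lognormal"` model draws integer depths whose distribution is long-tailed
#' with the requested median (`exp(meanlog)` of the underlying log-normal),
#' emulating the heavy right tail of droplet-based experiments.
#'
#' @param n number of cells.
#' @param model list with `model` (`"constant"` or `"lognormal"`) and either
#'   `value` (constant) or `median` and optional `sdlog` (default 0.5).
#' @param seed optional integer seed.
#' @return integer-valued depth vector of length `n` (minimum 1).
#' @export
sample_depths <- function(n, model, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  kind <- model$model
  if (identical(kind, "constant")) {
    v <- model$value
    if (is.null(v) || v <= 0) stop("constant depth model needs a positive value")
    rep(as.numeric(round(v)), n)
  } else if (identical(kind, "lognormal")) {
    med <- model$median
    sdlog <- if (is.null(model$sdlog)) 0.5 else model$sdlog
    if (is.null(med) || med <= 0 || sdlog <= 0) {
      stop("lognormal depth model needs positive median and sdlog")
    }
    pmax(1, round(stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)))
  } else {
    stop("unknown depth model: ", format(kind))
  }
}

#' Simulate UMI counts from the latent-expression measurement model
#'
#' Draws latent normals `v ~ N(0, R)`, maps each gene through the standard
#' normal CDF and the inverse Gamma CDF to obtain latent expressions `z`
#' with the requested Gamma marginals and copula dependence, then draws
#' counts `x_ij ~ Poisson(s_i z_ij)` independently.
#'
#' @param spec a [simulation_spec()].
#' @param return_latent if `TRUE`, attach the latent `z` matrix to the result
#'   metadata.
#' @return a [count_matrix()]; `meta$depths_drawn` records the depths used,
#'   and `meta$z` the latent matrix when requested. Depths of the returned
#'   object are the model depths `s_i` (the quantity conditioned on), not
#'   realized row sums.
#' @export
simulate_counts <- function(spec, return_latent = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  p <- length(spec$mu)
  s <- if (is.numeric(spec$depths)) spec$depths else
    sample_depths(n, spec$depths)
  alpha <- spec$mu^2 / spec$sigma_jj   # Gamma shape
  beta <- spec$sigma_jj / spec$mu      # Gamma scale
  L <- chol(spec$R + diag(1e-10, p))
  V <- matrix(stats::rnorm(n * p), n, p) %*% L
  U <- stats::pnorm(V)
  Z <- matrix(stats::qgamma(U, shape = rep(alpha, each = n),
                            scale = rep(beta, each = n)), n, p)
  X <- matrix(stats::rpois(n * p, lambda = as.vector(s * Z)), n, p)
  cm <- count_matrix(X, depths = s)
  cm$meta$depths_drawn <- s
  if (return_latent) cm$meta$z <- Z
  cm
}

#' Block-structured copula correlation matrix with known cluster labels
#'
#' Builds a `p x p` correlation matrix with `n_blocks` equally sized gene
#' clusters: entries `within` inside a cluster, `between` across clusters,
#' unit diagonal. Used to plant recoverable co-expression modules.
#'
#' @param p number of genes (need not be a multiple of `n_blocks`; sizes
#'   differ by at most one).
#' @param n_blocks number of clusters.
#' @param within within-cluster correlation.
#' @param between between-cluster correlation.
#' @return correlation matrix with attribute `"labels"`, the true cluster
#'   label of each gene.
#' @export
block_correlation <- function(p, n_blocks, within, between = 0) {
  if (p < 1 || n_blocks < 1 || n_blocks > p) stop("invalid p / n_blocks")
  labels <- sort(rep_len(seq_len(n_blocks), p))
  R <- matrix(between, p, p)
  for (b in seq_len(n_blocks)) {
    idx <- which(labels == b)
    R[idx, idx] <- within
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("within/between values do not yield a positive semi-definite matrix")
  }
  attr(R, "labels") <- labels
  R
}

#' Default marginal parameters for simulated gene panels
#'
#' Relative expression means drawn log-uniformly over four orders of
#' magnitude (1e-5 to 1e-1 of a cell's molecules by default), mimicking the
#' wide dynamic range of highly expressed gene panels, with a common
#' over-dispersion so that `sigma_jj = theta * mu_j^2`.
#'
#' @param p number of genes.
#' @param mu_range length-2 positive range of latent means.
#' @param theta common over-dispersion (default 0.5).
#' @param seed optional integer seed.
#' @return list with `mu` and `sigma_jj` vectors.
#' @export
default_marginals <- function(p, mu_range = c(1e-5, 1e-1), theta = 0.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(mu_range <= 0) || theta <= 0) stop("parameters must be positive")
  mu <- exp(stats::runif(p, log(mu_range[1]), log(mu_range[2])))
  list(mu = mu, sigma_jj = theta * mu^2)
}
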