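# Shared fixtures and independent oracles used across test files.

# small random count matrix: Gamma-Poisson counts (over-dispersion 0.5)
# around depth-scaled means
random_cm <- function(n = 30, p = 5, seed = 1, depth_median = 200) {
  set.seed(seed)
  s <- pmax(1, round(rlnorm(n, log(depth_median), 0.4)))
  mu <- runif(p, 1e-3, 5e-2)
  Z <- matrix(rgamma(n * p, shape = 2, scale = rep(mu / 2, each = n)), n, p)
  X <- matrix(rpois(n * p, as.vector(s * Z)), n, p)
  X[1, ] <- X[1, ] + 1  # guard against all-zero genes in tiny fixtures
  count_matrix(X, depths = s)
}

# Gamma-Poisson copula matrix at moderate scale
sim_cm <- function(p = 50, n = 500, seed = 1, R = diag(p), theta = 0.5,
                   mu_range = c(1e-5, 1e-1), depth_median = 5000) {
  marg <- default_marginals(p, mu_range = mu_range, theta = theta,
                            seed = seed)
  spec <- simulation_spec(marg$mu, marg$sigma_jj, R,
                          depths = list(model = "lognormal",
                                        median = depth_median),
                          n_cells = n, seed = seed + 7919L)
  cm <- simulate_counts(spec)
  cm$meta$marg <- marg
  cm
}

# brute-force 1-D minimizer of a weighted least squares objective
minimize_1d <- function(obj, lower, upper) {
  stats::optimize(obj, c(lower, upper), tol = 1e-12)$minimum
}

# step-by-step loop-based execution of the moment estimation algorithm,
# written with explicit per-cell sums, independent of the vectorized path
oracle_irls <- function(X, s, tol = 0.05, max_iter = 10) {
  n <- nrow(X); p <- ncol(X)
  f_mu <- function(x, w) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      num <- num + w[i] * s[i] * x[i]
      den <- den + w[i] * s[i]^2
    }
    num / den
  }
  f_sig <- function(x, mu, h) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      r2 <- (x[i] - s[i] * mu)^2 - s[i] * mu
      num <- num + h[i] * s[i]^2 * r2
      den <- den + h[i] * s[i]^4
    }
    num / den
  }
  mu <- numeric(p); sig <- numeric(p)
  for (j in seq_len(p)) {
    mu[j] <- f_mu(X[, j], rep(1, n))
    sig[j] <- f_sig(X[, j], mu[j], rep(1, n))
  }
  trace <- list(list(mu = mu, sigma = sig))
  delta <- 1
  t <- 0
  while (delta >= tol && t < max_iter) {
    t <- t + 1
    theta <- median(sig / mu^2)
    mu_new <- numeric(p); sig_new <- numeric(p)
    for (j in seq_len(p)) {
      w <- 1 / (s * mu[j] + s^2 * mu[j]^2 * theta)
      mu_new[j] <- f_mu(X[, j], w)
      h <- 1 / (s * mu_new[j] + s^2 * mu_new[j]^2 * theta)^2
      sig_new[j] <- f_sig(X[, j], mu_new[j], h)
    }
    ok <- sig > 0 & sig_new > 0
    delta <- if (any(ok)) max(abs(log(sig_new[ok]) - log(sig[ok]))) else 0
    mu <- mu_new; sig <- sig_new
    trace[[t + 1]] <- list(mu = mu, sigma = sig, theta = theta,
                           delta = delta)
  }
  list(mu = mu, sigma = sig, theta = theta, iterations = t, trace = trace)
}

# term-by-term evaluation of the pairwise test statistic
oracle_tstat <- function(x_j, x_jp, s, mu_j, mu_jp, sig_j, sig_jp, theta,
                         regularized = TRUE) {
  num <- 0; den <- 0
  for (i in seq_along(s)) {
    g <- 1 / ((s[i] * mu_j + s[i]^2 * mu_j^2 * theta) *
              (s[i] * mu_jp + s[i]^2 * mu_jp^2 * theta))
    e1 <- x_j[i] - s[i] * mu_j
    e2 <- x_jp[i] - s[i] * mu_jp
    num <- num + s[i]^2 * e1 * e2 * g
    if (regularized) {
      v1 <- s[i] * mu_j + s[i]^2 * mu_j^2 * theta
      v2 <- s[i] * mu_jp + s[i]^2 * mu_jp^2 * theta
    } else {
      v1 <- s[i] * mu_j + s[i]^2 * sig_j
      v2 <- s[i] * mu_jp + s[i]^2 * sig_jp
    }
    den <- den + s[i]^4 * v1 * v2 * g^2
  }
  num / sqrt(den)
}
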