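test_that("closed-form WLS updates minimize their stated objectives", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    s <- runif(n, 50, 500)
    w <- runif(n, 0.1, 2)
    x <- rpois(n, s * 0.02)
    mu_hat <- wls_mean(x, s, w)
    obj_mu <- function(m) sum(w * (x - s * m)^2)
    expect_lt(abs(mu_hat - minimize_1d(obj_mu, -1, 1)), 1e-8)

    h <- runif(n, 0.1, 2)
    sig_hat <- wls_variance(x, s, mu_hat, h)
    obj_sig <- function(v) {
      sum(h * ((x - s * mu_hat)^2 - s * mu_hat - s^2 * v)^2)
    }
    expect_lt(abs(sig_hat - minimize_1d(obj_sig, -1, 1)), 1e-8)

    x2 <- rpois(n, s * 0.01)
    mu2 <- wls_mean(x2, s, w)
    g <- runif(n, 0.1, 2)
    cov_hat <- wls_covariance(x, x2, s, mu_hat, mu2, g)
    obj_cov <- function(v) {
      sum(g * ((x - s * mu_hat) * (x2 - s * mu2) - s^2 * v)^2)
    }
    expect_lt(abs(cov_hat - minimize_1d(obj_cov, -1, 1)), 1e-8)
  }
})

test_that("WLS estimators reproduce forced arithmetic cases", {
  # exact proportionality x = 2 s
  s <- c(3, 7, 11)
  expect_equal(wls_mean(2 * s, s, c(1, 5, 2)), 2)
  expect_equal(wls_mean(rep(0, 3), s, rep(1, 3)), 0)
  # variance: s=(1,1), mu=1, x=(3,3) -> ((3-1)^2 - 1) = 3
  expect_equal(wls_variance(c(3, 3), c(1, 1), 1, c(1, 1)), 3)
  # negative moment estimate is returned as-is
  expect_equal(wls_variance(c(1, 1), c(1, 1), 1, c(1, 1)), -1)
  # covariance: residuals (1,-1) for both genes -> mean cross-product 1
  expect_equal(wls_covariance(c(2, 0), c(2, 0), c(1, 1), 1, 1, c(1, 1)), 1)
  # zero residual in one gene kills the covariance
  s <- c(2, 5)
  expect_equal(wls_covariance(c(4, 1), 3 * s, s, 0.9, 3, c(1, 1)), 0)
  expect_error(wls_mean(numeric(0), numeric(0), numeric(0)), "zero-length")
})

test_that("theta regularization is the cross-gene median of sigma/mu^2", {
  expect_equal(regularize_theta(c(1, 2, 3), c(1, 4, 9)), 1)
  expect_equal(regularize_theta(c(1, 2, 1), c(1, 8, 3)), 2)
  # genes with mu = 0 are excluded
  expect_equal(regularize_theta(c(0, 1, 2, 1), c(99, 1, 8, 3)), 2)
  expect_error(regularize_theta(c(0, 0), c(1, 1)), "no gene")
  # brute-force median on many genes
  set.seed(3)
  mu <- runif(101, 0.1, 1)
  sig <- runif(101, 0, 1)
  ratios <- sort(sig / mu^2)
  expect_equal(regularize_theta(mu, sig), ratios[51])
})

test_that("run_irls matches a step-by-step loop-based execution", {
  cm <- random_cm(n = 50, p = 3, seed = 17)
  est <- run_irls(cm)
  orc <- oracle_irls(cm$counts, cm$depths)
  expect_equal(unname(est$mu), orc$mu, tolerance = 1e-12)
  expect_equal(unname(est$sigma_jj), orc$sigma, tolerance = 1e-12)
  expect_equal(est$theta, orc$theta, tolerance = 1e-12)
  expect_equal(est$iterations, orc$iterations)
  expect_equal(est$delta_trace[length(est$delta_trace)],
               orc$trace[[length(orc$trace)]]$delta, tolerance = 1e-12)
})

test_that("a gene with x = s exactly is a fixed point at mu = 1", {
  set.seed(2)
  s <- pmax(1, round(rlnorm(40, log(100), 0.3)))
  X <- cbind(s, rpois(40, s * 0.05))
  cm <- count_matrix(X, depths = s)
  est <- suppressWarnings(run_irls(cm))
  expect_equal(unname(est$mu[1]), 1, tolerance = 1e-12)
})

test_that("with constant depths and unit weights mu equals mean(x)/s", {
  set.seed(4)
  x <- rpois(25, 3)
  s <- rep(10, 25)
  expect_equal(wls_mean(x, s, rep(1, 25)), mean(x / 10))
})

test_that("IRLS converges quickly on model-generated data", {
  cm <- sim_cm(p = 100, n = 1000, seed = 8)
  est <- run_irls(cm)
  expect_true(est$converged)
  expect_lte(est$iterations, 5)
  expect_equal(length(est$delta_trace), est$iterations)
  expect_lt(est$delta_trace[est$iterations], 0.05)
})

test_that("zero-count genes are flagged and excluded, all-zero input errors", {
  cm <- random_cm(n = 20, p = 4, seed = 6)
  cm$counts[, 2] <- 0
  expect_warning(est <- run_irls(cm), "all-zero")
  expect_equal(unname(est$flags[2]), "ZERO_GENE")
  expect_equal(unname(est$mu[2]), 0)
  z <- count_matrix(matrix(0, 3, 2), depths = c(5, 5, 5))
  expect_error(suppressWarnings(run_irls(z)), "nothing to estimate")
})

test_that("network estimates are symmetric with unit diagonal and clipping", {
  cm <- sim_cm(p = 30, n = 400, seed = 12,
               R = block_correlation(30, 3, within = 0.5))
  res <- estimate_network(cm)
  ok <- res$flags == "OK"
  expect_equal(res$rho, t(res$rho))
  expect_equal(res$sigma, t(res$sigma))
  expect_true(all(abs(res$rho) <= 1))
  expect_true(all(diag(res$rho)[ok] == 1))
  expect_true(all(res$pval[upper.tri(res$pval)] >= 0 &
                  res$pval[upper.tri(res$pval)] <= 1))
  # flagged rows are zeroed with p = q = 1
  if (any(!ok)) {
    expect_true(all(res$rho[!ok, ] == 0))
    expect_true(all(res$pval[!ok, ] == 1))
    expect_true(all(res$qval[!ok, ] == 1))
  }
})

test_that("pairwise covariance matches the per-pair WLS loop", {
  cm <- random_cm(n = 40, p = 5, seed = 23)
  res <- estimate_network(cm, tests = FALSE)
  est <- res$est
  s <- cm$depths
  ok <- which(res$flags == "OK")
  expect_gte(length(ok), 2)
  for (j in ok) {
    for (jp in ok[ok > j]) {
      w_j <- 1 / (s * est$mu[j] + s^2 * est$mu[j]^2 * est$theta)
      w_jp <- 1 / (s * est$mu[jp] + s^2 * est$mu[jp]^2 * est$theta)
      sig <- wls_covariance(cm$counts[, j], cm$counts[, jp], s,
                            est$mu[j], est$mu[jp], w_j * w_jp)
      expect_equal(res$sigma[j, jp], unname(sig), tolerance = 1e-12)
    }
  }
})

test_that("co-expression estimates are invariant to cell relabeling", {
  cm <- sim_cm(p = 20, n = 300, seed = 31)
  res1 <- estimate_network(cm, tests = FALSE)
  set.seed(99)
  perm <- sample.int(nrow(cm$counts))
  cm2 <- subset_cells(cm, perm)
  res2 <- estimate_network(cm2, tests = FALSE)
  expect_equal(res1$rho, res2$rho, tolerance = 1e-10)
})

test_that("estimation error of mu and rho decreases with sample size", {
  R <- block_correlation(20, 10, within = 0.5)
  err <- sapply(c(1000, 4000), function(n) {
    cm <- sim_cm(p = 20, n = n, seed = 55, R = R,
                 mu_range = c(1e-4, 1e-2))
    truth <- cm$meta$marg
    res <- estimate_network(cm, tests = FALSE)
    lab <- attr(R, "labels")
    within <- outer(lab, lab, "==") & upper.tri(R)
    c(mu = mean(abs(res$est$mu - truth$mu) / truth$mu),
      rho = mean(abs(res$rho[within] - 0.5)))
  })
  expect_lt(err["mu", 2], err["mu", 1])
  expect_lt(err["rho", 2], err["rho", 1])
})
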