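test_that("attenuation factor evaluates the closed form and its limits", {
  # s = 5000, CV = 1, mu = 0.01 -> sqrt(50/51)
  expect_equal(attenuation_factor(5000, 0.01, 1), sqrt(50 / 51))
  expect_equal(attenuation_factor(5000, 0.01, 1), 0.99015, tolerance = 1e-4)
  # vanishing expression kills the factor; high expression saturates it
  expect_lt(attenuation_factor(5000, 1e-9, 1), 1e-2)
  expect_gt(attenuation_factor(5000, 100, 1), 0.999999)
  expect_error(attenuation_factor(0, 1, 1), "positive")
  expect_error(attenuation_factor(1, -1, 1), "positive")
})

test_that("attenuation factor is strictly increasing in each argument", {
  mu_grid <- 10^seq(-6, 0, by = 0.5)
  a_mu <- attenuation_factor(5000, mu_grid, 1)
  expect_true(all(diff(a_mu) > 0))
  s_grid <- 10^seq(2, 5, by = 0.5)
  expect_true(all(diff(attenuation_factor(s_grid, 0.001, 1)) > 0))
  cv_grid <- seq(0.2, 3, by = 0.2)
  expect_true(all(diff(attenuation_factor(5000, 0.001, cv_grid)) > 0))
})

test_that("average co-expression matches a loop-based mean", {
  expect_equal(unname(average_coexpression(diag(4))), rep(0, 4))
  C <- matrix(0.3, 5, 5); diag(C) <- 1
  expect_equal(unname(average_coexpression(C)), rep(0.3, 5))
  set.seed(5)
  M <- matrix(rnorm(36), 6, 6); M <- (M + t(M)) / 2
  loop <- sapply(1:6, function(j) mean(M[j, -j]))
  expect_equal(unname(average_coexpression(M)), loop)
  expect_error(average_coexpression(matrix(1, 1, 1)), "two genes")
})

test_that("precision-recall handles perfect, random and toy cases", {
  # perfect separation by p value
  pr <- precision_recall(c(0.001, 0.002, 0.8, 0.9),
                         c(TRUE, TRUE, FALSE, FALSE), "pvalue_asc")
  expect_equal(pr$auc, 1)
  # toy case against an exhaustive sweep
  scores <- c(0.2, 0.9, 0.4, 0.1, 0.7, 0.3, 0.8, 0.5, 0.6, 0.05)
  truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
             FALSE, TRUE)
  pr <- precision_recall(scores, truth, "pvalue_asc")
  P <- sum(truth)
  brute <- t(sapply(sort(scores), function(th) {
    sel <- scores <= th
    c(recall = sum(truth & sel) / P, precision = sum(truth & sel) / sum(sel))
  }))
  expect_equal(pr$curve$recall, unname(brute[, "recall"]))
  expect_equal(pr$curve$precision, unname(brute[, "precision"]))
  # random scores on balanced truth: area near prevalence
  set.seed(9)
  sc <- runif(4000); tr <- rep(c(TRUE, FALSE), 2000)
  expect_equal(precision_recall(sc, tr, "pvalue_asc")$auc, 0.5,
               tolerance = 0.05)
  expect_error(precision_recall(1:3, rep(FALSE, 3)), "no positive")
})

test_that("precision-recall area is invariant to monotone score rescaling", {
  set.seed(13)
  sc <- runif(200); tr <- runif(200) < 0.3
  a1 <- precision_recall(sc, tr, "pvalue_asc")$auc
  a2 <- precision_recall(qnorm(sc), tr, "pvalue_asc")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # abs_desc ordering ranks by |score| descending
  a3 <- precision_recall(-log(sc), tr, "abs_desc")$auc
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("adjusted Rand index matches its pair-counting definition", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # one cluster against anything is chance level
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  # random labelings average near zero
  set.seed(21)
  aris <- replicate(50, {
    adjusted_rand_index(sample(1:4, 200, TRUE), sample(1:4, 200, TRUE))
  })
  expect_lt(abs(mean(aris)), 0.02)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:3, 50, TRUE)
    b <- sample(1:4, 50, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("subspace distance follows the principal-angle formula", {
  set.seed(31)
  p <- 12; k <- 4
  U <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  expect_equal(subspace_distance(U, U), 0)
  # orthogonal complement at k = p/2 is maximally distant
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(subspace_distance(Q[, 1:3], Q[, 4:6]), 1)
  # random pairs: sqrt(sum(sin^2 theta_i) / k) via principal angles
  V <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  sv <- svd(crossprod(U, V))$d
  sv <- pmin(pmax(sv, -1), 1)
  pa <- sqrt(sum(1 - sv^2) / k)
  expect_equal(subspace_distance(U, V), pa, tolerance = 1e-8)
  # invariant to right-rotation of either basis
  Rot <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  expect_equal(subspace_distance(U %*% Rot, V), subspace_distance(U, V),
               tolerance = 1e-10)
  expect_error(subspace_distance(U * 2, V), "orthonormal")
})

test_that("mean-correlation bias diagnostic is near zero for the model fit", {
  cm <- sim_cm(p = 50, n = 600, seed = 41,
               R = block_correlation(50, 25, within = 0.5),
               mu_range = c(1e-4, 1e-2))
  res <- estimate_network(cm, tests = FALSE)
  ok <- res$flags == "OK"
  bias_model <- mean_correlation_bias(res$est$mu[ok], res$rho[ok, ok])
  bl <- correlation_test(normalize_counts(cm), method = "pearson")
  bias_bl <- mean_correlation_bias(res$est$mu[ok], bl$rho[ok, ok])
  expect_lt(abs(bias_model), abs(bias_bl))
})
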