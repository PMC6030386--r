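test_that("spectral REML objective matches the dense restricted likelihood", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:20, 1)
    q <- sample(1:2, 1)
    X <- matrix(1, n, 1)
    if (q > 1) X <- cbind(X, matrix(rnorm(n * (q - 1)), n))
    L <- matrix(rnorm(n * n), n)
    K <- tcrossprod(L) / n
    y <- draw_mvn_outcome(X, rnorm(q), K, sigma_b2 = 1, sigma_e2 = 0.5)
    fit <- fit_lmm(y, X, K)
    if (fit$boundary) next
    Sigma <- fit$sigma_b2_hat * K + fit$sigma_e2_hat * diag(n)
    expect_equal(fit$reml_loglik, reml_loglik_dense(y, X, Sigma),
                 tolerance = 1e-6)
    # optimality: perturbing the variance components cannot improve the
    # dense criterion
    for (f in c(0.7, 1.3)) {
      expect_lte(reml_loglik_dense(y, X, f * Sigma),
                 fit$reml_loglik + 1e-6)
      expect_lte(reml_loglik_dense(y, X, fit$sigma_b2_hat * f * K +
                                     fit$sigma_e2_hat * diag(n)),
                 fit$reml_loglik + 1e-6)
    }
  }
})

test_that("zero kernel degenerates to ordinary least squares", {
  set.seed(42)
  n <- 25
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, -1)) + rnorm(n)
  fit <- fit_lmm(y, X, matrix(0, n, n))
  ols <- lm(y ~ X - 1)
  expect_equal(unname(fit$beta_hat), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$sigma_b2_hat, 0)
  expect_equal(fit$sigma_e2_hat, sum(resid(ols)^2) / (n - 2),
               tolerance = 1e-10)
})

test_that("variance-ratio recovery is within 0.05 at n = 300", {
  set.seed(2024)
  n <- 300
  dist <- make_dist(60, seed = 77)
  z <- make_props(n, 60, seed = 78)
  K <- tree_kernel(z, NULL, dist, kernel_spec(rho = 0.5, gamma = 1))
  K <- K / mean(diag(K))  # unit average variance so the ratio targets 0.8
  X <- matrix(1, n, 1)
  ratios <- replicate(50, {
    y <- draw_mvn_outcome(X, 0.5, K, sigma_b2 = 2, sigma_e2 = 0.5)
    f <- fit_lmm(y, X, K)
    f$sigma_b2_hat / (f$sigma_b2_hat + f$sigma_e2_hat)
  })
  expect_lt(abs(mean(ratios) - 0.8), 0.05)
})

test_that("estimation bias shrinks with sample size", {
  bias_at <- function(n, reps = 20) {
    dist <- make_dist(40, seed = 5)
    z <- make_props(n, 40, seed = 6)
    K <- tree_kernel(z, NULL, dist, kernel_spec(rho = 0.5))
    K <- K / mean(diag(K))
    X <- matrix(1, n, 1)
    set.seed(99)
    mean(replicate(reps, {
      y <- draw_mvn_outcome(X, 0, K, 2, 0.5)
      f <- fit_lmm(y, X, K)
      f$sigma_b2_hat / (f$sigma_b2_hat + f$sigma_e2_hat)
    })) - 0.8
  }
  expect_lte(abs(bias_at(300)), abs(bias_at(50)) + 0.02)
})

test_that("kernel and BLUP prediction forms agree", {
  for (seed in 1:5) {
    sim <- simulate_dataset(n = 40, p = 25,
                            design = simulation_design(m = 5,
                                                       signal_density_pct = 40),
                            seed = seed)
    idx <- 1:30
    fit <- treeglmm(sim$outcome[idx], sim$proportions[idx, ], sim$dist,
                    spec = kernel_spec(rho = 0.5, gamma = 0.7))
    z_new <- sim$proportions[-idx, ]
    p_kernel <- predict(fit, z_new, form = "kernel")
    p_blup <- predict(fit, z_new, form = "blup")
    expect_lt(max(abs(p_kernel - as.numeric(p_blup))), 1e-8)
  }
})

test_that("zero cross-kernel or zero sigma_b2 predicts the fixed part only", {
  set.seed(8)
  n <- 20
  X <- cbind(1, rnorm(n))
  L <- matrix(rnorm(n * n), n)
  K <- tcrossprod(L) / n
  y <- rnorm(n)
  fit <- fit_lmm(y, X, K)
  X_te <- cbind(1, rnorm(4))
  pred <- predict_lmm(fit, X_te, K_cross = matrix(0, 4, n))
  expect_equal(pred, drop(X_te %*% fit$beta_hat), tolerance = 1e-12)
})

test_that("prediction interpolates the training data as noise vanishes", {
  # p > n so the kernel is full rank and the conditional mean can
  # interpolate every direction of the training outcome
  sim <- simulate_dataset(n = 25, p = 50, seed = 12)
  fit <- treeglmm(sim$outcome, sim$proportions, sim$dist,
                  spec = kernel_spec(rho = 1, gamma = 1))
  inner <- fit$fit
  inner$sigma_e2_hat <- 1e-6 * var(sim$outcome)
  if (inner$sigma_b2_hat <= 0) skip("boundary fit; interpolation undefined")
  fit$fit <- inner
  pred <- predict(fit, sim$proportions)
  expect_lt(max(abs(pred - sim$outcome)), 0.05 * sd(sim$outcome))
})

test_that("predictions shrink monotonically to the fixed part as the variance ratio vanishes", {
  sim <- simulate_dataset(n = 30, p = 20, seed = 21)
  fit <- treeglmm(sim$outcome, sim$proportions, sim$dist,
                  spec = kernel_spec(rho = 1, gamma = 1))
  inner <- fit$fit
  z_new <- sim$proportions[1:5, ]
  fixed <- drop(matrix(1, 5, 1) %*% inner$beta_hat)
  prev_gap <- Inf
  for (scale in c(1, 0.1, 0.01, 0.001)) {
    f2 <- fit
    f2$fit$sigma_b2_hat <- inner$sigma_b2_hat * scale
    gap <- max(abs(predict(f2, z_new) - fixed))
    expect_lte(gap, prev_gap + 1e-10)
    prev_gap <- gap
  }
})

test_that("predictions are invariant to sample and OTU reordering", {
  sim <- simulate_dataset(n = 30, p = 15, seed = 31)
  fit <- treeglmm(sim$outcome, sim$proportions, sim$dist,
                  spec = kernel_spec(rho = 0.5, gamma = 0.5))
  z_new <- make_props(6, 15, seed = 99)
  colnames(z_new) <- sim$dist$tip_labels
  p1 <- predict(fit, z_new)
  perm_s <- c(3, 1, 6, 2, 5, 4)
  expect_equal(predict(fit, z_new[perm_s, ]), p1[perm_s], tolerance = 1e-12)
  perm_o <- sample(15)
  expect_equal(predict(fit, z_new[, perm_o]), p1, tolerance = 1e-12)
})

test_that("predictive variances are non-negative and grow off-sample", {
  sim <- simulate_dataset(n = 30, p = 20, seed = 41)
  fit <- treeglmm(sim$outcome, sim$proportions, sim$dist,
                  spec = kernel_spec(rho = 1, gamma = 1))
  pred <- predict(fit, sim$proportions, se = TRUE)
  v <- attr(pred, "variance")
  expect_true(all(v >= 0))
  expect_true(all(v <= fit$fit$sigma_b2_hat *
                    max(diag(tree_kernel(sim$proportions, NULL, sim$dist,
                                         fit$spec))) +
                    fit$fit$sigma_e2_hat + 1e-8))
})

test_that("rank-deficient designs are rejected", {
  set.seed(1)
  n <- 15
  x <- rnorm(n)
  X <- cbind(1, x, 2 * x)
  expect_error(fit_lmm(rnorm(n), X, diag(n)), "rank deficient")
})
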