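test_that("random trees are deterministic per seed and well-formed", {
  d2 <- random_tree(2, seed = 1)
  expect_equal(dim(d2$D), c(2, 2))
  expect_equal(d2$D, t(d2$D))
  expect_equal(unname(diag(d2$D)), c(0, 0))

  a <- random_tree(50, seed = 1)
  b <- random_tree(50, seed = 1)
  c <- random_tree(50, seed = 2)
  expect_equal(a$D, b$D)
  expect_gt(max(abs(a$D - c$D)), 0)
})

test_that("simulated proportions are normalized and library sizes calibrated", {
  dm <- dm_params(lognormal_proportions(40, seed = 1))
  sim <- simulate_counts(dm, 200, seed = 2)
  expect_lt(max(abs(rowSums(sim$proportions) - 1)), 1e-12)
  expect_equal(sim$counts / sim$library_sizes, sim$proportions)

  big <- simulate_counts(dm_params(rep(0.25, 4)), 5000, seed = 3)
  se <- sd(big$library_sizes) / sqrt(5000)
  expect_lt(abs(mean(big$library_sizes) - 5000), 2 * se + 3 * se)  # 5 se guard
  expect_true(all(big$library_sizes > 0))
})

test_that("compositional variance grows with the overdispersion phi", {
  mp <- c(0.4, 0.3, 0.2, 0.1)
  vars <- vapply(c(0.01, 0.1, 0.5), function(phi) {
    sim <- simulate_counts(dm_params(mp, phi = phi), 400, seed = 7)
    var(sim$proportions[, 1])
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
  # phi -> 0: proportions concentrate near the mean composition
  tight <- simulate_counts(dm_params(mp, phi = 0.001), 400, seed = 8)
  expect_lt(max(abs(colMeans(tight$proportions) - mp)), 0.02)
})

test_that("method-of-moments estimation recovers the DM parameters", {
  mp <- lognormal_proportions(20, seed = 5)
  dm <- dm_params(mp, phi = 0.05)
  sim <- simulate_counts(dm, 5000, seed = 6)
  est <- estimate_dm(sim$counts)
  expect_equal(est$mean_proportions,
               unname(colMeans(sim$proportions)), tolerance = 1e-12)
  expect_lt(abs(est$phi - 0.05) / 0.05, 0.2)

  flat <- matrix(rep(c(10, 20, 30, 40), each = 6), 6, 4)
  est0 <- estimate_dm(flat)
  expect_lt(est0$phi, 1e-6)
  expect_error(estimate_dm(matrix(5, 3, 1)), "taxa")
})

test_that("PAM clustering covers the degenerate and geometric cases", {
  dist <- make_dist(12, seed = 9)
  singletons <- pam_clusters(dist, 12)
  expect_length(singletons, 12)
  expect_true(all(lengths(singletons) == 1))
  one <- pam_clusters(dist, 1)
  expect_length(one, 1)
  expect_equal(sort(unlist(one)), 1:12, ignore_attr = TRUE)
  expect_error(pam_clusters(dist, 13), "between")

  # two far-separated clades must be recovered exactly
  D <- matrix(10, 6, 6)
  D[1:3, 1:3] <- 0.1
  D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  clades <- new_phylo_distances(paste0("t", 1:6), D)
  cl <- pam_clusters(clades, 2)
  got <- lapply(cl, function(ix) sort(unname(ix)))
  expect_true(setequal(list(got[[1]], got[[2]]), list(1:3, 4:6)))
})

test_that("aCluster selection orders the abundance levels", {
  dist <- make_dist(30, seed = 13)
  z <- make_props(50, 30, seed = 14)
  clusters <- pam_clusters(dist, 6)
  for (seed in 1:4) {
    ab <- vapply(c("low", "medium", "high"), function(level) {
      attr(select_aclusters(clusters, z, 2, level, seed = seed), "abundance")
    }, numeric(1))
    expect_true(ab["low"] <= ab["medium"] && ab["medium"] <= ab["high"])
  }
  all_sel <- select_aclusters(clusters, z, 6, "low", seed = 1)
  expect_equal(sort(as.integer(all_sel)), 1:6)

  # a single dominant cluster is always captured at the high level
  zdom <- z
  dom <- clusters[[1]]
  zdom[, dom] <- zdom[, dom] + 5
  zdom <- zdom / rowSums(zdom)
  for (seed in 1:5) {
    sel <- select_aclusters(clusters, zdom, 2, "high", seed = seed)
    expect_true(1 %in% sel)
  }
})

test_that("outcome generation hits the variance decomposition exactly", {
  for (seed in c(1, 77, 1234)) {
    sim <- simulate_dataset(n = 80, p = 60,
                            design = simulation_design(m = 6,
                                                       signal_density_pct = 34),
                            seed = seed)
    signal <- sim$truth$eta - sim$design$beta0
    frac <- var(signal) / (var(signal) + sim$truth$sigma_e2)
    expect_equal(frac, 0.8, tolerance = 1e-12)
  }
  # the generalized noise rule covers the lower signal-to-noise settings
  sim50 <- simulate_dataset(n = 60, p = 40,
                            design = simulation_design(var_explained = 0.5),
                            seed = 3)
  s <- sim50$truth$eta
  expect_equal(var(s) / (var(s) + sim50$truth$sigma_e2), 0.5,
               tolerance = 1e-12)
})

test_that("presence-transform outcomes depend only on the zero pattern", {
  dist <- make_dist(20, seed = 15)
  z <- make_props(30, 20, seed = 16)
  clusters <- pam_clusters(dist, 4)
  design <- simulation_design(m = 4, signal_density_pct = 50,
                              signal_transform = "presence")
  out1 <- generate_outcome(z, clusters, c(1, 2), design, seed = 5)
  z2 <- z * matrix(runif(length(z), 0.5, 2), nrow(z))  # same zero pattern
  out2 <- generate_outcome(z2, clusters, c(1, 2), design, seed = 5)
  expect_equal(out1$eta, out2$eta, tolerance = 1e-12)
})

test_that("binary outcomes with no OTU effect are iid Bernoulli at the intercept", {
  dist <- make_dist(15, seed = 17)
  z <- make_props(3000, 15, seed = 18)
  clusters <- pam_clusters(dist, 3)
  design <- simulation_design(m = 3, signal_density_pct = 34,
                              outcome_type = "binary", sigma_b2 = 1e-300,
                              beta0 = 0.5)
  out <- generate_outcome(z, clusters, 1, design, seed = 6)
  expect_lt(max(abs(out$eta - 0.5)), 1e-6)
  expect_lt(abs(mean(out$y) - plogis(0.5)), 0.05)
})

test_that("tree permutation preserves structure invariants", {
  dist <- make_dist(25, seed = 19)
  expect_equal(permute_tree(dist, 0, seed = 1)$D, dist$D)
  full <- permute_tree(dist, 100, seed = 2)
  expect_equal(sort(full$D[upper.tri(full$D)]),
               sort(dist$D[upper.tri(dist$D)]), tolerance = 1e-12)
  for (pct in c(10, 50, 90)) {
    perm <- permute_tree(dist, pct, seed = 3)
    expect_equal(perm$D, t(perm$D))
    expect_equal(unname(diag(perm$D)), rep(0, 25))
    expect_equal(perm$tip_labels, dist$tip_labels)
  }
})

test_that("balanced case-control sampling meets its quotas", {
  sim <- simulate_dataset(n_case = 15, n_control = 25, p = 30,
                          design = simulation_design(
                            m = 5, signal_density_pct = 40,
                            outcome_type = "binary"),
                          seed = 29)
  expect_equal(sum(sim$outcome == 1), 15)
  expect_equal(sum(sim$outcome == 0), 25)
  expect_equal(nrow(sim$proportions), 40)
})
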