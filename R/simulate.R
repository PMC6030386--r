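#' Random phylogeny over p OTUs
#'
#' Random topology with exponential branch lengths, as a self-contained
#' stand-in for a real OTU tree. Deterministic given `seed`.
#'
#' @param p Number of tips (>= 2). The real template this emulates has 778
#'   OTUs; smaller values are used for fast simulation.
#' @param seed Optional integer seed.
#' @return A `phylo_distances` object with the generating [ape::phylo] in
#'   element `$tree` (tips labelled `otu1..otup`).
#' @export
random_tree <- function(p, seed = NULL) {
  if (p < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(p, br = stats::rexp)
  tree$tip.label <- paste0("otu", seq_len(p))
  out <- phylo_distances(tree)
  out$tree <- tree
  out
}

#' Dirichlet-multinomial parameters
#'
#' @param mean_proportions Simplex vector of expected OTU proportions
#'   (normalized if it does not sum to one).
#' @param phi Overdispersion in (0, 1); the Dirichlet concentration is
#'   `mean_proportions * (1 - phi) / phi`, so small `phi` means samples
#'   close to the mean composition.
#' @param library_mean Expected total read count per sample (default 5000).
#' @param library_size_param Negative-binomial size (dispersion) parameter
#'   of the library-size distribution (default 25; variance
#'   `mu + mu^2 / size`).
#' @return An object of class `dm_params`.
#' @export
dm_params <- function(mean_proportions, phi = 0.02, library_mean = 5000,
                      library_size_param = 25) {
  mp <- as.numeric(mean_proportions)
  if (any(mp < 0) || sum(mp) <= 0) {
    stop("mean proportions must be non-negative with positive sum")
  }
  mp <- mp / sum(mp)
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  if (library_mean <= 0 || library_size_param <= 0) {
    stop("library-size parameters must be positive")
  }
  structure(list(mean_proportions = mp, phi = phi,
                 library_mean = library_mean,
                 library_size_param = library_size_param),
            class = "dm_params")
}

#' Heavy-tailed default mean composition
#'
#' Ranked log-normal proportions: a few dominant taxa and a long tail of
#' rare ones, the shape typical of 16S surveys. Used as the default mean
#' composition when no template OTU table is supplied.
#'
#' @param p Number of OTUs.
#' @param sdlog Log-scale standard deviation (default 2).
#' @param seed Optional integer seed.
#' @return Simplex vector of length `p`, sorted decreasing.
#' @export
lognormal_proportions <- function(p, sdlog = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sort(stats::rlnorm(p, meanlog = 0, sdlog = sdlog), decreasing = TRUE)
  x / sum(x)
}

#' Simulate an OTU count table from a Dirichlet-multinomial
#'
#' Per sample: library size from a negative binomial (zero draws redrawn),
#' composition from a Dirichlet with concentration
#' `mean_proportions (1 - phi) / phi`, counts multinomial, proportions the
#' counts divided by the library size.
#'
#' @param dm A [dm_params()] object.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @param otu_names Column names for the OTUs (default `otu1..otup`).
#' @return List with `counts` and `proportions` (samples x OTUs matrices)
#'   and `library_sizes`.
#' @export
simulate_counts <- function(dm, n, seed = NULL,
                            otu_names = paste0("otu", seq_along(dm$mean_proportions))) {
  stopifnot(inherits(dm, "dm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(dm$mean_proportions)
  N <- stats::rnbinom(n, mu = dm$library_mean, size = dm$library_size_param)
  n_zero <- sum(N == 0)
  while (any(N == 0)) {
    N[N == 0] <- stats::rnbinom(sum(N == 0), mu = dm$library_mean,
                                size = dm$library_size_param)
  }
  if (n_zero > 0) message(n_zero, " zero library size(s) redrawn")
  alpha <- dm$mean_proportions * (1 - dm$phi) / dm$phi
  # Dirichlet via normalized gammas, one row per sample
  G <- matrix(stats::rgamma(n * p, shape = rep(alpha, each = n)), n, p)
  P <- G / rowSums(G)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, N[i], P[i, ])[, 1],
                     numeric(p)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), otu_names)
  z <- counts / N
  list(counts = counts, proportions = z, library_sizes = N)
}

#' Method-of-moments estimation of Dirichlet-multinomial parameters
#'
#' Mean proportions are the average of the per-sample proportion vectors.
#' The overdispersion is estimated by pooling the taxon-wise moment
#' identity `Var(z_i) = pi_i (1 - pi_i) (phi + (1 - phi) E[1/N])` across
#' taxa.
#'
#' @param counts Count matrix, samples x OTUs (>= 2 samples, >= 2 taxa).
#' @param library_mean,library_size_param Carried into the returned
#'   parameter object (not estimated from `counts` unless left `NULL`, in
#'   which case the library mean is the observed mean total and the size
#'   parameter a moment estimate).
#' @return A [dm_params()] object.
#' @export
estimate_dm <- function(counts, library_mean = NULL,
                        library_size_param = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples")
  if (ncol(counts) < 2) stop("need at least 2 taxa")
  N <- rowSums(counts)
  if (any(N <= 0)) stop("every sample needs a positive total count")
  z <- counts / N
  pi_hat <- colMeans(z)
  v <- apply(z, 2, stats::var)
  cbar <- mean(1 / N)
  s <- pi_hat * (1 - pi_hat)
  phi_hat <- (sum(v) - cbar * sum(s)) / ((1 - cbar) * sum(s))
  phi_hat <- min(max(phi_hat, 1e-8), 1 - 1e-8)
  if (is.null(library_mean)) library_mean <- mean(N)
  if (is.null(library_size_param)) {
    vN <- stats::var(N)
    library_size_param <- if (vN > mean(N)) mean(N)^2 / (vN - mean(N)) else 1e6
  }
  dm_params(pi_hat, phi = phi_hat, library_mean = library_mean,
            library_size_param = library_size_param)
}

#' Partition OTUs into phylogenetic clusters
#'
#' Partitioning-around-medoids on the patristic distance matrix; with
#' `m` equal to the number of tips every OTU is its own cluster (the
#' phylogenetically unrelated limit).
#'
#' @param dist A `phylo_distances` object.
#' @param m Number of clusters, `1 <= m <= p`.
#' @return List of integer vectors of tip indices, one per cluster; tip
#'   labels carried as names of each vector.
#' @export
pam_clusters <- function(dist, m) {
  stopifnot(inherits(dist, "phylo_distances"))
  p <- length(dist$tip_labels)
  if (m < 1 || m > p) stop("m must be between 1 and the number of OTUs")
  cl <- if (m == p) {
    seq_len(p)
  } else if (m == 1) {
    rep(1L, p)
  } else {
    cluster::pam(stats::as.dist(dist$D), k = m, cluster.only = TRUE)
  }
  lapply(split(seq_len(p), cl), function(ix) {
    names(ix) <- dist$tip_labels[ix]
    ix
  })
}

#' Select outcome-associated clusters at a target abundance level
#'
#' Draws `n_draws` random subsets of `m_c` clusters, records each subset's
#' cumulative mean abundance, and returns the subset attaining the maximum
#' (`"high"`), median (`"medium"`) or minimum (`"low"`) cumulative
#' abundance.
#'
#' @param clusters List of tip-index vectors from [pam_clusters()].
#' @param proportions Samples x OTUs proportion matrix.
#' @param m_c Number of clusters to select.
#' @param abundance_level `"low"`, `"medium"` or `"high"`.
#' @param n_draws Number of random draws (default 1000).
#' @param seed Optional integer seed.
#' @return Integer vector of selected cluster indices (into `clusters`),
#'   with the achieved cumulative abundance as attribute `"abundance"`.
#' @export
select_aclusters <- function(clusters, proportions, m_c,
                             abundance_level = c("high", "medium", "low"),
                             n_draws = 1000, seed = NULL) {
  abundance_level <- match.arg(abundance_level)
  m <- length(clusters)
  if (m_c < 1 || m_c > m) stop("m_c must be between 1 and length(clusters)")
  if (!is.null(seed)) set.seed(seed)
  mean_ab <- colMeans(as.matrix(proportions))
  cl_ab <- vapply(clusters, function(ix) sum(mean_ab[ix]), numeric(1))
  draws <- replicate(n_draws, sort(sample.int(m, m_c)), simplify = FALSE)
  a_t <- vapply(draws, function(d) sum(cl_ab[d]), numeric(1))
  pick <- switch(abundance_level,
                 high = which.max(a_t),
                 low = which.min(a_t),
                 medium = order(a_t)[ceiling(n_draws / 2)])
  sel <- draws[[pick]]
  attr(sel, "abundance") <- a_t[pick]
  sel
}

#' Simulation design: one cell of the parameter sweep
#'
#' @param m Number of phylogenetic clusters the OTUs are partitioned into
#'   (small `m` = large clusters = deep phylogenetic signal; `m = p` =
#'   unrelated singleton signals).
#' @param signal_density_pct Percentage `s` of clusters carrying signal;
#'   `m_c = max(1, floor(m * s / 100))`.
#' @param abundance_level Abundance of the selected clusters
#'   (`"high"`, `"medium"`, `"low"`).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param signal_transform How abundance enters the linear predictor:
#'   `"identity"`, `"sqrt"`, or `"presence"` (indicator of non-zero).
#' @param sigma_b2 Variance of the shared per-cluster coefficients;
#'   default 2 for continuous, 4 for binary outcomes.
#' @param var_explained Fraction of outcome variance attributable to the
#'   OTU signal for continuous outcomes (default 0.8, i.e. residual
#'   variance one quarter of the signal variance; 0.5 and 0.33 give the
#'   lower signal-to-noise settings).
#' @param beta0 Intercept of the linear predictor (default 0).
#' @param tree_permute_pct Percentage of tips whose distance-matrix rows
#'   and columns are randomly permuted to emulate a mis-specified tree
#'   (default 0).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(m = 10, signal_density_pct = 10,
                              abundance_level = c("high", "medium", "low"),
                              outcome_type = c("continuous", "binary"),
                              signal_transform = c("identity", "sqrt",
                                                   "presence"),
                              sigma_b2 = NULL, var_explained = 0.8,
                              beta0 = 0, tree_permute_pct = 0) {
  abundance_level <- match.arg(abundance_level)
  outcome_type <- match.arg(outcome_type)
  signal_transform <- match.arg(signal_transform)
  if (signal_density_pct <= 0 || signal_density_pct > 100) {
    stop("signal_density_pct must be in (0, 100]")
  }
  if (is.null(sigma_b2)) {
    sigma_b2 <- if (outcome_type == "continuous") 2 else 4
  }
  if (var_explained <= 0 || var_explained >= 1) {
    stop("var_explained must be in (0, 1)")
  }
  if (tree_permute_pct < 0 || tree_permute_pct > 100) {
    stop("tree_permute_pct must be in [0, 100]")
  }
  structure(list(m = m, signal_density_pct = signal_density_pct,
                 abundance_level = abundance_level,
                 outcome_type = outcome_type,
                 signal_transform = signal_transform,
                 sigma_b2 = sigma_b2, var_explained = var_explained,
                 beta0 = beta0, tree_permute_pct = tree_permute_pct),
            class = "simulation_design")
}

apply_signal_transform <- function(z, transform) {
  switch(transform,
         identity = z,
         sqrt = sqrt(z),
         presence = (z != 0) * 1)
}

#' Generate outcomes from cluster-level abundance signals
#'
#' Each selected cluster receives one coefficient `b_l ~ N(0, sigma_b2)`
#' shared by all member OTUs; the linear predictor is
#' `eta_i = beta0 + sum_l b_l sum_{k in C_l} f(z_ik)` with `f` the design's
#' signal transform. Continuous outcomes add Gaussian noise with variance
#' `(1 - v) / v` times the empirical signal variance (v = `var_explained`),
#' so the OTUs explain exactly `v` of the outcome variability; binary
#' outcomes are Bernoulli draws through the logistic link.
#'
#' @param z Samples x OTUs proportion matrix.
#' @param clusters List of tip-index vectors from [pam_clusters()].
#' @param aclusters Indices (into `clusters`) of the signal clusters.
#' @param design A [simulation_design()].
#' @param seed Optional integer seed.
#' @param b Optional fixed coefficient vector (length `length(aclusters)`)
#'   to reuse coefficients across batches; drawn if `NULL`.
#' @return List: `y`, `eta`, `signal` (`eta - beta0`), `b`, `sigma_e2`
#'   (continuous), `pi` (binary), `aclusters`.
#' @export
generate_outcome <- function(z, clusters, aclusters, design, seed = NULL,
                             b = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!length(aclusters)) stop("need at least one signal cluster")
  if (anyDuplicated(unlist(clusters[aclusters]))) {
    stop("signal clusters must be disjoint")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- as.matrix(z)
  fz <- apply_signal_transform(z, design$signal_transform)
  S <- vapply(clusters[aclusters],
              function(ix) rowSums(fz[, ix, drop = FALSE]), numeric(nrow(z)))
  S <- matrix(S, nrow = nrow(z))
  if (is.null(b)) b <- stats::rnorm(length(aclusters), 0,
                                    sqrt(design$sigma_b2))
  signal <- drop(S %*% b)
  eta <- design$beta0 + signal
  if (design$outcome_type == "continuous") {
    v <- design$var_explained
    sigma_e2 <- (1 - v) / v * stats::var(signal)
    y <- eta + stats::rnorm(length(eta), 0, sqrt(sigma_e2))
    list(y = y, eta = eta, signal = signal, b = b, sigma_e2 = sigma_e2,
         aclusters = aclusters)
  } else {
    pi <- stats::plogis(eta)
    y <- stats::rbinom(length(eta), 1, pi)
    list(y = y, eta = eta, signal = signal, b = b, pi = pi,
         aclusters = aclusters)
  }
}

#' Permute part of a patristic distance matrix (noisy tree)
#'
#' Selects `ceiling(pct * p / 100)` tips and applies one random permutation
#' jointly to their rows and columns, emulating tree mis-specification
#' while preserving symmetry, the zero diagonal and the multiset of
#' distances.
#'
#' @param dist A `phylo_distances` object.
#' @param pct Percentage of tips to permute, 0..100.
#' @param seed Optional integer seed.
#' @return A `phylo_distances` with the same tip labels and a permuted `D`.
#' @export
permute_tree <- function(dist, pct, seed = NULL) {
  stopifnot(inherits(dist, "phylo_distances"))
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  p <- length(dist$tip_labels)
  k <- ceiling(pct * p / 100)
  if (k < 2) return(dist)
  sel <- sample.int(p, k)
  perm <- seq_len(p)
  perm[sel] <- sel[sample.int(k)]
  D <- dist$D[perm, perm]
  new_phylo_distances(dist$tip_labels, unname(D))
}

#' One complete synthetic dataset
#'
#' End-to-end generator: random tree, Dirichlet-multinomial counts with a
#' heavy-tailed mean composition, PAM clustering of the tips, selection of
#' signal clusters at the design's abundance level, and outcome generation.
#' For binary outcomes with `n_case`/`n_control` set, samples are drawn in
#' batches (coefficients fixed once) and kept until both quotas are met,
#' giving a balanced case-control sample.
#'
#' @param n Number of samples (ignored when `n_case`/`n_control` given).
#' @param p Number of OTUs.
#' @param design A [simulation_design()].
#' @param dm Optional [dm_params()]; default heavy-tailed log-normal
#'   composition with `phi = 0.02`, library mean 5000, size 25.
#' @param seed Integer seed driving every random step.
#' @param n_case,n_control Optional case/control quotas for binary designs.
#' @return List of class `sim_dataset`: `dist` (true tree distances),
#'   `dist_observed` (permuted when `tree_permute_pct > 0`, else the true
#'   one), `tree`, `counts`, `proportions`, `outcome`, `truth` (clusters,
#'   signal cluster indices, coefficients, `eta`, `sigma_e2`), `design`.
#' @export
simulate_dataset <- function(n = 100, p = 200, design = simulation_design(),
                             dm = NULL, seed = 1, n_case = NULL,
                             n_control = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$m > p) stop("design$m cannot exceed p")
  seed <- as.integer(seed) %% 900000000L
  dist <- random_tree(p, seed = seed)
  if (is.null(dm)) {
    dm <- dm_params(lognormal_proportions(p, seed = seed + 1L))
  }
  m_c <- max(1L, floor(design$m * design$signal_density_pct / 100))
  clusters <- pam_clusters(dist, design$m)
  balanced <- design$outcome_type == "binary" &&
    !is.null(n_case) && !is.null(n_control)
  n_target <- if (balanced) n_case + n_control else n

  sim <- simulate_counts(dm, n_target, seed = seed + 2L)
  sel <- select_aclusters(clusters, sim$proportions, m_c,
                          design$abundance_level, seed = seed + 3L)
  out <- generate_outcome(sim$proportions, clusters, sel, design,
                          seed = seed + 4L)
  if (balanced) {
    keep_case <- which(out$y == 1)
    keep_ctrl <- which(out$y == 0)
    counts <- sim$counts
    z <- sim$proportions
    y <- out$y
    eta <- out$eta
    batch <- 5L
    while (length(keep_case) < n_case || length(keep_ctrl) < n_control) {
      more <- simulate_counts(dm, n_target, seed = seed + batch)
      mo <- generate_outcome(more$proportions, clusters, sel, design,
                             seed = seed + batch + 1L, b = out$b)
      off <- nrow(counts)
      counts <- rbind(counts, more$counts)
      z <- rbind(z, more$proportions)
      y <- c(y, mo$y)
      eta <- c(eta, mo$eta)
      keep_case <- c(keep_case, off + which(mo$y == 1))
      keep_ctrl <- c(keep_ctrl, off + which(mo$y == 0))
      batch <- batch + 2L
      if (batch > 2000L) stop("case/control quotas unreachable; ",
                              "check the design's intercept")
    }
    keep <- sort(c(keep_case[seq_len(n_case)], keep_ctrl[seq_len(n_control)]))
    counts <- counts[keep, , drop = FALSE]
    z <- z[keep, , drop = FALSE]
    rownames(counts) <- rownames(z) <- paste0("s", seq_along(keep))
    out$y <- y[keep]
    out$eta <- eta[keep]
    sim <- list(counts = counts, proportions = z)
  }
  dist_observed <- if (design$tree_permute_pct > 0) {
    permute_tree(dist, design$tree_permute_pct, seed = seed + 4000L)
  } else dist
  structure(list(dist = dist, dist_observed = dist_observed,
                 tree = dist$tree,
                 counts = sim$counts, proportions = sim$proportions,
                 outcome = out$y,
                 truth = list(clusters = clusters, aclusters = out$aclusters,
                              b = out$b, eta = out$eta,
                              sigma_e2 = out$sigma_e2),
                 design = design, dm = dm, seed = seed),
            class = "sim_dataset")
}
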