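#' Patristic distances from a phylogenetic tree
#'
#' Wraps a tip-label vector and the matrix of patristic distances (sums of
#' branch lengths along the shortest tip-to-tip path) into the container the
#' kernel functions consume.
#'
#' @param tree An [ape::phylo] object with branch lengths, or a path to a
#'   Newick file.
#' @return An object of class `phylo_distances` with elements `tip_labels`
#'   (character vector) and `D` (symmetric non-negative matrix, zero
#'   diagonal, dimnames set to the tip labels).
#' @export
phylo_distances <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- ape::read.tree(tree)
  }
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an ape 'phylo' object or a path to a Newick file")
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances are undefined")
  }
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label, drop = FALSE]
  new_phylo_distances(tree$tip.label, D)
}

#' Construct a phylo_distances object from a raw distance matrix
#'
#' @param tip_labels Character vector of unique OTU identifiers.
#' @param D Symmetric non-negative matrix of patristic distances with zero
#'   diagonal; dimension must match `tip_labels`.
#' @return A `phylo_distances` object.
#' @export
new_phylo_distances <- function(tip_labels, D) {
  tip_labels <- as.character(tip_labels)
  D <- as.matrix(D)
  if (anyDuplicated(tip_labels)) stop("tip labels must be unique")
  if (nrow(D) != length(tip_labels) || ncol(D) != length(tip_labels)) {
    stop("dimension of D does not match the number of tip labels")
  }
  if (!all(is.finite(D))) stop("D contains non-finite entries")
  if (any(D < 0)) stop("patristic distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("D must be symmetric")
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(tip_labels, tip_labels)
  structure(list(tip_labels = tip_labels, D = D), class = "phylo_distances")
}

#' @export
print.phylo_distances <- function(x, ...) {
  cat("phylo_distances:", length(x$tip_labels), "tips, median off-diagonal",
      signif(stats::median(x$D[upper.tri(x$D)]), 4), "\n")
  invisible(x)
}

#' Kernel tuning state
#'
#' Bundles the two tuning parameters of the phylogeny-based kernel: `rho`
#' controls the phylogenetic depth at which OTU effects are correlated
#' (rho = 0 means all OTUs share one effect; rho -> Inf decorrelates them,
#' discarding the tree), and `gamma` is the exponent of the abundance power
#' transform (gamma = 0 reduces abundances to presence/absence).
#'
#' @param rho Non-negative evolutionary-rate parameter; `Inf` is accepted
#'   and maps to an identity correlation.
#' @param gamma Non-negative power-transform exponent.
#' @param squared_distance Use the squared patristic distance in the
#'   exponent (default `TRUE`, the recommended variant with a stronger
#'   signal-grouping effect); `FALSE` uses the plain distance.
#' @param rescale_distance If `TRUE`, divide distances by their median
#'   off-diagonal value before exponentiation so a common rho grid
#'   transfers across trees of different depths. Default `FALSE`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(rho = 1, gamma = 1, squared_distance = TRUE,
                        rescale_distance = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0) {
    stop("`rho` must be a single non-negative number (Inf allowed)")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("`gamma` must be a single finite non-negative number")
  }
  structure(list(rho = rho, gamma = gamma,
                 squared_distance = isTRUE(squared_distance),
                 rescale_distance = isTRUE(rescale_distance)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: rho = %g, gamma = %g, %s distance%s\n",
              x$rho, x$gamma,
              if (x$squared_distance) "squared" else "plain",
              if (x$rescale_distance) " (median-rescaled)" else ""))
  invisible(x)
}

# Relative eigenvalue floor under which the correlation matrix is clipped
# back to positive semi-definiteness.
.pd_floor <- 1e-10

#' Phylogeny-induced correlation matrix among OTU effects
#'
#' Computes `C_ij = exp(-2 * rho * d_ij)` (or `d_ij^2` with the squared
#' flag) from patristic distances. With the squared exponent positive
#' definiteness is not guaranteed, so eigenvalues below a small relative
#' floor are clipped and the diagonal re-normalized to one.
#'
#' @param dist A `phylo_distances` object.
#' @param spec A `kernel_spec`.
#' @return An object of class `correlation_matrix`: list with `C` (symmetric,
#'   unit diagonal, entries in \[0,1\]) and `pd_corrected` (logical).
#' @export
correlation_matrix <- function(dist, spec) {
  stopifnot(inherits(dist, "phylo_distances"), inherits(spec, "kernel_spec"))
  D <- dist$D
  p <- nrow(D)
  if (spec$rescale_distance && p > 1L) {
    med <- stats::median(D[upper.tri(D)])
    if (med > 0) D <- D / med
  }
  if (is.infinite(spec$rho)) {
    C <- diag(p)
    dimnames(C) <- dimnames(dist$D)
    return(structure(list(C = C, pd_corrected = FALSE),
                     class = "correlation_matrix"))
  }
  if (spec$rho == 0) {
    # exact limit: every trait identical; all-ones is PSD (rank 1), so the
    # eigenvalue floor must not perturb it
    C <- matrix(1, p, p, dimnames = dimnames(dist$D))
    return(structure(list(C = C, pd_corrected = FALSE),
                     class = "correlation_matrix"))
  }
  ex <- if (spec$squared_distance) D^2 else D
  C <- exp(-2 * spec$rho * ex)
  diag(C) <- 1
  pd_corrected <- FALSE
  if (p > 1L) {
    ev <- eigen(C, symmetric = TRUE)
    lam <- ev$values
    floor_val <- .pd_floor * max(lam)
    if (min(lam) < floor_val) {
      lam <- pmax(lam, floor_val)
      C <- ev$vectors %*% (lam * t(ev$vectors))
      # clipping perturbs the diagonal; restore unit self-correlation
      s <- 1 / sqrt(diag(C))
      C <- C * tcrossprod(s)
      C <- (C + t(C)) / 2
      diag(C) <- 1
      pd_corrected <- TRUE
    }
  }
  dimnames(C) <- dimnames(dist$D)
  structure(list(C = C, pd_corrected = pd_corrected),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d x %d%s\n", nrow(x$C), ncol(x$C),
              if (x$pd_corrected) " (PD-corrected)" else ""))
  invisible(x)
}

#' Power transform of relative abundances
#'
#' Elementwise `z^gamma` with zeros kept exactly at zero; at `gamma = 0` the
#' result is the presence/absence indicator (so the transform is continuous
#' from the definition side: `z^gamma -> 1` for `z > 0` as `gamma -> 0`).
#'
#' @param z Matrix (samples x OTUs) or vector of proportions in \[0, 1\].
#' @param gamma Non-negative exponent.
#' @return Transformed object of the same shape.
#' @export
power_transform <- function(z, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    stop("`gamma` must be a single finite non-negative number")
  }
  if (any(z < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  out <- z
  nz <- z != 0
  if (gamma == 0) {
    out[] <- as.numeric(nz)
  } else {
    out[nz] <- z[nz]^gamma
    out[!nz] <- 0
  }
  out
}

# Align the columns of an abundance matrix to the tree tips; errors on
# missing OTUs rather than silently subsetting the tree.
align_to_tips <- function(z, dist) {
  z <- as.matrix(z)
  if (is.null(colnames(z))) {
    if (ncol(z) != length(dist$tip_labels)) {
      stop("abundance matrix has ", ncol(z), " OTU columns but the tree has ",
           length(dist$tip_labels), " tips (and no column names to match by)")
    }
    colnames(z) <- dist$tip_labels
    return(z)
  }
  missing <- setdiff(dist$tip_labels, colnames(z))
  extra <- setdiff(colnames(z), dist$tip_labels)
  if (length(missing) || length(extra)) {
    stop("OTU/tip label mismatch; missing from table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "",
         "; absent from tree: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ..." else "")
  }
  z[, dist$tip_labels, drop = FALSE]
}

#' Phylogeny-based kernel between samples
#'
#' Evaluates `K = f(Z_a; gamma) C(rho) f(Z_b; gamma)^T`, the microbiome
#' similarity between all pairs of samples: the inner product of
#' power-transformed abundance profiles under the phylogeny-induced
#' correlation among OTUs.
#'
#' @param z_a Abundance matrix, samples x OTUs (proportions).
#' @param z_b Second abundance matrix, or `NULL` to reuse `z_a` (square,
#'   symmetric PSD kernel).
#' @param dist A `phylo_distances` object; columns of the abundance matrices
#'   are aligned to its tip labels (by name when present).
#' @param spec A `kernel_spec`.
#' @param C Optional precomputed `correlation_matrix` for `spec` (used by
#'   the tuning loop to avoid recomputation).
#' @return Matrix `nrow(z_a)` x `nrow(z_b)`.
#' @export
tree_kernel <- function(z_a, z_b = NULL, dist, spec, C = NULL) {
  stopifnot(inherits(dist, "phylo_distances"), inherits(spec, "kernel_spec"))
  symmetric <- is.null(z_b)
  Fa <- power_transform(align_to_tips(z_a, dist), spec$gamma)
  Fb <- if (symmetric) Fa else power_transform(align_to_tips(z_b, dist), spec$gamma)
  if (is.null(C)) C <- correlation_matrix(dist, spec)
  stopifnot(inherits(C, "correlation_matrix"))
  K <- Fa %*% C$C %*% t(Fb)
  if (symmetric) K <- (K + t(K)) / 2
  K
}
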