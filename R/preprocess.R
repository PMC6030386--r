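#' Preprocessing configuration
#'
#' @param outlier_threshold Samples with Bray-Curtis outlier index above
#'   this are removed (default 2).
#' @param prevalence_min OTUs present in fewer than this fraction of
#'   samples are removed (default 0.10).
#' @param median_nonzero_min OTUs whose median non-zero count is below
#'   this are removed (default 10).
#' @param winsor_quantile Per-taxon winsorization quantile (default 0.97).
#' @param sqrt_transform Apply a square-root transform as the final stage
#'   (default `TRUE`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(outlier_threshold = 2, prevalence_min = 0.10,
                              median_nonzero_min = 10,
                              winsor_quantile = 0.97,
                              sqrt_transform = TRUE) {
  if (outlier_threshold <= 0 || prevalence_min < 0 ||
      median_nonzero_min < 0) {
    stop("thresholds must be positive")
  }
  if (winsor_quantile <= 0 || winsor_quantile >= 1) {
    stop("winsor_quantile must be in (0, 1)")
  }
  structure(list(outlier_threshold = outlier_threshold,
                 prevalence_min = prevalence_min,
                 median_nonzero_min = median_nonzero_min,
                 winsor_quantile = winsor_quantile,
                 sqrt_transform = isTRUE(sqrt_transform)),
            class = "preprocess_config")
}

#' Remove outlier samples by Bray-Curtis distance
#'
#' For each sample the outlier index is its median Bray-Curtis distance to
#' the other samples, divided by the median of those medians; samples with
#' index above `threshold` are dropped. Distances are computed on
#' proportions so library size plays no role. If all samples are identical
#' (zero median distance) no sample is removed.
#'
#' @param counts Samples x OTUs count matrix (>= 3 samples).
#' @param threshold Outlier-index cutoff (default 2).
#' @return List: `kept` (row indices), `o` (outlier index per sample),
#'   `removed` (row names or indices dropped).
#' @export
outlier_filter <- function(counts, threshold = 2) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 3) stop("need at least 3 samples")
  z <- counts / rowSums(counts)
  d <- as.matrix(vegan::vegdist(z, method = "bray"))
  m <- vapply(seq_len(n), function(j) stats::median(d[j, -j]), numeric(1))
  med <- stats::median(m)
  if (med == 0) {
    warning("median inter-sample distance is zero; outlier index undefined, ",
            "no samples removed")
    o <- rep(1, n)
  } else {
    o <- m / med
  }
  names(o) <- rownames(counts)
  kept <- which(o <= threshold)
  list(kept = kept, o = o,
       removed = if (is.null(rownames(counts))) setdiff(seq_len(n), kept)
                 else rownames(counts)[setdiff(seq_len(n), kept)])
}

#' Filter uninformative OTUs
#'
#' Removes OTUs with prevalence (fraction of samples with a non-zero
#' count) below `prevalence_min` or with a median non-zero count below
#' `median_nonzero_min`.
#'
#' @param counts Samples x OTUs count matrix.
#' @param prevalence_min Minimum prevalence (default 0.10).
#' @param median_nonzero_min Minimum median of the non-zero counts
#'   (default 10).
#' @return List: `kept` (column indices), `prevalence`,
#'   `median_nonzero`, and per-rule casualty counts `n_low_prevalence`,
#'   `n_low_median`.
#' @export
otu_filter <- function(counts, prevalence_min = 0.10,
                       median_nonzero_min = 10) {
  counts <- as.matrix(counts)
  prev <- colMeans(counts > 0)
  med_nz <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz)) stats::median(nz) else 0
  })
  fail_prev <- prev < prevalence_min
  fail_med <- med_nz < median_nonzero_min
  kept <- which(!fail_prev & !fail_med)
  if (!length(kept)) {
    stop("no OTUs survive filtering (", sum(fail_prev),
         " below prevalence, ", sum(fail_med), " below median count)")
  }
  list(kept = kept, prevalence = prev, median_nonzero = med_nz,
       n_low_prevalence = sum(fail_prev), n_low_median = sum(fail_med))
}

#' Size-factor normalization by geometric mean of pairwise ratios
#'
#' For zero-inflated count data: the size factor of sample `j` is the
#' geometric mean, over the other samples `k`, of the median count ratio
#' `c_ij / c_ik` over taxa observed in both samples. Size factors are
#' rescaled to geometric mean one and the counts divided by them.
#'
#' @param counts Samples x OTUs count matrix; every sample must share at
#'   least one observed taxon with at least one other sample.
#' @return List: `normalized` (counts / size factor), `s` (size factors).
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 samples")
  logc <- log(counts)
  logc[!is.finite(logc)] <- NA
  s <- numeric(n)
  for (j in seq_len(n)) {
    rjk <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      if (k == j) next
      lr <- logc[j, ] - logc[k, ]
      lr <- lr[!is.na(lr)]
      if (length(lr)) rjk[k] <- stats::median(lr)
    }
    rjk <- rjk[!is.na(rjk)]
    if (!length(rjk)) {
      nm <- rownames(counts)
      stop("sample ", if (is.null(nm)) j else nm[j],
           " shares no observed taxa with any other sample")
    }
    # include the trivial self-ratio (log 1) in the geometric mean: with the
    # divisor length+1 a pure library-size scaling lambda_j is recovered
    # exactly as s_j proportional to lambda_j
    s[j] <- exp(sum(rjk) / (length(rjk) + 1))
  }
  s <- s / exp(mean(log(s)))
  names(s) <- rownames(counts)
  list(normalized = counts / s, s = s)
}

#' Cap extreme values at a per-taxon quantile
#'
#' For each taxon (column), values above its empirical `q` quantile are set
#' equal to that quantile. The inverse-ECDF quantile convention (R type 1)
#' is used: the cap is an order statistic, which makes the operation
#' exactly idempotent (an interpolated quantile shifts after capping, so a
#' second pass would cap further).
#'
#' @param x Samples x OTUs numeric matrix.
#' @param q Quantile in (0, 1), default 0.97.
#' @return Matrix of the same shape with `out <= x` elementwise.
#' @export
winsorize <- function(x, q = 0.97) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  x <- as.matrix(x)
  caps <- apply(x, 2, stats::quantile, probs = q, type = 1, names = FALSE)
  pmin(x, rep(caps, each = nrow(x)))
}

#' Full preprocessing pipeline for an OTU count table
#'
#' Fixed stage order: outlier-sample filter, OTU filter, size-factor
#' normalization, per-taxon winsorization, optional square-root transform.
#' Each stage's input/output dimensions are recorded in the report.
#'
#' @param counts Samples x OTUs count matrix.
#' @param config A [preprocess_config()].
#' @return List of class `preprocess_result`: `table` (processed matrix),
#'   `counts` (filtered raw counts), `size_factors`, `report` (per-stage
#'   dimensions and removals), `config`.
#' @export
preprocess <- function(counts, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  counts <- as.matrix(counts)
  report <- list(input = dim(counts))
  sf <- outlier_filter(counts, config$outlier_threshold)
  counts <- counts[sf$kept, , drop = FALSE]
  report$samples_removed <- sf$removed
  of <- otu_filter(counts, config$prevalence_min, config$median_nonzero_min)
  counts <- counts[, of$kept, drop = FALSE]
  report$otus_removed <- list(low_prevalence = of$n_low_prevalence,
                              low_median_nonzero = of$n_low_median)
  nf <- size_factor_normalize(counts)
  tab <- winsorize(nf$normalized, config$winsor_quantile)
  if (config$sqrt_transform) tab <- sqrt(tab)
  report$output <- dim(tab)
  structure(list(table = tab, counts = counts, size_factors = nf$s,
                 report = report, config = config),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat(sprintf(
    "preprocess: %d x %d -> %d x %d (samples x OTUs); %d sample(s) removed\n",
    x$report$input[1], x$report$input[2],
    x$report$output[1], x$report$output[2],
    length(x$report$samples_removed)))
  invisible(x)
}
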