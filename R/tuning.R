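#' Default tuning grids for the kernel parameters
#'
#' The phylogenetic-depth parameter rho is searched on
#' `{0, 2^-5, 2^-4, ..., 2^4, 2^5}` with a very large value (1e4) appended
#' as the tree-agnostic fallback (at rho = 1e4 the correlation is
#' numerically the identity and the model reduces to a plain linear kernel
#' on transformed abundances). The power-transform exponent gamma is
#' searched on `{0, 0.01, 0.1, 0.3, 0.5, ..., 1.9}` (12 values), spanning
#' presence/absence (0) through identity (1) to super-linear weighting.
#'
#' @param include_fallback Append the large tree-agnostic rho (default
#'   `TRUE`).
#' @return Numeric vector of grid values.
#' @export
default_rho_grid <- function(include_fallback = TRUE) {
  g <- c(0, 2^(-5:5))
  if (include_fallback) g <- c(g, 1e4)
  g
}

#' @rdname default_rho_grid
#' @export
default_gamma_grid <- function() {
  c(0, 0.01, seq(0.1, 1.9, by = 0.2))
}

#' Cross-validation tuning grid
#'
#' @param rho_values Ordered non-negative rho grid
#'   (default [default_rho_grid()]).
#' @param gamma_values Ordered non-negative gamma grid
#'   (default [default_gamma_grid()]).
#' @param n_folds Number of CV folds (default 5).
#' @param criterion `"auto"` (PMSE for continuous, AUC for binary),
#'   `"pmse"`, or `"auc"`.
#' @param seed Optional integer seed controlling the fold assignment.
#' @return An object of class `tuning_grid`.
#' @export
tuning_grid <- function(rho_values = default_rho_grid(),
                        gamma_values = default_gamma_grid(),
                        n_folds = 5,
                        criterion = c("auto", "pmse", "auc"),
                        seed = NULL) {
  criterion <- match.arg(criterion)
  if (!length(rho_values) || !length(gamma_values)) {
    stop("grids must be non-empty")
  }
  if (any(rho_values < 0) || any(gamma_values < 0)) {
    stop("grid values must be non-negative")
  }
  if (n_folds < 2) stop("need at least 2 folds")
  structure(list(rho_values = rho_values, gamma_values = gamma_values,
                 n_folds = as.integer(n_folds), criterion = criterion,
                 seed = seed),
            class = "tuning_grid")
}

#' Predicted mean square error
#' @param y_obs Observed outcomes.
#' @param y_hat Predictions.
#' @return Mean of squared errors.
#' @export
pmse <- function(y_obs, y_hat) {
  stopifnot(length(y_obs) == length(y_hat))
  mean((as.numeric(y_obs) - as.numeric(y_hat))^2)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tied scores averaged.
#'
#' @param y_obs 0/1 class labels containing both classes.
#' @param p_hat Scores or probabilities.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(y_obs, p_hat) {
  y_obs <- as.numeric(y_obs)
  stopifnot(length(y_obs) == length(p_hat), all(y_obs %in% c(0, 1)))
  n1 <- sum(y_obs == 1)
  n0 <- sum(y_obs == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(p_hat)
  (sum(r[y_obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Squared-correlation R2 between observed and predicted outcomes
#'
#' `R2 = {sum (yhat_i - mean(yhat)) (y_i - mean(y))}^2 /
#'       {sum (yhat_i - mean(yhat))^2 sum (y_i - mean(y))^2}`,
#' i.e. the squared sample correlation; for binary outcomes the predicted
#' probability plays the role of `y_hat`. Zero variance in either vector
#' yields 0 with a warning.
#'
#' @param y_obs Observed outcomes.
#' @param y_hat Predictions (or predicted probabilities).
#' @return Scalar in \[0, 1\].
#' @export
r_squared <- function(y_obs, y_hat) {
  y_obs <- as.numeric(y_obs)
  y_hat <- as.numeric(y_hat)
  stopifnot(length(y_obs) == length(y_hat))
  co <- y_obs - mean(y_obs)
  ch <- y_hat - mean(y_hat)
  vo <- sum(co^2)
  vh <- sum(ch^2)
  if (vo <= 0 || vh <= 0) {
    warning("zero variance in observed or predicted values; R2 set to 0")
    return(0)
  }
  sum(co * ch)^2 / (vo * vh)
}

# Fold assignment: plain random split for continuous outcomes, stratified
# by class for binary so every fold sees both classes.
make_folds <- function(y, n_folds, binary) {
  n <- length(y)
  fold <- integer(n)
  if (binary) {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      if (length(idx) < n_folds) {
        stop("cannot stratify: class ", cls, " has fewer samples (",
             length(idx), ") than folds (", n_folds, ")")
      }
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Tune (gamma, rho) by k-fold cross-validation
#'
#' Grid search over the kernel tuning parameters: for every (gamma, rho)
#' cell the held-out criterion (PMSE minimized for continuous outcomes,
#' AUC maximized for binary) is averaged over folds; the winning cell is
#' refitted on all samples. Ties are broken by the first optimum in
#' row-major order (gamma ascending, then rho ascending). Folds are
#' stratified by class for binary outcomes.
#'
#' @param y Outcome vector.
#' @param Z Abundance matrix, samples x OTUs (proportions).
#' @param tree Tree / `phylo_distances` / Newick path.
#' @param X Optional covariates (samples x covariates).
#' @param grid A [tuning_grid()].
#' @param squared_distance,rescale_distance Passed to [kernel_spec()].
#' @param family As in [treeglmm()].
#' @return An object of class `tuning_result`: `cv_table` (data.frame with
#'   columns gamma, rho, value), `best_gamma`, `best_rho`, `criterion`,
#'   and `final_model` (a `treeglmm` refit on all data at the winner).
#' @export
cross_validate <- function(y, Z, tree, X = NULL, grid = tuning_grid(),
                           squared_distance = TRUE, rescale_distance = FALSE,
                           family = c("auto", "gaussian", "binomial")) {
  stopifnot(inherits(grid, "tuning_grid"))
  family <- match.arg(family)
  dist <- as_phylo_distances(tree)
  Z <- align_to_tips(Z, dist)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(Z) != n) stop("nrow(Z) must equal length(y)")
  if (family == "auto") {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  criterion <- grid$criterion
  if (criterion == "auto") {
    criterion <- if (family == "binomial") "auc" else "pmse"
  }
  if (criterion == "auc" && family != "binomial") {
    stop("AUC criterion requires a binary outcome")
  }
  Xd <- build_design(X, n)
  if (!is.null(grid$seed)) set.seed(grid$seed)
  fold <- make_folds(y, grid$n_folds, binary = family == "binomial")

  # correlation matrices depend on rho only, transformed abundances on
  # gamma only; precompute both, then each cell is one n x n kernel whose
  # fold blocks are exact sub-kernels (entries are pairwise in samples)
  specs <- lapply(grid$rho_values, function(r)
    kernel_spec(rho = r, gamma = 1, squared_distance = squared_distance,
                rescale_distance = rescale_distance))
  Cs <- lapply(specs, function(s) correlation_matrix(dist, s))
  Fs <- lapply(grid$gamma_values, function(g) power_transform(Z, g))

  cells <- expand.grid(rho = grid$rho_values, gamma = grid$gamma_values,
                       KEEP.OUT.ATTRS = FALSE)  # gamma outer, rho inner
  cells <- cells[, c("gamma", "rho")]
  values <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    gi <- match(cells$gamma[ci], grid$gamma_values)
    ri <- match(cells$rho[ci], grid$rho_values)
    K_full <- Fs[[gi]] %*% Cs[[ri]]$C %*% t(Fs[[gi]])
    K_full <- (K_full + t(K_full)) / 2
    crit_folds <- numeric(grid$n_folds)
    for (f in seq_len(grid$n_folds)) {
      tr <- fold != f
      te <- !tr
      if (family == "gaussian") {
        fit <- fit_lmm(y[tr], Xd[tr, , drop = FALSE], K_full[tr, tr])
        pred <- predict_lmm(fit, Xd[te, , drop = FALSE],
                            K_full[te, tr, drop = FALSE])
        crit_folds[f] <- pmse(y[te], pred)
      } else {
        fit <- fit_glmm(y[tr], Xd[tr, , drop = FALSE], K_full[tr, tr])
        pred <- predict_glmm(fit, Xd[te, , drop = FALSE],
                             K_full[te, tr, drop = FALSE])
        crit_folds[f] <- if (criterion == "auc") auc(y[te], pred)
                         else pmse(y[te], pred)
      }
    }
    values[ci] <- mean(crit_folds)
  }
  best <- if (criterion == "pmse") which.min(values) else which.max(values)
  best_gamma <- cells$gamma[best]
  best_rho <- cells$rho[best]
  final_spec <- kernel_spec(rho = best_rho, gamma = best_gamma,
                            squared_distance = squared_distance,
                            rescale_distance = rescale_distance)
  final_model <- treeglmm(y, Z, dist, X = X, spec = final_spec,
                          family = family)
  structure(list(cv_table = data.frame(gamma = cells$gamma, rho = cells$rho,
                                       value = values),
                 best_gamma = best_gamma, best_rho = best_rho,
                 criterion = criterion, final_model = final_model),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result (%s over %d cells): best gamma = %g, rho = %g, %s = %.4g\n",
              x$criterion, nrow(x$cv_table), x$best_gamma, x$best_rho,
              x$criterion,
              x$cv_table$value[x$cv_table$gamma == x$best_gamma &
                                 x$cv_table$rho == x$best_rho][1]))
  invisible(x)
}
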