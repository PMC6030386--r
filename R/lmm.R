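#' Restricted log-likelihood of a Gaussian linear mixed model, dense form
#'
#' Direct evaluation of the REML criterion of `y ~ N(X beta, Sigma)` at the
#' generalized-least-squares `beta`, using dense solves and determinants
#' (no spectral shortcut). The criterion includes the `-log|X'X|` term so
#' it is invariant to the basis of the fixed-effect design.
#'
#' @param y Outcome vector.
#' @param X Design matrix (with intercept column).
#' @param Sigma Covariance matrix of `y`.
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik_dense <- function(y, X, Sigma) {
  n <- length(y)
  q <- ncol(X)
  Si <- solve(Sigma)
  XtSiX <- crossprod(X, Si %*% X)
  beta <- solve(XtSiX, crossprod(X, Si %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Si %*% r))
  ld_S <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  ld_XSX <- as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus)
  ld_XX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  -0.5 * ((n - q) * log(2 * pi) + ld_S + ld_XSX - ld_XX + quad)
}

# REML profile criterion on the spectral path, as a function of
# delta = sigma_e^2 / sigma_b^2.  Inputs are rotated into the eigenbasis of
# the (weighted) kernel: yr = U'y, Xr = U'X, lam = eigenvalues.
# Returns the profiled restricted log-likelihood and the implied estimates.
.reml_profile <- function(delta, yr, Xr, lam, ld_XX) {
  n <- length(yr)
  q <- ncol(Xr)
  h <- lam + delta
  Xh <- Xr / h
  XtHiX <- crossprod(Xr, Xh)
  beta <- solve(XtHiX, crossprod(Xh, yr))
  r <- yr - Xr %*% beta
  q2 <- sum(r^2 / h)
  sigma_b2 <- q2 / (n - q)
  ll <- -0.5 * ((n - q) * log(2 * pi) + (n - q) * log(sigma_b2) +
                  sum(log(h)) +
                  determinant(XtHiX, logarithm = TRUE)$modulus - ld_XX +
                  (n - q))
  list(ll = as.numeric(ll), beta = drop(beta), sigma_b2 = sigma_b2,
       sigma_e2 = sigma_b2 * delta)
}

# Ordinary least squares expressed as the delta -> Inf (sigma_b2 = 0)
# boundary of the same REML criterion.
.reml_ols <- function(y, X) {
  n <- length(y)
  q <- ncol(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma_e2 <- rss / (n - q)
  ll <- -0.5 * (n - q) * (log(2 * pi * sigma_e2) + 1)
  list(ll = ll, beta = fit$coefficients, sigma_b2 = 0, sigma_e2 = sigma_e2)
}

#' Fit the kernel linear mixed model by REML
#'
#' Estimates `(beta, sigma_b2, sigma_e2)` of
#' `y ~ N(X beta, sigma_b2 K + sigma_e2 W^-1)` by restricted maximum
#' likelihood. The kernel is eigendecomposed once and the REML criterion is
#' profiled down to a one-dimensional search over the variance ratio
#' `delta = sigma_e2 / sigma_b2` on a log grid (61 points over
#' `10^-6 .. 10^6`), refined by numerical optimization in the best bracket.
#' The `sigma_b2 = 0` boundary (ordinary least squares) is always evaluated
#' and returned when it dominates.
#'
#' @param y Continuous outcome vector.
#' @param X Fixed-effect design matrix; if missing, an intercept-only
#'   design. An intercept column is required (checked by column of ones).
#' @param K Symmetric PSD kernel matrix over the training samples.
#' @param weights Optional positive observation weights `w` giving residual
#'   covariance `sigma_e2 * diag(1/w)` (used by the PQL working model).
#' @return An object of class `lmm_fit`: `beta_hat`, `sigma_b2_hat`,
#'   `sigma_e2_hat`, `reml_loglik`, `delta` (ratio at the optimum, `Inf` at
#'   the boundary), `boundary` flag, and the training references `y`, `X`,
#'   `K`, `weights` needed for prediction.
#' @export
fit_lmm <- function(y, X = NULL, K, weights = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  q <- ncol(X)
  if (n < q + 2) stop("need at least ncol(X) + 2 samples")
  if (qr(X)$rank < q) stop("fixed-effect design is rank deficient")
  K <- as.matrix(K)
  if (!all(dim(K) == n)) stop("K must be n x n")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("K must be symmetric")
  }
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    w <- as.numeric(weights)
    if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
      stop("weights must be positive and finite")
    }
  }
  sw <- sqrt(w)
  yt <- y * sw
  Xt <- X * sw
  Kt <- K * tcrossprod(sw)

  ols <- .reml_ols(yt, Xt)
  kscale <- mean(diag(Kt))
  if (kscale <= 1e-12 * max(1, mean(yt^2))) {
    # degenerate kernel: model collapses to (weighted) linear regression
    fit <- ols
    delta_hat <- Inf
    boundary <- TRUE
  } else {
    ev <- eigen(Kt, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    if (min(ev$values) < -1e-8 * max(lam)) {
      warning("kernel is not PSD beyond the numerical floor; ",
              "negative eigenvalues clipped to zero")
    }
    yr <- drop(crossprod(ev$vectors, yt))
    Xr <- crossprod(ev$vectors, Xt)
    ld_XX <- determinant(crossprod(Xt), logarithm = TRUE)$modulus
    # delta grid is relative to the kernel scale so the bracket covers the
    # same variance-ratio range whatever the units of K
    grid <- kscale * 10^seq(-6, 6, length.out = 61)
    lls <- vapply(grid, function(d) .reml_profile(d, yr, Xr, lam, ld_XX)$ll,
                  numeric(1))
    i <- which.max(lls)
    lo <- log(grid[max(1L, i - 1L)])
    hi <- log(grid[min(length(grid), i + 1L)])
    opt <- stats::optimize(function(ld) .reml_profile(exp(ld), yr, Xr, lam,
                                                      ld_XX)$ll,
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-8)
    delta_hat <- exp(opt$maximum)
    fit <- .reml_profile(delta_hat, yr, Xr, lam, ld_XX)
    boundary <- FALSE
    if (ols$ll >= fit$ll) {
      fit <- ols
      delta_hat <- Inf
      boundary <- TRUE
    }
  }
  beta <- fit$beta
  names(beta) <- colnames(X)
  structure(list(beta_hat = beta,
                 sigma_b2_hat = fit$sigma_b2,
                 sigma_e2_hat = fit$sigma_e2,
                 reml_loglik = fit$ll,
                 delta = delta_hat,
                 boundary = boundary,
                 y = y, X = X, K = K, weights = w),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "kernel LMM fit (REML): sigma_b2 = %.4g, sigma_e2 = %.4g%s\n",
    x$sigma_b2_hat, x$sigma_e2_hat,
    if (x$boundary) " [sigma_b2 at boundary 0]" else ""))
  cat("fixed effects:", paste(sprintf("%.4g", x$beta_hat), collapse = ", "),
      "\n")
  invisible(x)
}

# Solve Sigma %*% X = B for symmetric PD Sigma with a one-shot jitter
# retry (rho = 0 makes the kernel rank one and Sigma can be near singular).
solve_sym <- function(Sigma, B) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * sum(diag(Sigma)) / nrow(Sigma)
    ch <- tryCatch(chol(Sigma + jit * diag(nrow(Sigma))),
                   error = function(e) NULL)
    if (is.null(ch)) stop("training covariance is singular even after jitter")
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

#' Predict new samples from a fitted kernel LMM
#'
#' Conditional-mean prediction under the joint Gaussian model:
#' `y_hat = X_te beta + sigma_b2 K_cross Sigma_tr^-1 (y_tr - X_tr beta)`
#' with `Sigma_tr = sigma_b2 K_tr + sigma_e2 W^-1`.
#'
#' @param model An `lmm_fit`.
#' @param X_te Test fixed-effect design (matrix, rows = test samples); if
#'   `NULL`, an intercept-only design matching `K_cross`.
#' @param K_cross Cross-kernel matrix, test samples x training samples.
#' @param K_te Optional test-test kernel; when supplied together with
#'   `se = TRUE`, the diagonal of the conditional covariance is returned.
#' @param se Return predictive variances (requires `K_te`).
#' @return Numeric vector of predictions, with attribute `"variance"` when
#'   `se = TRUE`.
#' @export
predict_lmm <- function(model, X_te = NULL, K_cross, K_te = NULL, se = FALSE) {
  stopifnot(inherits(model, "lmm_fit"))
  K_cross <- as.matrix(K_cross)
  n_te <- nrow(K_cross)
  if (is.null(X_te)) X_te <- matrix(1, n_te, ncol(model$X))
  X_te <- as.matrix(X_te)
  if (ncol(X_te) != ncol(model$X)) stop("X_te has wrong number of columns")
  if (nrow(X_te) != n_te) stop("X_te rows must match K_cross rows")
  if (ncol(K_cross) != length(model$y)) {
    stop("K_cross columns must match the training sample count")
  }
  mean_part <- drop(X_te %*% model$beta_hat)
  resid <- model$y - drop(model$X %*% model$beta_hat)
  if (model$sigma_b2_hat <= 0) {
    yhat <- mean_part
    if (se) attr(yhat, "variance") <- rep(model$sigma_e2_hat, n_te)
    return(yhat)
  }
  Sigma_tr <- model$sigma_b2_hat * model$K +
    model$sigma_e2_hat * diag(1 / model$weights)
  alpha <- solve_sym(Sigma_tr, resid)
  yhat <- mean_part + model$sigma_b2_hat * drop(K_cross %*% alpha)
  if (se) {
    if (is.null(K_te)) stop("K_te is required for predictive variances")
    V_cross <- model$sigma_b2_hat * K_cross
    tmp <- solve_sym(Sigma_tr, t(V_cross))
    v <- model$sigma_b2_hat * diag(as.matrix(K_te)) + model$sigma_e2_hat -
      rowSums(V_cross * t(tmp))
    attr(yhat, "variance") <- pmax(v, 0)
  }
  yhat
}
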