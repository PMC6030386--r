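#' Fit a phylogeny-regularized mixed model to an OTU table
#'
#' The user-facing fit: takes relative abundances, a phylogenetic tree and
#' an optional covariate matrix, builds the phylogeny-based kernel
#' `K = f(Z; gamma) C(rho) f(Z; gamma)^T`, and fits the outcome by REML
#' (continuous) or PQL (binary). OTU effects are random with correlation
#' `C(rho)` induced by patristic distances, so the model pools signal
#' across related taxa; covariate effects are fixed.
#'
#' @param y Outcome vector: continuous, or 0/1 for binary.
#' @param Z Abundance matrix, samples x OTUs (proportions in \[0, 1\]);
#'   column names matched to tree tip labels when present.
#' @param tree An [ape::phylo], a `phylo_distances`, or a Newick file path.
#' @param X Optional covariate matrix/data.frame (samples x covariates);
#'   an intercept is always added as the first column.
#' @param spec A [kernel_spec()] fixing `(gamma, rho)`.
#' @param family `"gaussian"`, `"binomial"`, or `"auto"` (binary iff `y`
#'   takes only values 0 and 1).
#' @param ... Passed to [fit_glmm()] for binary outcomes.
#' @return An object of class `treeglmm` wrapping the kernel-level fit
#'   (`$fit`, an `lmm_fit` or `glmm_fit`) together with the training
#'   abundances, design, phylogeny and kernel state needed for prediction.
#' @seealso [predict.treeglmm()], [cross_validate()]
#' @examples
#' sim <- simulate_dataset(n = 40, p = 30, seed = 1)
#' fit <- treeglmm(sim$outcome, sim$proportions, sim$dist,
#'                 spec = kernel_spec(rho = 1, gamma = 0.5))
#' predict(fit, sim$proportions)[1:5]
#' @export
treeglmm <- function(y, Z, tree, X = NULL, spec = kernel_spec(),
                     family = c("auto", "gaussian", "binomial"), ...) {
  family <- match.arg(family)
  dist <- as_phylo_distances(tree)
  Z <- align_to_tips(Z, dist)
  y <- as.numeric(y)
  if (nrow(Z) != length(y)) stop("nrow(Z) must equal length(y)")
  if (family == "auto") {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  Xd <- build_design(X, length(y))
  C <- correlation_matrix(dist, spec)
  K <- tree_kernel(Z, NULL, dist, spec, C = C)
  fit <- if (family == "gaussian") {
    fit_lmm(y, Xd, K)
  } else {
    fit_glmm(y, Xd, K, ...)
  }
  structure(list(fit = fit, family = family, spec = spec, dist = dist,
                 Z = Z, X = Xd, y = y, C = C),
            class = "treeglmm")
}

# Intercept-first fixed design from an optional covariate table.
build_design <- function(X, n) {
  if (is.null(X)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("covariate rows must match the number of samples")
  cbind("(Intercept)" = 1, X)
}

as_phylo_distances <- function(tree) {
  if (inherits(tree, "phylo_distances")) tree else phylo_distances(tree)
}

#' @export
print.treeglmm <- function(x, ...) {
  cat(sprintf("treeglmm fit (%s): n = %d samples, p = %d OTUs\n",
              x$family, length(x$y), length(x$dist$tip_labels)))
  print(x$spec)
  print(x$fit)
  invisible(x)
}

#' Predict outcomes for new samples
#'
#' Conditional-mean ("kernel") prediction by default:
#' `y_hat = X_te beta + Sigma_te,tr Sigma_tr^-1 (y_tr - X_tr beta)`.
#' `form = "blup"` instead materializes the best linear unbiased predictor
#' of the per-OTU random effects,
#' `b_hat = sigma_b2 C f(Z_tr)' Sigma_tr^-1 (y_tr - X_tr beta)`, and
#' predicts `X_te beta + f(Z_te) b_hat`; the two forms agree to numerical
#' precision and the BLUP route additionally exposes `b_hat` as an
#' attribute.
#'
#' @param object A `treeglmm` fit.
#' @param Z_new Abundance matrix for the new samples (samples x OTUs).
#' @param X_new Covariates for the new samples (same columns as at fit
#'   time, intercept added automatically).
#' @param type `"response"` (default; probabilities for binary fits) or
#'   `"link"` (linear predictor).
#' @param form `"kernel"` or `"blup"`.
#' @param se Also return predictive variances (continuous, kernel form
#'   only) as attribute `"variance"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.treeglmm <- function(object, Z_new, X_new = NULL,
                             type = c("response", "link"),
                             form = c("kernel", "blup"), se = FALSE, ...) {
  type <- match.arg(type)
  form <- match.arg(form)
  Z_new <- align_to_tips(Z_new, object$dist)
  n_te <- nrow(Z_new)
  X_te <- if (is.null(X_new)) {
    if (ncol(object$X) > 1) stop("model was fitted with covariates; supply X_new")
    matrix(1, n_te, 1)
  } else {
    build_design(X_new, n_te)
  }
  inner <- if (object$family == "gaussian") object$fit else object$fit$working
  if (form == "kernel") {
    K_cross <- tree_kernel(Z_new, object$Z, object$dist, object$spec,
                           C = object$C)
    K_te <- if (se) tree_kernel(Z_new, NULL, object$dist, object$spec,
                                C = object$C) else NULL
    eta <- predict_lmm(inner, X_te = X_te, K_cross = K_cross, K_te = K_te,
                       se = se)
  } else {
    eta <- drop(X_te %*% inner$beta_hat)
    if (inner$sigma_b2_hat > 0) {
      F_tr <- power_transform(object$Z, object$spec$gamma)
      F_te <- power_transform(Z_new, object$spec$gamma)
      Sigma_tr <- inner$sigma_b2_hat * inner$K +
        inner$sigma_e2_hat * diag(1 / inner$weights)
      alpha <- solve_sym(Sigma_tr, inner$y - drop(inner$X %*% inner$beta_hat))
      b_hat <- inner$sigma_b2_hat *
        drop(object$C$C %*% crossprod(F_tr, alpha))
      eta <- eta + drop(F_te %*% b_hat)
      attr(eta, "b_hat") <- stats::setNames(b_hat, object$dist$tip_labels)
    }
  }
  if (object$family == "binomial" && type == "response") {
    p <- stats::plogis(as.numeric(eta))
    p <- pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
    attributes(p) <- attributes(eta)[setdiff(names(attributes(eta)), "names")]
    return(p)
  }
  eta
}

#' Serialize a fitted model to JSON
#'
#' Writes every component needed to reproduce predictions (coefficients,
#' variance components, kernel state, training abundances, outcome, design,
#' patristic distances, and — for binary fits — the converged working
#' response and weights) so `fit` and `predict` can run as separate CLI
#' invocations.
#'
#' @param object A `treeglmm` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "treeglmm"))
  inner <- if (object$family == "gaussian") object$fit else object$fit$working
  doc <- list(
    format = "treeglmm-model", version = 1L,
    family = object$family,
    spec = unclass(object$spec),
    beta_hat = as.numeric(inner$beta_hat),
    beta_names = names(inner$beta_hat),
    sigma_b2_hat = inner$sigma_b2_hat,
    sigma_e2_hat = inner$sigma_e2_hat,
    reml_loglik = inner$reml_loglik,
    y = object$y,
    working_y = inner$y,
    weights = inner$weights,
    X = object$X,
    Z = object$Z,
    tip_labels = object$dist$tip_labels,
    D = object$dist$D,
    pql = if (object$family == "binomial") {
      list(iterations = object$fit$iterations,
           converged = object$fit$converged,
           eta = object$fit$eta)
    })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path File written by [write_model()].
#' @return A `treeglmm` object; the kernel is rebuilt from the stored
#'   abundances, distances and tuning state.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "treeglmm-model")) {
    stop("not a treeglmm model file: ", path)
  }
  spec <- kernel_spec(rho = doc$spec$rho, gamma = doc$spec$gamma,
                      squared_distance = doc$spec$squared_distance,
                      rescale_distance = doc$spec$rescale_distance)
  dist <- new_phylo_distances(doc$tip_labels, doc$D)
  Z <- as.matrix(doc$Z)
  colnames(Z) <- doc$tip_labels
  X <- as.matrix(doc$X)
  colnames(X) <- doc$beta_names
  C <- correlation_matrix(dist, spec)
  K <- tree_kernel(Z, NULL, dist, spec, C = C)
  inner <- structure(list(
    beta_hat = stats::setNames(as.numeric(doc$beta_hat), doc$beta_names),
    sigma_b2_hat = doc$sigma_b2_hat,
    sigma_e2_hat = doc$sigma_e2_hat,
    reml_loglik = doc$reml_loglik,
    delta = if (doc$sigma_b2_hat > 0) doc$sigma_e2_hat / doc$sigma_b2_hat
            else Inf,
    boundary = doc$sigma_b2_hat <= 0,
    y = as.numeric(doc$working_y), X = X, K = K,
    weights = as.numeric(doc$weights)), class = "lmm_fit")
  fit <- if (doc$family == "binomial") {
    structure(list(working = inner, eta = as.numeric(doc$pql$eta),
                   mu = stats::plogis(as.numeric(doc$pql$eta)),
                   beta_hat = inner$beta_hat,
                   sigma_b2_hat = inner$sigma_b2_hat,
                   sigma_e2_hat = inner$sigma_e2_hat,
                   iterations = doc$pql$iterations,
                   converged = doc$pql$converged,
                   eta_steps = numeric(0),
                   y = as.numeric(doc$y)), class = "glmm_fit")
  } else {
    inner
  }
  structure(list(fit = fit, family = doc$family, spec = spec, dist = dist,
                 Z = Z, X = X, y = as.numeric(doc$y), C = C),
            class = "treeglmm")
}
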