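#' Adaptive elastic-net penalty value
#'
#' `sum_j [ (1-alpha)/2 * beta_j^2 + alpha * w_j * |beta_j| ]`, the mixed
#' ridge/weighted-L1 penalty applied to the edge coefficients (never to the
#' intercept).
#'
#' @param beta coefficient vector
#' @param alpha elastic-net mixing parameter in (0, 1]
#' @param weights per-coefficient L1 multipliers (default all 1)
#' @return penalty value (nonnegative scalar)
#' @export
aen_penalty <- function(beta, alpha, weights = rep(1, length(beta))) {
  w <- if (inherits(weights, "penalty_weights")) weights$normalized else weights
  stopifnot(length(w) == length(beta))
  sum(0.5 * (1 - alpha) * beta^2 + alpha * w * abs(beta))
}

log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))

#' Penalized log-likelihood objective
#'
#' The average Bernoulli log-likelihood of the logistic model minus
#' `lambda` times [aen_penalty()], computed with a numerically stable
#' log(1+exp) so that saturated linear predictors do not overflow.
#'
#' @param beta0 intercept
#' @param beta coefficient vector
#' @param x feature matrix (columns aligned with `beta`)
#' @param y 0/1 response
#' @param lambda penalty level
#' @param alpha mixing parameter
#' @param weights L1 multipliers
#' @return objective value (to be maximized)
#' @export
aen_objective <- function(beta0, beta, x, y, lambda, alpha,
                          weights = rep(1, length(beta))) {
  eta <- as.vector(beta0 + x %*% beta)
  mean(y * eta - log1pexp(eta)) - lambda * aen_penalty(beta, alpha, weights)
}

resolve_features <- function(x) {
  if (inherits(x, "edge_features")) {
    list(x = x$x, y = x$y, exclude = x$zero_var, ids = colnames(x$x), ef = x)
  } else {
    x <- as.matrix(x)
    list(x = x, y = NULL, exclude = rep(FALSE, ncol(x)),
         ids = colnames(x) %||% paste0("f", seq_len(ncol(x))), ef = NULL)
  }
}

resolve_weights <- function(weights, M, ids) {
  if (is.null(weights)) return(rep(1, M))
  w <- if (inherits(weights, "penalty_weights")) weights$normalized else weights
  if (!is.null(names(w)) && !is.null(ids) && all(ids %in% names(w))) w <- w[ids]
  if (length(w) != M) stop("penalty weight length does not match feature count")
  if (any(!is.finite(w)) || any(w <= 0)) stop("penalty weights must be positive and finite")
  unname(w)
}

#' Smallest penalty level with an all-zero solution
#'
#' `lambda_max = max_m |x_m' (y - ybar)| / (n * alpha * w_m)` over penalized
#' columns of a standardized feature matrix: fitting at or above this level
#' yields an empty model, so it anchors the top of the regularization path.
#'
#' @param x standardized feature matrix or `edge_features`
#' @param y 0/1 response (taken from `x` when it carries labels)
#' @param alpha mixing parameter, must be positive (pure ridge never
#'   thresholds to zero)
#' @param weights L1 multipliers
#' @return positive scalar
#' @export
aen_lambda_max <- function(x, y = NULL, alpha = 0.3, weights = NULL) {
  if (alpha <= 0) stop("alpha must be positive: ridge has no sparsity threshold")
  f <- resolve_features(x)
  y <- y %||% f$y
  n <- nrow(f$x)
  w <- resolve_weights(weights, ncol(f$x), f$ids)
  g <- abs(as.vector(crossprod(f$x, y - mean(y)))) / (n * alpha * w)
  g[f$exclude] <- 0
  max(g)
}

default_lambda_grid <- function(lmax, nlambda, lambda_min_ratio) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit the penalized edge-interaction logistic model along a lambda path
#'
#' Maximizes the penalized log-likelihood by iteratively reweighted least
#' squares with an inner cyclic coordinate-descent sweep, warm-starting each
#' point of a log-spaced decreasing lambda grid from the previous solution.
#' IRLS probabilities are clamped to \[1e-5, 1-1e-5\] to keep working weights
#' bounded under separation. Convergence at each lambda is certified by the
#' KKT stationarity residual of the true (unclamped) objective.
#'
#' @param x an `edge_features` object (standardized) or a numeric matrix
#' @param y 0/1 response; taken from `x` if absent
#' @param alpha elastic-net mixing parameter (default 0.3)
#' @param weights `penalty_weights` or numeric L1 multipliers (default 1)
#' @param nlambda number of path points (default 100)
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#' @param lambda optional explicit decreasing lambda sequence
#' @param tol_inner coordinate-descent tolerance on the maximum weighted
#'   squared coefficient change
#' @param tol_outer IRLS tolerance on the maximum coefficient change
#' @param max_outer,max_inner iteration caps
#' @param kkt_tol residual below which a fit is flagged converged
#' @return object of class `aen_path`: `lambda`, `beta0` (vector), `beta`
#'   (M x nlambda matrix, rownames = feature ids), `kkt`, `iterations`,
#'   `converged`, `df` (active-set sizes), `selection_count` (per feature,
#'   number of path points with nonzero coefficient), `alpha`, `weights`.
#' @export
aen_path <- function(x, y = NULL, alpha = 0.3, weights = NULL,
                     nlambda = 100L, lambda_min_ratio = 0.01, lambda = NULL,
                     tol_inner = 1e-8, tol_outer = 1e-8,
                     max_outer = 100L, max_inner = 1000L, kkt_tol = 1e-4) {
  f <- resolve_features(x)
  y <- y %||% f$y
  if (is.null(y)) stop("response y is required")
  y <- as.numeric(y)
  if (length(y) != nrow(f$x)) stop("length of y does not match rows of x")
  if (anyNA(f$x) || any(!is.finite(f$x))) stop("non-finite values in feature matrix")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  w <- resolve_weights(weights, ncol(f$x), f$ids)

  if (is.null(lambda)) {
    lmax <- aen_lambda_max(x, y, alpha, weights)
    if (lmax <= 0) lmax <- 1e-3  # all columns orthogonal to the response
    lambda <- default_lambda_grid(lmax, nlambda, lambda_min_ratio)
  } else {
    lambda <- as.numeric(lambda)
    if (any(diff(lambda) >= 0)) {
      if (length(lambda) > 1L) stop("lambda must be strictly decreasing")
    }
    if (any(lambda <= 0)) stop("lambda must be positive")
  }

  res <- cd_aen_path(f$x, y, w, alpha, lambda, f$exclude,
                     tol_inner, tol_outer, as.integer(max_outer),
                     as.integer(max_inner), 1e-5, kkt_tol)
  beta <- res$beta
  rownames(beta) <- f$ids
  sel <- rowSums(beta != 0)
  structure(list(lambda = lambda, beta0 = as.vector(res$beta0), beta = beta,
                 kkt = as.vector(res$kkt), iterations = as.vector(res$iterations),
                 converged = as.vector(res$converged),
                 df = colSums(beta != 0), selection_count = sel,
                 alpha = alpha, weights = w, features = f$ef),
            class = "aen_path")
}

#' @export
print.aen_path <- function(x, ...) {
  cat(sprintf("aen_path: %d lambda values, %d features, df range %d-%d\n",
              length(x$lambda), nrow(x$beta), min(x$df), max(x$df)))
  invisible(x)
}

#' Fit at a single penalty level
#'
#' Convenience wrapper around [aen_path()] for one lambda (optionally warm
#' started from above via a short internal path).
#'
#' @inheritParams aen_path
#' @param lambda single positive penalty level
#' @return object of class `aen_fit`: `beta0`, `beta` (named), `active`
#'   (ids of nonzero coefficients), `lambda`, `alpha`, `objective`,
#'   `kkt_residual`, `iterations`, `converged`.
#' @export
aen_fit <- function(x, y = NULL, lambda, alpha = 0.3, weights = NULL, ...) {
  stopifnot(length(lambda) == 1L, lambda > 0)
  path <- aen_path(x, y, alpha = alpha, weights = weights, lambda = lambda, ...)
  f <- resolve_features(x)
  yy <- y %||% f$y
  beta <- path$beta[, 1L]
  obj <- aen_objective(path$beta0[1L], beta, f$x, yy, lambda, alpha, path$weights)
  structure(list(beta0 = path$beta0[1L], beta = beta,
                 active = names(beta)[beta != 0], lambda = lambda,
                 alpha = alpha, weights = path$weights, objective = obj,
                 kkt_residual = path$kkt[1L], iterations = path$iterations[1L],
                 converged = path$converged[1L], features = f$ef),
            class = "aen_fit")
}

#' @export
print.aen_fit <- function(x, ...) {
  cat(sprintf("aen_fit: lambda = %.4g, %d active of %d features, KKT %.2e\n",
              x$lambda, length(x$active), length(x$beta), x$kkt_residual))
  invisible(x)
}

#' Predicted class probabilities
#'
#' @param object an `aen_fit`
#' @param newx feature matrix aligned with the fit's columns (an
#'   `edge_features` built with the same record, or a matrix)
#' @param type `"response"` (probabilities), `"link"` or `"class"`
#' @param ... unused
#' @return numeric vector
#' @export
predict.aen_fit <- function(object, newx, type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  xm <- if (inherits(newx, "edge_features")) newx$x else as.matrix(newx)
  if (ncol(xm) != length(object$beta)) stop("feature column mismatch")
  if (!is.null(colnames(xm)) && !identical(colnames(xm), names(object$beta))) {
    if (!all(names(object$beta) %in% colnames(xm))) stop("feature column mismatch")
    xm <- xm[, names(object$beta), drop = FALSE]
  }
  eta <- as.vector(object$beta0 + xm %*% object$beta)
  switch(type,
         link = eta,
         response = 1 / (1 + exp(-eta)),
         class = as.integer(eta > 0))
}

#' Extract one path point as a fit
#' @param path an `aen_path`
#' @param index lambda index
#' @return an `aen_fit`
#' @export
path_fit <- function(path, index) {
  stopifnot(index >= 1L, index <= length(path$lambda))
  beta <- path$beta[, index]
  structure(list(beta0 = path$beta0[index], beta = beta,
                 active = names(beta)[beta != 0], lambda = path$lambda[index],
                 alpha = path$alpha, weights = path$weights, objective = NA_real_,
                 kkt_residual = path$kkt[index], iterations = path$iterations[index],
                 converged = path$converged[index], features = path$features),
            class = "aen_fit")
}

#' KKT stationarity residual of a penalized logistic solution
#'
#' Independent R-side check of the certificate the solver reports: for
#' active coordinates the subgradient equation must hold, for inactive ones
#' the gradient must lie inside the L1 threshold, and the intercept gradient
#' must vanish.
#'
#' @param beta0,beta solution
#' @param x feature matrix
#' @param y 0/1 response
#' @param lambda,alpha,weights penalty configuration
#' @return maximum violation (scalar)
#' @export
kkt_residual <- function(beta0, beta, x, y, lambda, alpha,
                         weights = rep(1, length(beta))) {
  w <- if (inherits(weights, "penalty_weights")) weights$normalized else weights
  p <- 1 / (1 + exp(-(beta0 + as.vector(x %*% beta))))
  g <- as.vector(crossprod(x, y - p)) / length(y)
  act <- beta != 0
  viol <- abs(mean(y - p))
  if (any(act)) {
    viol <- max(viol, abs(g[act] - lambda * (1 - alpha) * beta[act] -
                            lambda * alpha * w[act] * sign(beta[act])))
  }
  if (any(!act)) {
    viol <- max(viol, max(pmax(abs(g[!act]) - lambda * alpha * w[!act], 0)))
  }
  viol
}

#' Serialize a solution path
#'
#' Writes `<prefix>_coefficients.tsv` (feature id, one column per lambda),
#' `<prefix>_selection.tsv` (feature id, selection count) and
#' `<prefix>_path.json` (lambda grid, intercepts, convergence metadata).
#'
#' @param path an `aen_path`
#' @param prefix output path prefix
#' @return invisibly, the written file names
#' @export
write_solution_path <- function(path, prefix) {
  coef_file <- paste0(prefix, "_coefficients.tsv")
  sel_file <- paste0(prefix, "_selection.tsv")
  meta_file <- paste0(prefix, "_path.json")
  cf <- data.frame(feature = rownames(path$beta), path$beta, check.names = FALSE)
  colnames(cf)[-1L] <- sprintf("lambda_%03d", seq_along(path$lambda))
  write.table(cf, coef_file, sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- data.frame(feature = rownames(path$beta),
                    selection_count = unname(path$selection_count))
  sel <- sel[order(-sel$selection_count, sel$feature), ]
  write.table(sel, sel_file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(lambda = path$lambda, beta0 = path$beta0,
                            kkt = path$kkt, converged = path$converged,
                            alpha = path$alpha, df = unname(path$df)),
                       meta_file, auto_unbox = TRUE, digits = NA)
  invisible(c(coef_file, sel_file, meta_file))
}
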