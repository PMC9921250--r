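#' L2-regularised logistic regression via IRLS
#'
#' Minimises the negative binomial log-likelihood plus `alpha/2 * ||beta||^2`
#' (intercept unpenalised) by iteratively reweighted least squares; the
#' deterministic full-batch analogue of the stochastic-average-gradient
#' solver, with the same objective. Backbone of the `lr` base model, the RFE
#' ranker and the stacking meta-layer.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param alpha L2 penalty strength (default 0.1).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return list with `intercept`, `beta`.
#' @export
ridge_logistic <- function(x, y, alpha = 0.1, max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xb <- cbind(1, x)
  pen <- diag(c(0, rep(alpha, p)), p + 1)
  coefs <- numeric(p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(xb %*% coefs)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(xb * w)
    new <- drop(solve(xtw %*% xb + pen, xtw %*% z))
    if (max(abs(new - coefs)) < tol) { coefs <- new; break }
    coefs <- new
  }
  list(intercept = coefs[1], beta = coefs[-1])
}

predict_ridge_logistic <- function(fit, x)
  sigmoid(fit$intercept + drop(as.matrix(x) %*% fit$beta))
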