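#' RBF-kernel soft-margin SVM (dual quadratic program) with Platt calibration
#'
#' Solves the dual soft-margin problem `max sum(a) - a' Q a / 2` subject to
#' `0 <= a_i <= C`, `sum(a_i y_i) = 0` with `Q_ij = y_i y_j K(x_i, x_j)`,
#' using a dense QP solver; a small ridge keeps Q positive definite.
#' Decision probabilities come from Platt scaling: a univariate logistic fit
#' of the labels on the decision values.
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y 0/1 labels.
#' @param cost soft-margin C (default 1).
#' @param gamma RBF width; `"scale"` (default) uses `1 / (p * var(x))`.
#' @param tol support-vector threshold on the dual coefficients.
#' @return object of class `svm_rbf`.
#' @keywords internal
svm_rbf <- function(x, y, cost = 1, gamma = "scale", tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  ys <- ifelse(y == 1, 1, -1)
  if (identical(gamma, "scale")) {
    v <- mean(apply(x, 2, var))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  K <- .rbf_kernel(x, x, gamma)
  Q <- (ys %o% ys) * K + diag(1e-8, n)
  # quadprog: min -d'a + a'Da/2  s.t. A'a >= b (first meq as equalities)
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n), Amat = Amat,
                            bvec = bvec, meq = 1)
  a <- pmin(pmax(sol$solution, 0), cost)
  sv <- a > tol
  # intercept from margin vectors (0 < a < C), fall back to all SVs
  marg <- sv & a < cost - tol
  if (!any(marg)) marg <- sv
  f_no_b <- K %*% (a * ys)
  b <- mean(ys[marg] - f_no_b[marg])
  fit <- list(x_sv = x[sv, , drop = FALSE], coef_sv = (a * ys)[sv],
              b = b, gamma = gamma)
  dec <- drop(f_no_b + b)
  platt <- ridge_logistic(matrix(dec, ncol = 1), y, alpha = 1e-6)
  fit$platt <- platt
  structure(fit, class = "svm_rbf")
}

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  k <- .rbf_kernel(as.matrix(newdata), object$x_sv, object$gamma)
  dec <- drop(k %*% object$coef_sv) + object$b
  predict_ridge_logistic(object$platt, matrix(dec, ncol = 1))
}
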