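#' Fit a depth-limited regression/classification tree (CART)
#'
#' Greedy weighted least-squares CART. On 0/1 responses the squared-error
#' impurity is proportional to the Gini impurity, so the same engine serves
#' the decision-tree feature ranker, the bagged random forest and the
#' Newton-step gradient-boosting learner.
#'
#' @param x numeric feature matrix.
#' @param y numeric response (0/1 labels or pseudo-residuals).
#' @param w observation weights (default 1).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_split minimum rows in a node to attempt a split.
#' @param min_leaf minimum rows per child.
#' @param mtry features sampled per node (default all).
#' @param min_gain minimum SSE reduction to accept a split.
#' @param seed seed for the per-node feature subsampling.
#' @return object of class `cart_tree` with `$importance` (per-column SSE
#'   reduction totals).
#' @export
cart_tree <- function(x, y, w = rep(1, length(y)), max_depth = 4L,
                      min_split = 10L, min_leaf = 3L, mtry = ncol(x),
                      min_gain = 1e-9, seed = 1L) {
  x <- as.matrix(x)
  fit <- .cart_grow(x, as.numeric(y), as.numeric(w), as.integer(max_depth),
                    as.integer(min_split), as.integer(min_leaf),
                    as.integer(mtry), min_gain, as.integer(seed))
  names(fit$importance) <- colnames(x)
  structure(fit, class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  .cart_predict(unclass(object), as.matrix(newdata))
}
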