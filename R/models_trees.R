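#' Random forest of bagged CART trees with majority vote
#'
#' Each tree is grown on a bootstrap sample with per-node feature subsampling
#' (`mtry = floor(sqrt(p))`); each tree votes for the class of its leaf
#' (leaf class-1 fraction >= 0.5) and the forest's positive probability is
#' the fraction of trees voting 1.
#'
#' @param x numeric feature matrix; @param y 0/1 labels.
#' @param n_trees,max_depth,min_split,min_leaf ensemble shape.
#' @param seed RNG seed.
#' @return object of class `rf_model`.
#' @keywords internal
random_forest <- function(x, y, n_trees = 60L, max_depth = 4L,
                          min_split = 10L, min_leaf = 3L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    idx <- sample(n, n, replace = TRUE)
    cart_tree(x[idx, , drop = FALSE], y[idx], max_depth = max_depth,
              min_split = min_split, min_leaf = min_leaf, mtry = mtry,
              seed = sample.int(.Machine$integer.max, 1))
  }))
  structure(list(trees = trees), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  votes <- vapply(object$trees, function(tr)
    as.numeric(predict(tr, newdata) >= 0.5), numeric(nrow(as.matrix(newdata))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' Gradient-boosted trees with logistic loss and Newton leaf values
#'
#' Stagewise additive model on the logit scale: at each round a CART tree is
#' fitted to the Newton pseudo-residuals `(y - p) / h` with hessian weights
#' `h = p(1-p)`, so each leaf's weighted mean is the Newton step
#' `sum(y - p) / sum(h)`. `min_split_loss` gates splits on their gain.
#'
#' @param x numeric feature matrix; @param y 0/1 labels.
#' @param n_rounds boosting rounds; @param eta shrinkage.
#' @param max_depth tree depth; @param min_split_loss minimum split gain.
#' @param max_delta_step cap on per-leaf steps (0 = no cap).
#' @param seed RNG seed.
#' @return object of class `gbt_model`.
#' @keywords internal
gradient_boost <- function(x, y, n_rounds = 100L, eta = 0.3, max_depth = 5L,
                           min_split_loss = 0.001, max_delta_step = 0,
                           seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  f0 <- log(max(mean(y), 1e-10) / max(1 - mean(y), 1e-10))
  fx <- rep(f0, n)
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    p <- sigmoid(fx)
    h <- pmax(p * (1 - p), 1e-10)
    z <- (y - p) / h
    tr <- cart_tree(x, z, w = h, max_depth = max_depth, min_split = 2L,
                    min_leaf = 1L, min_gain = min_split_loss,
                    seed = seed + m)
    step <- predict(tr, x)
    if (max_delta_step > 0)
      step <- pmin(pmax(step, -max_delta_step), max_delta_step)
    fx <- fx + eta * step
    trees[[m]] <- tr
  }
  structure(list(f0 = f0, eta = eta, trees = trees,
                 max_delta_step = max_delta_step), class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  fx <- rep(object$f0, nrow(newdata))
  for (tr in object$trees) {
    step <- predict(tr, newdata)
    if (object$max_delta_step > 0)
      step <- pmin(pmax(step, -object$max_delta_step), object$max_delta_step)
    fx <- fx + object$eta * step
  }
  sigmoid(fx)
}
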