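#' Isolation forest anomaly scores
#'
#' Isolation-tree ensemble: each tree is grown on a random sub-sample by
#' recursively splitting a randomly chosen feature at a uniformly random value
#' between the in-node minimum and maximum, until isolation or a depth limit
#' of `ceiling(log2(psi))`. Points that isolate early (short mean path length
#' `E[h]`) are anomalous; the score is `2^(-E[h]/c(psi))` with `c(n)` the
#' expected path length of an unsuccessful BST search, so scores near 1 flag
#' outliers.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_trees number of isolation trees (default 100).
#' @param sample_size sub-sample size per tree (default `min(256, n)`).
#' @param seed RNG seed.
#' @return numeric vector of anomaly scores in (0, 1), one per row.
#' @export
isolation_forest_score <- function(x, n_trees = 100, sample_size = NULL,
                                   seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size %||% 256L, n)
  depth_limit <- ceiling(log2(max(psi, 2)))
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      idx <- sample(n, psi)
      .grow_itree(x[idx, , drop = FALSE], 0L, depth_limit)
    })
    paths <- vapply(trees, function(tr) .itree_paths(tr, x), numeric(n))
    if (n == 1L) paths <- matrix(paths, nrow = 1L)
    eh <- rowMeans(paths)
    2^(-eh / .avg_path(psi))
  })
}

# expected path length of unsuccessful search in a BST of n points
.avg_path <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

.grow_itree <- function(x, depth, limit) {
  n <- nrow(x)
  if (n <= 1L || depth >= limit)
    return(list(leaf = TRUE, size = n))
  rng <- apply(x, 2, range)
  usable <- which(rng[1, ] < rng[2, ])
  if (!length(usable)) return(list(leaf = TRUE, size = n))
  j <- if (length(usable) == 1L) usable else sample(usable, 1L)
  sv <- runif(1, rng[1, j], rng[2, j])
  left <- x[, j] < sv
  list(leaf = FALSE, feature = j, split = sv,
       left = .grow_itree(x[left, , drop = FALSE], depth + 1L, limit),
       right = .grow_itree(x[!left, , drop = FALSE], depth + 1L, limit))
}

.itree_paths <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, idx, depth) {
    if (!length(idx)) return(invisible())
    if (node$leaf) {
      out[idx] <<- depth + .avg_path(node$size)
      return(invisible())
    }
    left <- x[idx, node$feature] < node$split
    recurse(node$left, idx[left], depth + 1)
    recurse(node$right, idx[!left], depth + 1)
  }
  recurse(tree, seq_len(nrow(x)), 0)
  out
}
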