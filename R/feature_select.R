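#' Per-method feature rankings
#'
#' Each ranker scores every eligible feature on its native scale and returns
#' a full ranking, best first. Constant features score 0 and rank last. Ties
#' within a ranking break by schema column position (stable, deterministic).
#' One-hot encoded categorical columns are aggregated back to their original
#' column name (max score for the correlation-style methods, summed score for
#' the additive chi-squared/tree/lasso importances).
#'
#' Methods: `pearson` = |corr(feature, label)|; `anova` = between/within class
#' F statistic; `chi2` = chi-squared statistic of the label against the
#' feature after equal-frequency binning of continuous features; `rfe` =
#' recursive feature elimination order under a re-fit L2-regularised logistic
#' classifier (last eliminated = rank 1); `lasso` = |coefficient| of an
#' L1-penalised logistic fit on standardized features; `tree` =
#' impurity-decrease importance of a depth-limited decision tree.
#'
#' @param ds a preprocessed [tabular_dataset()] (no missing cells).
#' @param n_bins equal-frequency bins for continuous features (chi2 ranker).
#' @param penalty L1 penalty (glmnet lambda) for the lasso ranker; `NULL`
#'   selects it by seeded 5-fold cross-validation.
#' @param seed seed for the cross-validated penalty choice / tree fits.
#' @return object of class `feature_ranking` with fields `method`,
#'   `ranked_features`, `scores` (aligned with `ranked_features`) and
#'   `candidates` (schema order, used for tie-breaks).
#' @name rankers
NULL

.make_ranking <- function(method, scores, candidates) {
  stopifnot(length(scores) == length(candidates))
  scores[!is.finite(scores)] <- 0
  ord <- order_desc_stable(scores)
  structure(list(method = method,
                 ranked_features = candidates[ord],
                 scores = scores[ord],
                 candidates = candidates),
            class = "feature_ranking")
}

# aggregate encoded-column scores to original feature names
.aggregate_scores <- function(scores, origin, candidates, how = c("max", "sum")) {
  how <- match.arg(how)
  agg <- vapply(candidates, function(f) {
    s <- scores[origin == f]
    if (!length(s)) 0 else if (how == "max") max(s) else sum(s)
  }, numeric(1))
  unname(agg)
}

.ranking_inputs <- function(ds) {
  x <- feature_matrix(ds)
  if (nrow(x) < 10) abort("ranking requires n >= 10 rows", "data_error")
  if (anyNA(x)) abort("ranking requires a fully imputed dataset", "data_error")
  list(x = x, y = dataset_labels(ds), origin = attr(x, "origin"),
       candidates = feature_names(ds$schema))
}

#' @rdname rankers
#' @export
rank_pearson <- function(ds) {
  inp <- .ranking_inputs(ds)
  sc <- abs(suppressWarnings(cor(inp$x, inp$y)))[, 1]
  sc[is.na(sc)] <- 0
  .make_ranking("pearson",
                .aggregate_scores(sc, inp$origin, inp$candidates, "max"),
                inp$candidates)
}

#' @rdname rankers
#' @export
rank_anova <- function(ds) {
  inp <- .ranking_inputs(ds)
  y <- inp$y
  sc <- apply(inp$x, 2, function(v) {
    g0 <- v[y == 0]; g1 <- v[y == 1]
    n0 <- length(g0); n1 <- length(g1); n <- n0 + n1
    gm <- mean(v)
    between <- n0 * (mean(g0) - gm)^2 + n1 * (mean(g1) - gm)^2
    within <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
    if (within == 0) { if (between == 0) 0 else Inf }
    else (between / 1) / (within / (n - 2))
  })
  .make_ranking("anova",
                .aggregate_scores(sc, inp$origin, inp$candidates, "max"),
                inp$candidates)
}

#' @rdname rankers
#' @export
rank_chi2 <- function(ds, n_bins = 5) {
  inp <- .ranking_inputs(ds)
  y <- inp$y
  feats <- inp$candidates
  sc <- vapply(feats, function(f) {
    cs <- schema_col(ds$schema, f)
    v <- ds$data[[f]]
    if (cs$type == "numeric_continuous") {
      br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
      if (length(br) < 2) return(0)
      v <- cut(v, breaks = br, include.lowest = TRUE)
    }
    tab <- table(v, y)
    if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }, numeric(1))
  .make_ranking("chi2_binned", unname(sc), feats)
}

#' @rdname rankers
#' @export
rank_rfe <- function(ds) {
  inp <- .ranking_inputs(ds)
  x <- scale(inp$x)
  x[is.nan(x)] <- 0
  y <- inp$y
  p <- ncol(x)
  remaining <- seq_len(p)
  elim_round <- integer(p)        # round at which each column was eliminated
  for (round in seq_len(p - 1)) {
    fit <- ridge_logistic(x[, remaining, drop = FALSE], y, alpha = 1e-2)
    cf <- abs(fit$beta)
    drop_j <- remaining[order(cf, seq_along(cf))[1]]
    elim_round[drop_j] <- round
    remaining <- setdiff(remaining, drop_j)
  }
  elim_round[remaining] <- p      # survivor: eliminated last
  constant <- apply(inp$x, 2, function(v) var(v) == 0)
  elim_round[constant] <- 0       # contract: constant features score 0
  .aggregate_scores(elim_round, inp$origin, inp$candidates, "max") |>
    .make_ranking(method = "rfe", candidates = inp$candidates)
}

#' @rdname rankers
#' @export
rank_lasso <- function(ds, penalty = NULL, seed = 1L) {
  inp <- .ranking_inputs(ds)
  x <- inp$x
  y <- inp$y
  if (is.null(penalty)) {
    foldid <- with_seed(seed, sample(rep_len(1:5, nrow(x))))
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               standardize = TRUE, foldid = foldid)
    penalty <- cvfit$lambda.min
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = TRUE, lambda = penalty)
  sc <- abs(as.numeric(fit$beta))
  .make_ranking("lasso",
                .aggregate_scores(sc, inp$origin, inp$candidates, "sum"),
                inp$candidates)
}

#' @rdname rankers
#' @export
rank_tree <- function(ds, seed = 1L) {
  inp <- .ranking_inputs(ds)
  fit <- cart_tree(inp$x, inp$y, max_depth = 5L, min_split = 10L,
                   min_leaf = 3L, seed = seed)
  .make_ranking("tree",
                .aggregate_scores(fit$importance, inp$origin, inp$candidates,
                                  "sum"),
                inp$candidates)
}

#' Vote for the top-x common features across rankings
#'
#' Implements rank-aggregation voting: take each method's top-`x` list,
#' intersect them, and order the intersection by mean rank across methods.
#' When the intersection falls short of `x` (disjoint tops), the shortfall is
#' filled Borda-style with the lowest mean-rank features not already included;
#' the completion is recorded in `fill_in`.
#'
#' @param rankings non-empty list of `feature_ranking` objects over the same
#'   candidate set.
#' @param x number of features to select, `1 <= x <= n_features`.
#' @return object of class `selection_result` with `selected` (length `x`),
#'   `per_method`, `intersection`, `fill_in` (data frame of completion
#'   features and their mean ranks), `mean_ranks`.
#' @export
vote_top_features <- function(rankings, x) {
  if (!length(rankings)) abort("empty rankings list", "argument_error")
  candidates <- rankings[[1]]$candidates
  for (r in rankings)
    if (!setequal(r$candidates, candidates))
      abort("rankings cover different candidate sets", "argument_error")
  if (x < 1 || x > length(candidates))
    abort("x must lie in [1, n_features]", "argument_error")
  rank_of <- vapply(rankings, function(r)
    match(candidates, r$ranked_features), integer(length(candidates)))
  if (length(candidates) == 1L) rank_of <- matrix(rank_of, nrow = 1L)
  mean_rank <- rowMeans(rank_of)
  names(mean_rank) <- candidates
  tops <- lapply(rankings, function(r) r$ranked_features[seq_len(x)])
  inter <- Reduce(intersect, tops)
  borda_order <- candidates[order(mean_rank, seq_along(candidates))]
  selected <- inter[order(mean_rank[inter], match(inter, candidates))]
  fill <- character(0)
  if (length(selected) < x)
    fill <- setdiff(borda_order, selected)[seq_len(x - length(selected))]
  structure(list(selected = c(selected, fill),
                 per_method = rankings,
                 intersection = inter,
                 fill_in = data.frame(feature = fill,
                                      mean_rank = unname(mean_rank[fill])),
                 mean_ranks = mean_rank,
                 x = x),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> x = %d, methods: %s\n", x$x,
              paste(vapply(x$per_method, `[[`, "", "method"), collapse = ", ")))
  cat("  selected    :", paste(x$selected, collapse = ", "), "\n")
  cat("  intersection:", paste(x$intersection, collapse = ", "), "\n")
  if (nrow(x$fill_in))
    cat("  fill-in     :", paste(x$fill_in$feature, collapse = ", "), "\n")
  invisible(x)
}

#' Hybrid voting feature selection
#'
#' Runs the requested rankers simultaneously on the dataset and votes for the
#' top-`x` common features. The default method set is the five-method hybrid
#' \{pearson, anova, rfe, lasso, tree\}; `chi2_binned` is available on
#' request. Identifier columns are excluded by schema typing before ranking.
#'
#' @param ds a preprocessed [tabular_dataset()].
#' @param x number of features to select.
#' @param methods subset of
#'   `c("pearson", "anova", "chi2_binned", "rfe", "lasso", "tree")`.
#' @param n_bins,penalty,seed passed to the respective rankers.
#' @return a `selection_result` (see [vote_top_features()]).
#' @export
select_features <- function(ds, x,
                            methods = c("pearson", "anova", "rfe", "lasso", "tree"),
                            n_bins = 5, penalty = NULL, seed = 1L) {
  all_m <- c("pearson", "anova", "chi2_binned", "rfe", "lasso", "tree")
  methods <- match.arg(methods, all_m, several.ok = TRUE)
  rankings <- lapply(methods, function(m) switch(m,
    pearson = rank_pearson(ds),
    anova = rank_anova(ds),
    chi2_binned = rank_chi2(ds, n_bins = n_bins),
    rfe = rank_rfe(ds),
    lasso = rank_lasso(ds, penalty = penalty, seed = seed),
    tree = rank_tree(ds, seed = seed)))
  vote_top_features(rankings, x)
}
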