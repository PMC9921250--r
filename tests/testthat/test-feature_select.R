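# independent oracle: set intersection of top-x lists + Borda completion
oracle_vote <- function(rankings, x) {
  candidates <- rankings[[1]]$candidates
  rank_of <- sapply(rankings, function(r) match(candidates, r$ranked_features))
  if (length(candidates) == 1L) rank_of <- matrix(rank_of, nrow = 1)
  mean_rank <- rowMeans(rank_of)
  tops <- lapply(rankings, function(r) r$ranked_features[seq_len(x)])
  inter <- candidates
  for (tp in tops) inter <- inter[inter %in% tp]
  sel <- inter[order(mean_rank[match(inter, candidates)], match(inter, candidates))]
  pool <- candidates[order(mean_rank, seq_along(candidates))]
  while (length(sel) < x) {
    nxt <- pool[!pool %in% sel][1]
    sel <- c(sel, nxt)
  }
  sel
}

fake_ranking <- function(perm, candidates)
  structure(list(method = "fake", ranked_features = perm,
                 scores = rev(seq_along(perm)), candidates = candidates),
            class = "feature_ranking")

test_that("single planted feature ranks first under pearson", {
  b <- planted_signal_benchmark(1, 3, 1000, seed = 3)
  r <- rank_pearson(b$dataset)
  expect_identical(r$ranked_features[1], b$truth)
  # oracle: exhaustive correlation computation
  x <- feature_matrix(b$dataset)
  cors <- abs(cor(x, dataset_labels(b$dataset)))[, 1]
  expect_equal(r$scores, unname(sort(cors, decreasing = TRUE)),
               tolerance = 1e-12)
})

test_that("a feature identical to the label has pearson score 1", {
  set.seed(5)
  y <- rep(0:1, 25)
  ds <- toy_dataset(cbind(y, rnorm(50), rnorm(50)), y)
  r <- rank_pearson(ds)
  expect_identical(r$ranked_features[1], "f1")
  expect_equal(r$scores[1], 1)
})

test_that("constant features rank last in all six methods", {
  set.seed(6)
  y <- rep(0:1, 40)
  ds <- toy_dataset(cbind(rnorm(80) + y, rnorm(80), rep(3, 80)), y)
  rankings <- list(rank_pearson(ds), rank_anova(ds), rank_chi2(ds),
                   rank_rfe(ds), rank_lasso(ds, penalty = 0.05),
                   rank_tree(ds))
  for (r in rankings) {
    expect_identical(r$ranked_features[3], "f3", label = r$method)
    expect_equal(r$scores[3], 0, label = r$method)
  }
})

test_that("every ranker returns a full permutation with aligned scores", {
  b <- planted_signal_benchmark(3, 4, 300, seed = 9)
  feats <- feature_names(b$dataset$schema)
  rankers <- list(rank_pearson, rank_anova, rank_chi2, rank_rfe,
                  function(d) rank_lasso(d, penalty = 0.02), rank_tree)
  for (rk in rankers) {
    r <- rk(b$dataset)
    expect_setequal(r$ranked_features, feats)
    expect_length(r$scores, length(feats))
    expect_true(all(diff(r$scores) <= 1e-12))   # best first
  }
})

test_that("vote_top_features handles unanimity and boundaries", {
  cand <- paste0("f", 1:6)
  same <- fake_ranking(cand, cand)
  res <- vote_top_features(list(same, same, same, same, same), 3)
  expect_identical(res$selected, cand[1:3])
  expect_identical(sort(res$intersection), sort(cand[1:3]))
  expect_equal(nrow(res$fill_in), 0)
  # x = n_features selects everything
  res_all <- vote_top_features(list(same, same), 6)
  expect_setequal(res_all$selected, cand)
  expect_error_class(vote_top_features(list(), 2), "argument_error")
  expect_error_class(vote_top_features(list(same), 9), "argument_error")
})

test_that("hand-built ranking triple equals the enumeration oracle", {
  cand <- paste0("f", 1:6)
  r1 <- fake_ranking(c("f1", "f2", "f3", "f4", "f5", "f6"), cand)
  r2 <- fake_ranking(c("f2", "f3", "f6", "f1", "f5", "f4"), cand)
  r3 <- fake_ranking(c("f3", "f5", "f2", "f6", "f4", "f1"), cand)
  res <- vote_top_features(list(r1, r2, r3), 3)
  # top-3 lists: {f1,f2,f3}, {f2,f3,f6}, {f3,f5,f2}; intersection {f2,f3}
  expect_setequal(res$intersection, c("f2", "f3"))
  expect_identical(res$selected, oracle_vote(list(r1, r2, r3), 3))
  expect_equal(nrow(res$fill_in), 1)
})

test_that("voting is permutation-invariant and always returns x features", {
  set.seed(31)
  cand <- paste0("f", 1:6)
  for (i in 1:25) {
    rks <- lapply(1:3, function(j) fake_ranking(sample(cand), cand))
    for (x in 1:6) {
      res <- vote_top_features(rks, x)
      expect_length(res$selected, x)
      expect_true(all(res$intersection %in% res$selected))
      shuffled <- vote_top_features(rev(rks), x)
      expect_identical(res$selected, shuffled$selected)
      expect_identical(res$selected, oracle_vote(rks, x))
    }
  }
})

test_that("select_features defaults to the five-method hybrid", {
  b <- planted_signal_benchmark(2, 2, 200, seed = 12)
  sel <- select_features(b$dataset, x = 2, penalty = 0.02)
  expect_length(sel$per_method, 5)
  expect_setequal(vapply(sel$per_method, `[[`, "", "method"),
                  c("pearson", "anova", "rfe", "lasso", "tree"))
  # boundary: x = n_features
  sel_all <- select_features(b$dataset, x = 4, penalty = 0.02)
  expect_setequal(sel_all$selected, feature_names(b$dataset$schema))
})

test_that("rankings and voting are deterministic under a fixed seed", {
  b <- planted_signal_benchmark(3, 3, 250, seed = 8)
  s1 <- select_features(b$dataset, x = 3, seed = 5)
  s2 <- select_features(b$dataset, x = 3, seed = 5)
  expect_identical(s1$selected, s2$selected)
})
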