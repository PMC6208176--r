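test_that("feature trees validate structure and number localities", {
  tr <- feature_tree(ft_split(1, 0, ft_feature(2, ft_leaf()), ft_leaf()), 3)
  expect_equal(tr$n_localities, 2)
  expect_error(
    feature_tree(ft_feature(2, ft_feature(2, ft_leaf())), 3),
    "repeated"
  )
  expect_error(feature_tree(ft_feature(9, ft_leaf()), 3), "out of range")
})

test_that("locality assignment accumulates path feature nodes", {
  lone <- feature_tree(ft_leaf(), 4)
  a <- assign_locality(lone, c(1, 2, 3, 4))
  expect_equal(a$locality, 1)
  expect_length(a$features, 0)
  # a feature node above a split belongs to both localities (compound
  # locality sharing)
  tr <- feature_tree(ft_feature(3, ft_split(1, 0.5,
                                            ft_feature(2, ft_leaf()),
                                            ft_leaf())), 4)
  left <- assign_locality(tr, c(0, 9, 9, 9))
  right <- assign_locality(tr, c(1, 9, 9, 9))
  expect_true(3 %in% left$features)
  expect_true(3 %in% right$features)
  expect_equal(left$features, c(3L, 2L))
  expect_equal(right$features, 3L)
})

test_that("tree routing of many samples equals brute-force routing", {
  set.seed(20)
  for (rep in 1:5) {
    tr <- random_tree(6, depth = 3)
    X <- matrix(rnorm(100 * 6), 100)
    for (i in 1:100) {
      a <- assign_locality(tr, X[i, ])
      b <- oracle_route(tr$root, X[i, ])
      expect_equal(a$locality, b$leaf)
      expect_equal(a$features, b$features)
    }
  }
})

test_that("tree score matches the exhaustive oracle and its bounds", {
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(score_tree(feature_tree(ft_leaf(), 2), X, rep("a", 20), 3), 1)
  X2 <- matrix(c(0, 1), 2, 1)
  expect_equal(score_tree(feature_tree(ft_leaf(), 1), X2, c("a", "b"), 1), 0)
  for (rep in 1:10) {
    tr <- random_tree(5, depth = 3)
    X <- matrix(rnorm(20 * 5), 20)
    y <- sample(c("a", "b"), 20, replace = TRUE)
    k <- sample(1:4, 1)
    s <- score_tree(tr, X, y, k)
    expect_equal(s, oracle_score(tr, X, y, k))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("localities partition the training set", {
  set.seed(22)
  tr <- random_tree(5, depth = 3)
  X <- matrix(rnorm(60 * 5), 60)
  part <- emofuse:::tree_partition(tr, X)
  expect_true(all(part$locality >= 1 & part$locality <= tr$n_localities))
  expect_equal(length(part$locality), 60)
})

test_that("degenerate search returns the single-leaf tree", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4), 30)
  y <- sample(c("a", "b"), 30, replace = TRUE)
  res <- search_feature_tree(X, y, k = 3, budget = 1, max_depth = 0, seed = 1)
  expect_equal(res$tree$n_localities, 1)
  expect_equal(res$score, score_tree(feature_tree(ft_leaf(), 4), X, y, 3))
})

test_that("search never scores below the single-leaf baseline", {
  set.seed(24)
  for (rep in 1:10) {
    X <- matrix(rnorm(40 * 5), 40)
    y <- sample(c("a", "b"), 40, replace = TRUE)
    res <- search_feature_tree(X, y, k = 3, budget = 30, max_depth = 3,
                               seed = rep)
    expect_gte(res$score, res$baseline)
  }
})

test_that("search is deterministic given the seed", {
  tbl <- generate_local_feature_table(80, 8, 5, left = 1, right = 2, seed = 30)
  X <- as.matrix(tbl[, paste0("f", 1:8)])
  r1 <- search_feature_tree(X, tbl$label, budget = 60, seed = 99)
  r2 <- search_feature_tree(X, tbl$label, budget = 60, seed = 99)
  expect_identical(r1$tree, r2$tree)
  expect_identical(r1$score, r2$score)
})

test_that("two-locality subsets have the requested size and recover structure", {
  tbl <- generate_local_feature_table(150, 12, 11, left = c(1, 2),
                                      right = c(3, 4), seed = 31)
  ft <- tbl[, paste0("f", 1:12)]
  ft$arousal <- ifelse(tbl$label == "A", 8, 2)
  # valence labels from an independent planted rule on the same features
  tbl2 <- generate_local_feature_table(150, 12, 12, left = c(5, 6),
                                       right = c(7, 8), seed = 31)
  ft$valence <- ifelse(tbl2$label == "A", 8, 2)
  ft$quarter <- quadrant_label(ft$arousal, ft$valence)
  subs <- two_locality_subsets(ft, k = 3, budget = 100, n_keep = 4, seed = 1)
  expect_length(subs$arousal, 4)
  expect_length(subs$valence, 4)
  expect_gt(length(intersect(subs$arousal, paste0("f", c(1, 2, 11)))), 0)
  # n_keep >= F returns everything with a warning
  small <- ft[, c("f1", "f2", "arousal", "valence", "quarter")]
  expect_warning(
    all_feats <- two_locality_subsets(small, k = 3, budget = 20, n_keep = 10,
                                      seed = 1),
    "fewer"
  )
  expect_setequal(all_feats$arousal, c("f1", "f2"))
})

test_that("feature trees serialize to JSON and back", {
  tr <- feature_tree(ft_feature(2, ft_split(1, 0.25,
                                            ft_leaf(), ft_feature(3, ft_leaf()))), 4)
  js <- tree_to_json(tr)
  back <- tree_from_json(js)
  expect_equal(back, tr)
  x <- c(0.1, 9, 9, 9)
  expect_equal(assign_locality(back, x), assign_locality(tr, x))
})
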