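# Gain-ratio tree induction: information measures, split selection vs the
# exhaustive oracle, growth, pessimistic pruning, prediction, serialization.

test_that("entropy, info_gain and split_info match hand values and oracle", {
  expect_equal(entropy(c(5, 5)), 1.0)
  expect_equal(entropy(c(10, 0)), 0.0)
  expect_equal(entropy(c(9, 5)), 0.9403, tolerance = 1e-4)
  expect_error(entropy(c(0, 0)), "zero")

  expect_equal(info_gain(c(9, 5), list(c(2, 3), c(4, 0), c(3, 2))),
               0.2467, tolerance = 1e-3)
  expect_equal(info_gain(c(6, 4), list(c(3, 2), c(3, 2))), 0)
  expect_equal(info_gain(c(9, 5), list(c(9, 0), c(0, 5))), entropy(c(9, 5)))
  expect_error(info_gain(c(9, 5), list(c(2, 3), c(4, 1))), "sum to parent")

  expect_equal(split_info(c(7, 7)), 1.0)
  expect_equal(split_info(c(5, 4, 5)), 1.577, tolerance = 1e-3)
  expect_error(split_info(c(14)), "two children")
  # monotone decrease toward 0 as the split gets more lopsided
  si <- vapply(c(10, 100, 1000), function(n) split_info(c(1, n - 1)),
               numeric(1))
  expect_true(all(diff(si) < 0))

  set.seed(14)
  for (rep in 1:50) {
    counts <- sample(0:20, sample(2:5, 1), replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(entropy(counts), oracle_entropy(counts), tolerance = 1e-12)
    sizes <- sample(1:30, sample(2:4, 1), replace = TRUE)
    expect_equal(split_info(sizes), oracle_split_info(sizes),
                 tolerance = 1e-12)
  }
})

test_that("best_split handles the trivial and degenerate cases", {
  ft <- separable_table(20, seed = 2)
  sp <- best_split(feature_matrix(ft), ft$label)
  expect_equal(sp$feature, "sig")
  expect_equal(sp$info_gain, 1.0) # parent entropy of a balanced 2-class node
  expect_equal(sp$gain_ratio, sp$info_gain / sp$split_info)

  const <- feature_table(matrix(1, 20, 3,
                                dimnames = list(NULL, c("a", "b", "c"))),
                         label = rep(c("x", "y"), 10))
  expect_null(best_split(feature_matrix(const), const$label))
  expect_error(best_split(feature_matrix(ft), ft$label, character(0)),
               "empty feature set")
})

test_that("best_split agrees with the exhaustive oracle on random tables", {
  # smaller replicate of the full 200-table acceptance check
  for (s in 1:40) {
    set.seed(s)
    ft <- random_table(sample(5:50, 1), sample(1:6, 1), sample(2:3, 1),
                       seed = s)
    x <- feature_matrix(ft)
    got <- best_split(x, ft$label, config = tree_config(min_leaf = 1))
    want <- oracle_best_split(x, ft$label)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
    }
  }
})

test_that("gain ratio is invariant under duplicating every row", {
  set.seed(77)
  ft <- random_table(30, 4, 2, seed = 77)
  x <- feature_matrix(ft)
  cfg <- tree_config(min_leaf = 1) # so duplication cannot alter candidates
  s1 <- best_split(x, ft$label, config = cfg)
  s2 <- best_split(rbind(x, x), c(ft$label, ft$label), config = cfg)
  expect_equal(s1$gain_ratio, s2$gain_ratio, tolerance = 1e-12)
  expect_equal(s1$feature, s2$feature)
  expect_equal(s1$threshold, s2$threshold)
})

test_that("grow_tree stopping rules and training-error property hold", {
  pure <- feature_table(matrix(rnorm(20), 10, 2,
                               dimnames = list(NULL, c("u", "v"))),
                        label = rep("only", 10))
  tr <- grow_tree(pure)
  expect_true(tr$root$leaf)

  sep <- separable_table(25, seed = 3)
  tr2 <- grow_tree(sep)
  expect_false(tr2$root$leaf)
  expect_true(tr2$root$left$leaf && tr2$root$right$leaf) # depth-1 tree
  expect_equal(tree_train_error(tr2, sep), 0)

  unl <- feature_table(matrix(rnorm(10), 5, 2))
  expect_error(grow_tree(unl), "label")

  # unpruned training error never exceeds the majority-vote error
  for (s in 1:20) {
    ft <- random_table(sample(10:40, 1), sample(2:5, 1), sample(2:3, 1),
                       seed = 100 + s)
    tr <- grow_tree(ft)
    expect_lte(tree_train_error(tr, ft), majority_error(ft$label) + 1e-12)
  }
})

test_that("pessimistic pruning shrinks spurious trees and never raises the
          error bound", {
  shrunk <- 0
  for (s in 1:25) {
    set.seed(s)
    ft <- random_table(80, 4, 2, seed = 300 + s, integer_features = FALSE)
    tr <- grow_tree(ft)
    pr <- prune_tree(tr)
    expect_lte(tree_size(pr), tree_size(tr))
    expect_lte(tree_pessimistic_error(pr), tree_pessimistic_error(tr) + 1e-9)
    if (tree_size(pr) < tree_size(tr)) shrunk <- shrunk + 1
  }
  expect_gt(shrunk / 25, 0.9)

  # confident splits on separable data survive pruning
  sep <- separable_table(40, seed = 5)
  tr <- grow_tree(sep)
  pr <- prune_tree(tr)
  expect_equal(tree_size(pr), tree_size(tr))
  expect_equal(tree_train_error(pr, sep), 0)
})

test_that("predict_tree routes, normalizes and reproduces training labels", {
  sep <- separable_table(15, seed = 8)
  tr <- grow_tree(sep)
  p <- predict_tree(tr, sep)
  expect_equal(p$label, sep$label)
  expect_equal(unname(rowSums(p$prob)), rep(1, nrow(sep)))

  leaf_only <- grow_tree(feature_table(
    matrix(0, 6, 1, dimnames = list(NULL, "z")),
    label = c(rep("a", 4), rep("b", 2))))
  expect_true(leaf_only$root$leaf)
  p2 <- predict_tree(leaf_only, matrix(5, 3, 1, dimnames = list(NULL, "z")))
  expect_equal(p2$label, rep("a", 3))
  expect_equal(p2$prob[1, ], c(a = 4 / 6, b = 2 / 6))

  expect_error(predict_tree(tr, matrix(0, 2, 1,
                                       dimnames = list(NULL, "other"))),
               "missing feature")

  # continuous features and singleton leaves allowed: unpruned trees grow to
  # pure leaves and reproduce their training labels
  for (s in 1:10) {
    ft <- random_table(30, 5, 2, seed = 400 + s, integer_features = FALSE)
    tr <- grow_tree(ft, config = tree_config(min_leaf = 1))
    expect_equal(predict_tree(tr, ft)$label, ft$label)
  }
})

test_that("tree JSON serialization round-trips losslessly", {
  ft <- random_table(40, 4, 3, seed = 55)
  tr <- prune_tree(grow_tree(ft))
  js <- tree_to_json(tr)
  tr2 <- tree_from_json(js)
  expect_equal(tr2$classes, tr$classes)
  expect_equal(predict_tree(tr2, ft), predict_tree(tr, ft))
  expect_equal(tree_size(tr2), tree_size(tr))
  f <- tempfile(fileext = ".json")
  tree_to_json(tr, f)
  expect_equal(predict_tree(tree_from_json(f), ft)$label,
               predict_tree(tr, ft)$label)
})
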