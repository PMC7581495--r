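test_that("forest separates a toy problem and is seed-deterministic", {
  toy <- toy_forest_data()
  f <- train_forest(toy$x, toy$y, n_trees = 50, seed = 7)
  expect_equal(mean(predict_class(f, toy$x) == toy$y), 1)

  f2 <- train_forest(toy$x, toy$y, n_trees = 50, seed = 7)
  expect_identical(f$trees, f2$trees)
  f3 <- train_forest(toy$x, toy$y, n_trees = 50, seed = 8)
  expect_false(identical(f$trees, f3$trees))

  expect_error(train_forest(toy$x, rep("a", nrow(toy$x))),
               class = "histoprox_contract_error")
})

test_that("training tolerates missing covariates and routes them deterministically", {
  toy <- toy_forest_data()
  xm <- toy$x
  xm[seq(1, nrow(xm), by = 5), 3] <- NA     # MISSING tissue-like column
  f <- train_forest(xm, toy$y, n_trees = 50, seed = 1)
  expect_s3_class(f, "hp_forest")
  # identical records with missing values land in identical leaves
  li <- leaf_index(f, xm[c(1, 1), , drop = FALSE])
  expect_equal(li[1, ], li[2, ])
})

test_that("leaf identity matches a hand-traced depth-3 tree", {
  # hand-built tree: x1 < 0 -> (x2 < 0 -> leafA | leafB); x1 >= 0 -> leafC
  tree <- list(feature = c(0L, 1L, -1L, -1L, -1L),
               threshold = c(0, 0, 0, 0, 0),
               left = c(1L, 3L, -1L, -1L, -1L),
               right = c(2L, 4L, -1L, -1L, -1L),
               majority = c(0L, 1L, 0L, 0L, 0L),
               pred = c(0L, 0L, 1L, 0L, 1L),
               counts = matrix(0, 5, 2))
  forest <- structure(list(trees = list(tree), n_trees = 1L, mtry = 1L,
                           min_node = 1L, seed = 0L, classes = c("a", "b"),
                           feature_names = c("x1", "x2")),
                      class = "hp_forest")
  # exhaustive path-trace oracle in R
  trace_oracle <- function(x1, x2) {
    if (is.na(x1)) x1 <- -1                       # root majority branch: left
    if (x1 > 0) return(2L)
    if (is.na(x2)) return(4L)                     # node-1 majority -> right
    if (x2 <= 0) return(3L) else return(4L)
  }
  cases <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(0.5, 2), c(NA, 0), c(-1, NA))
  got <- leaf_index(forest, cases)
  want <- vapply(seq_len(nrow(cases)),
                 function(i) trace_oracle(cases[i, 1], cases[i, 2]), integer(1))
  expect_equal(as.vector(got), want)
})

test_that("activations are tree-vote fractions that sum to one", {
  toy <- toy_forest_data()
  f <- train_forest(toy$x, toy$y, n_trees = 10, seed = 2)
  a <- predict_activations(f, toy$x)
  expect_equal(rowSums(a), rep(1, nrow(a)))
  expect_true(all(a >= 0))
  # oracle: recompute the vote histogram from per-tree leaf predictions
  li <- leaf_index(f, toy$x[1:5, , drop = FALSE])
  votes <- vapply(seq_len(f$n_trees), function(t) {
    f$trees[[t]]$pred[li[, t] + 1L]
  }, integer(5))
  byhand <- t(apply(votes, 1, function(v) tabulate(v + 1L, 2L) / f$n_trees))
  expect_equal(unname(a[1:5, ]), byhand)
})

test_that("proximity is a bounded symmetric co-leaf count, maximal at identity", {
  toy <- toy_forest_data(n = 60)
  f <- train_forest(toy$x, toy$y, n_trees = 120, seed = 5)
  x <- toy$x
  expect_equal(proximity(f, x[1, , drop = FALSE], x[1, , drop = FALSE]), 120L)
  for (i in 2:8) {
    pij <- proximity(f, x[1, , drop = FALSE], x[i, , drop = FALSE])
    pji <- proximity(f, x[i, , drop = FALSE], x[1, , drop = FALSE])
    expect_identical(pij, pji)
    expect_true(pij >= 0L && pij <= 120L)
    expect_lte(pij, proximity(f, x[1, , drop = FALSE], x[1, , drop = FALSE]))
  }
  # 3-tree hand-assigned forest: records co-leafed in exactly 2 trees
  lt <- function(leafA, leafB) list(
    feature = c(0L, -1L, -1L), threshold = c(0, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    majority = c(0L, 0L, 0L), pred = c(0L, 0L, 1L),
    counts = matrix(0, 3, 2))
  f3 <- structure(list(trees = list(lt(), lt(), lt()), n_trees = 3L,
                       mtry = 1L, min_node = 1L, seed = 0L,
                       classes = c("a", "b"), feature_names = "x1"),
                  class = "hp_forest")
  # same side in trees 1..3 depends only on sign; co-leafed in all 3 or 0
  expect_equal(proximity(f3, matrix(-1), matrix(-2)), 3L)
  expect_equal(proximity(f3, matrix(-1), matrix(2)), 0L)
  # mixed forest: flip one tree's threshold so exactly 2 trees agree
  f3$trees[[2]]$threshold <- c(-1.5, 0, 0)
  expect_equal(proximity(f3, matrix(-1), matrix(-2)), 2L)
})

test_that("permutation importance isolates the informative feature", {
  # 1-informative-feature fixture
  withr::with_seed(0, {
    n <- 150
    y <- sample(rep(c("a", "b"), n / 2))
    x <- cbind(info = ifelse(y == "a", 1, -1) + rnorm(n, 0, 0.3),
               noise1 = rnorm(n), noise2 = rnorm(n), const = rep(1, n))
  })
  f <- train_forest(x[1:100, ], y[1:100], n_trees = 200, seed = 0)
  imp <- permutation_importance(f, x[101:150, ], y[101:150],
                                n_repeats = 5, seed = 0)
  imp <- setNames(imp$importance, imp$feature)
  expect_gt(imp[["info"]], 0.2)
  expect_lt(abs(imp[["noise1"]]), 0.05)
  expect_equal(imp[["const"]], 0)         # permuting a constant is identity
  expect_error(permutation_importance(f, x, y, n_repeats = 1),
               class = "histoprox_contract_error")
})

test_that("ensembles average activations and quantify uncertainty", {
  toy <- toy_forest_data()
  fs <- purrr::map(1:3, function(s) train_forest(toy$x, toy$y, n_trees = 30,
                                                 seed = s))
  ens <- forest_ensemble(fs)
  pr <- ensemble_predict(ens, toy$x[1:4, , drop = FALSE])
  manual <- Reduce(`+`, pr$per_member) / 3
  expect_equal(pr$activations, manual)
  expect_equal(rowSums(pr$activations), rep(1, 4))

  # unanimous forests -> significant; the check is seed-deterministic
  u1 <- uncertainty_check(ens, toy$x[1, , drop = FALSE], seed = 1)
  u2 <- uncertainty_check(ens, toy$x[1, , drop = FALSE], seed = 1)
  expect_true(u1$significant)
  expect_false(u1$uncertain)
  expect_identical(u1$interval, u2$interval)

  # near-uniform vote pattern -> uncertain
  mk_tree <- function(pred) list(
    feature = c(0L, -1L, -1L), threshold = c(0, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    majority = c(0L, 0L, 0L), pred = c(0L, pred, pred),
    counts = matrix(0, 3, 3))
  preds <- rep(c(0L, 1L, 2L), each = 10)   # 10 votes per class
  noisy <- structure(list(trees = purrr::map(preds, mk_tree), n_trees = 30L,
                          mtry = 1L, min_node = 1L, seed = 0L,
                          classes = c("a", "b", "c"), feature_names = "x1"),
                     class = "hp_forest")
  un <- uncertainty_check(noisy, matrix(0.5), seed = 0)
  expect_true(un$uncertain)

  # class-order mismatch rejected
  f_bad <- train_forest(toy$x, factor(toy$y, levels = c("b", "a")),
                        n_trees = 10, seed = 1)
  expect_error(forest_ensemble(list(fs[[1]], f_bad)),
               class = "histoprox_contract_error")
})

test_that("accuracy agrees with an established forest implementation", {
  # independent cross-check on complete data: our forest and randomForest
  # should reach comparable held-out accuracy on a moderately hard problem
  withr::with_seed(9, {
    n <- 240
    y <- sample(rep(c("a", "b"), n / 2))
    x <- matrix(rnorm(n * 10), n, 10)
    x[, 1] <- x[, 1] + ifelse(y == "a", 1.2, -1.2)   # overlapping classes
    colnames(x) <- paste0("f", 1:10)
  })
  tr <- 1:160; te <- 161:240
  ours <- train_forest(x[tr, ], y[tr], n_trees = 200, seed = 0)
  acc_ours <- mean(predict_class(ours, x[te, ]) == y[te])
  rf <- withr::with_seed(0, randomForest::randomForest(x[tr, ],
                                                       factor(y[tr]),
                                                       ntree = 200))
  acc_rf <- mean(as.character(predict(rf, x[te, ])) == y[te])
  expect_lt(abs(acc_ours - acc_rf), 0.1)
  expect_gt(acc_ours, 0.75)
})

test_that("null-model forest is calibrated to the class prior", {
  withr::with_seed(2, {
    n <- 300
    y <- sample(rep(c("a", "b", "c"), n / 3))
    x <- matrix(rnorm(n * 8), n, 8)
    colnames(x) <- paste0("f", 1:8)
    ysh <- sample(y[1:200])
  })
  f <- train_forest(x[1:200, ], ysh, n_trees = 100, seed = 0)
  acc <- mean(predict_class(f, x[201:300, ]) == y[201:300])
  prior <- max(table(y[201:300])) / 100
  expect_lt(abs(acc - 1 / 3), 0.12)        # sampling error at n = 100
  expect_lt(acc, prior + 0.12)
})

test_that("forests persist to JSON with bit-identical leaf routing", {
  toy <- toy_forest_data(n = 40)
  f <- train_forest(toy$x, toy$y, n_trees = 15, seed = 4)
  path <- file.path(tempdir(), "forest.json")
  save_forest(f, path)
  g <- load_forest(path)
  expect_identical(leaf_index(f, toy$x), leaf_index(g, toy$x))
  expect_equal(predict_activations(f, toy$x), predict_activations(g, toy$x))
  expect_identical(g$classes, f$classes)
})

test_that("tidy and glance summarise forest structure", {
  toy <- toy_forest_data(n = 40)
  f <- train_forest(toy$x, toy$y, n_trees = 8, seed = 4)
  td <- tidy(f)
  expect_equal(nrow(td), 8L)
  expect_true(all(td$n_leaves == (td$n_nodes + 1) / 2))
  gl <- glance(f)
  expect_equal(gl$n_trees, 8L)
  expect_equal(gl$n_classes, 2L)
})
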