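test_that("AUROC matches the pairwise-concordance oracle", {
  # paper-style worked example: scores (.9,.8,.7,.6), labels (1,0,1,0) -> 0.75
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)

  concordance_oracle <- function(s, pos) {
    pos <- as.logical(pos)
    pairs <- expand.grid(i = which(pos), j = which(!pos))
    mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  }
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      s <- round(runif(n), 2)            # ties likely
      pos <- runif(n) < 0.4
      if (!any(pos) || all(pos)) pos[1:2] <- c(TRUE, FALSE)
    })
    expect_equal(auroc(s, pos), concordance_oracle(s, pos))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)),
               class = "histoprox_contract_error")
})

test_that("weighted AUROC is the count-weighted mean", {
  expect_equal(weighted_auroc(c(0.9, 0.6), c(10, 30)), 0.675)
  expect_equal(weighted_auroc(tibble::tibble(auroc = 0.8, count = 5)), 0.8)
  expect_error(weighted_auroc(numeric(), numeric()),
               class = "histoprox_contract_error")
})

test_that("stratified folds partition every record exactly once, reproducibly", {
  y <- rep(c("a", "b", "c"), times = c(30, 20, 10))
  f1 <- histoprox:::stratified_folds(y, 5, seed = 3)
  f2 <- histoprox:::stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:5))
  # stratification: each class spread across folds
  expect_true(all(table(y, f1)["a", ] == 6))
})

test_that("ten-fold replicates separate a synthetic stain task", {
  fx <- small_corpus()
  x <- fuse_features(hand = small_hand_features(),
                     cov = extract_covariates(fx$manifest))
  he <- fx$manifest$gold_stain %in% c("HE", "IHC")
  rep <- kfold_replicates(x[he, ], fx$manifest$gold_stain[he], k = 3,
                          n_replicates = 2, n_trees = 100, task = "he_vs_ihc")
  expect_s3_class(rep, "hp_eval_report")
  expect_equal(nrow(rep$per_replicate), 2L)
  expect_gt(rep$overall, 0.9)            # palettes are easily separable
  gl <- glance(rep)
  expect_equal(gl$n_replicates, 2L)
})

test_that("leave-one-pathologist-out holds groups out without leakage", {
  fx <- small_corpus()
  x <- fuse_features(hand = small_hand_features(),
                     cov = extract_covariates(fx$manifest))
  seen <- new.env(); seen$groups <- character()
  rep <- lopo_cv(x, fx$manifest$gold_disease, fx$manifest$pathologist_id,
                 n_trees = 100, seeds = 0, k_max = 5,
                 fit_transform = function(tr) {
                   # leakage assertion: fitted transforms never see held-out rows
                   held <- setdiff(seq_len(nrow(x)), tr)
                   g <- unique(fx$manifest$pathologist_id[held])
                   expect_length(g, 1L)
                   expect_false(g %in% fx$manifest$pathologist_id[tr])
                   seen$groups <- c(seen$groups, g)
                   x
                 })
  expect_setequal(seen$groups, unique(fx$manifest$pathologist_id))
  expect_equal(nrow(dplyr::filter(rep$per_group, k == 1)),
               length(unique(fx$manifest$pathologist_id)))
  expect_error(lopo_cv(x, fx$manifest$gold_disease, rep("g1", nrow(x))),
               class = "histoprox_contract_error")
})

test_that("one record per group reduces leave-one-group-out to leave-one-out", {
  toy <- toy_forest_data(n = 20)
  rep <- lopo_cv(toy$x, toy$y, groups = paste0("g", seq_len(20)),
                 n_trees = 60, seeds = 0, k_max = 3)
  expect_equal(nrow(dplyr::filter(rep$per_group, k == 1)), 20L)
  expect_gt(rep$overall, 0.5)            # separable: neighbors share labels
})

test_that("permutation null preserves the label multiset and stays near prior", {
  withr::with_seed(5, {
    n <- 120
    y <- sample(rep(c("a", "b", "c"), n / 3))
    x <- matrix(rnorm(n * 10), n, 10)    # pure noise features
    colnames(x) <- paste0("f", 1:10)
    g <- rep(paste0("g", 1:4), length.out = n)
  })
  nl <- permutation_null(x, y, g, n_trees = 150, seeds = 0, k_max = 3)
  # noise features: null precision@1 is near the 1/3 prior
  expect_lt(abs(nl$overall - 1 / 3), 0.1)
  # two different seeds give similar chance-level precision
  nl2 <- permutation_null(x, y, g, n_trees = 150, seeds = 1, k_max = 3)
  expect_lt(abs(nl$overall - nl2$overall), 0.1)
})

test_that("rank-sum statistic and p-values match the combinatorial oracle", {
  # complete separation, n = m = 10 -> U = 100, exact p = 2 / C(20, 10)
  rs <- ranksum_compare(6:15, (1:10) / 10)
  expect_equal(rs$U, 100)
  expect_equal(rs$U_prime, 0)
  expect_equal(rs$method, "exact")
  expect_equal(rs$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # identical samples (all ties) -> U = 50, p about 1
  rs_eq <- ranksum_compare(rep(1, 10), rep(1, 10))
  expect_equal(rs_eq$U, 50)
  expect_gt(rs_eq$p_value, 0.9)

  # complement identity U + U' = n*m on random inputs; agreement with
  # wilcox.test as the independent implementation
  for (seed in 1:5) {
    ab <- withr::with_seed(seed, list(a = rnorm(8), b = rnorm(11)))
    rs_r <- ranksum_compare(ab$a, ab$b)
    expect_equal(rs_r$U + rs_r$U_prime, 88)
    wt <- wilcox.test(ab$a, ab$b, exact = TRUE, correct = TRUE)
    expect_equal(rs_r$U, unname(wt$statistic))
    expect_equal(rs_r$p_value, wt$p.value, tolerance = 1e-9)
  }
  expect_error(ranksum_compare(1, 1:5), class = "histoprox_contract_error")
})

test_that("eval reports expose tidy, glance, and autoplot views", {
  toy <- toy_forest_data(n = 30)
  rep <- lopo_cv(toy$x, toy$y, groups = rep(c("g1", "g2", "g3"), 10),
                 n_trees = 50, seeds = c(0, 1), k_max = 3)
  td <- tidy(rep)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("task", "protocol", "precision_at_1") %in% names(td)))
  expect_s3_class(autoplot(rep), "ggplot")
})
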