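search_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- small_corpus()
      x <- fuse_features(hand = small_hand_features(),
                         cov = extract_covariates(fx$manifest))
      forest <- train_forest(x, fx$manifest$gold_disease, n_trees = 120,
                             seed = 0)
      cache <<- list(fx = fx, x = x, forest = forest,
                     labels = setNames(fx$manifest$gold_disease,
                                       fx$manifest$id))
    }
    cache
  }
})

test_that("index precomputes one leaf per tree per corpus record", {
  s <- search_fixture()
  idx <- build_index(s$forest, s$x, ids = rownames(s$x))
  expect_equal(dim(idx$leaf_tables[[1]]), c(nrow(s$x), s$forest$n_trees))
  # rebuilding is deterministic and rows equal direct leaf_index calls
  idx2 <- build_index(s$forest, s$x, ids = rownames(s$x))
  expect_identical(idx$leaf_tables, idx2$leaf_tables)
  r <- withr::with_seed(1, sample(nrow(s$x), 1))
  expect_equal(idx$leaf_tables[[1]][r, ],
               as.vector(leaf_index(s$forest, s$x[r, , drop = FALSE])))
})

test_that("querying ranks by proximity with id tie-break and self on top", {
  s <- search_fixture()
  idx <- build_index(s$forest, s$x, ids = rownames(s$x))
  q <- query_index(idx, s$x[5, , drop = FALSE], k = 10)
  expect_s3_class(q, "hp_query_result")
  # the query is itself in the corpus: rank 1 is itself at maximal similarity
  expect_equal(q$ranked$id[1], rownames(s$x)[5])
  expect_equal(q$ranked$similarity[1], s$forest$n_trees)
  expect_true(all(diff(q$ranked$similarity) <= 0))
  # ties broken by ascending corpus id
  t_ids <- q$ranked |>
    dplyr::group_by(.data$similarity) |>
    dplyr::summarise(sorted = !is.unsorted(id))
  expect_true(all(t_ids$sorted))
  expect_equal(sum(q$prediction), 1, tolerance = 1e-9)

  expect_warning(qa <- query_index(idx, s$x[5, , drop = FALSE], k = 999),
                 "corpus size")
  expect_equal(nrow(qa$ranked), nrow(s$x))
})

test_that("ranking matches the exhaustive pairwise-proximity oracle", {
  s <- search_fixture()
  take <- 1:12                      # small corpus for brute force
  idx <- build_index(s$forest, s$x[take, ], ids = rownames(s$x)[take])
  for (qi in c(2L, 7L)) {
    q <- query_index(idx, s$x[qi + 15, , drop = FALSE], k = 12)
    brute <- vapply(take, function(j) {
      proximity(s$forest, s$x[qi + 15, , drop = FALSE],
                s$x[j, , drop = FALSE])
    }, integer(1))
    oracle <- tibble::tibble(id = rownames(s$x)[take], similarity = brute) |>
      dplyr::arrange(dplyr::desc(similarity), id)
    expect_equal(q$ranked$id, oracle$id)
    expect_equal(q$ranked$similarity, oracle$similarity)
  }
})

test_that("removing a corpus record preserves the relative order of the rest", {
  s <- search_fixture()
  idx_all <- build_index(s$forest, s$x, ids = rownames(s$x))
  q_all <- query_index(idx_all, s$x[3, , drop = FALSE], k = nrow(s$x))
  drop_id <- q_all$ranked$id[4]
  keep <- rownames(s$x) != drop_id
  idx_sub <- build_index(s$forest, s$x[keep, ], ids = rownames(s$x)[keep])
  q_sub <- query_index(idx_sub, s$x[3, , drop = FALSE], k = sum(keep))
  expect_equal(q_sub$ranked$id, setdiff(q_all$ranked$id, drop_id))
})

test_that("sanity flags encode the three checks", {
  s <- search_fixture()
  idx <- build_index(s$forest, s$x, ids = rownames(s$x))
  true_lab <- unname(s$labels[5])
  q_ok <- query_index(idx, s$x[5, , drop = FALSE], k = 3,
                      expected_label = true_lab)
  expect_false(q_ok$flags$prediction_check_flag)

  wrong <- setdiff(disease_states(), true_lab)[1]
  q_bad <- query_index(idx, s$x[5, , drop = FALSE], k = 3,
                       expected_label = wrong)
  expect_true(q_bad$flags$prediction_check_flag)
  expect_false(q_ok$flags$heatmap_available)

  # near-uniform tree votes raise the uncertainty flag
  mk_tree <- function(pred) list(
    feature = c(0L, -1L, -1L), threshold = c(0, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    majority = c(0L, 0L, 0L), pred = c(0L, pred, pred),
    counts = matrix(0, 3, 3))
  noisy <- structure(list(trees = purrr::map(rep(c(0L, 1L, 2L), 10), mk_tree),
                          n_trees = 30L, mtry = 1L, min_node = 1L, seed = 0L,
                          classes = disease_states(), feature_names = "f1"),
                     class = "hp_forest")
  fl <- sanity_flags(noisy, matrix(0.2, dimnames = list(NULL, "f1")))
  expect_true(fl$uncertainty_flag)
})

test_that("prediction heatmaps renormalize 25 tiles with 4 imputed", {
  fx <- small_corpus()
  enc <- new_patch_encoder(seed = 0)
  enc$training_meta$classes <- disease_states()
  hm <- prediction_heatmap(enc, fx$std[[1]])
  expect_equal(nrow(hm$tiles), 25L)
  expect_equal(sum(hm$tiles$imputed), 4L)
  expect_equal(rowSums(as.matrix(hm$tiles[, hm$classes])), rep(1, 25),
               tolerance = 1e-9)

  # constant image: all tiles identical
  flat <- standardize(array(150, dim = c(512, 512, 3)))
  hm_flat <- prediction_heatmap(enc, flat)
  vals <- as.matrix(hm_flat$tiles[, hm_flat$classes])
  expect_equal(max(apply(vals, 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-9)

  fh <- feature_heatmap(enc, flat, feature_idx = 7)
  expect_equal(diff(range(fh$tiles$value)), 0, tolerance = 1e-9)
  expect_true(all(fh$tiles$value >= 0 & fh$tiles$value <= 1))
  expect_error(feature_heatmap(enc, flat, feature_idx = 101),
               class = "histoprox_contract_error")
})

test_that("precision@k is the matching fraction of the top k", {
  ranked <- tibble::tibble(id = paste0("c", 1:8))
  labs <- setNames(c("m", "m", "n", "m", "m", "n", "m", "n"), ranked$id)
  expect_equal(as.numeric(precision_at_k(ranked, "m", labs, k = 8)), 5 / 8)
  expect_equal(as.numeric(precision_at_k(ranked, "m", labs, k = 2)), 1)
  expect_equal(as.numeric(precision_at_k(ranked, "x", labs, k = 8)), 0)
  short <- precision_at_k(ranked, "m", labs, k = 20)
  expect_true(attr(short, "truncated"))
})

test_that("autoplot methods return ggplot objects", {
  s <- search_fixture()
  idx <- build_index(s$forest, s$x, ids = rownames(s$x))
  q <- query_index(idx, s$x[1, , drop = FALSE], k = 5)
  expect_s3_class(autoplot(q), "ggplot")
  enc <- new_patch_encoder(seed = 0)
  hm <- prediction_heatmap(enc, small_corpus()$std[[1]])
  expect_s3_class(autoplot(hm), "ggplot")
})
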