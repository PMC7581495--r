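# Random forest with exposed decision paths: training, class activations,
# leaf identity, proximity, permutation importance, ensembling, uncertainty.

as_feature_matrix <- function(x, feature_names = NULL) {
  if (is.data.frame(x)) {
    x <- as.matrix(dplyr::select(x, dplyr::where(is.numeric)))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (!is.null(feature_names)) {
    if (ncol(x) != length(feature_names)) {
      abort(paste0("record has ", ncol(x), " features but the forest was ",
                   "trained on ", length(feature_names),
                   " — feature-block schema mismatch"),
            class = "histoprox_schema_error")
    }
    if (!is.null(colnames(x)) && !identical(colnames(x), feature_names)) {
      missing_blocks <- setdiff(feature_names, colnames(x))
      if (length(missing_blocks) > 0L) {
        abort(paste0("schema mismatch; first missing feature: ",
                     missing_blocks[1L]),
              class = "histoprox_schema_error")
      }
      x <- x[, feature_names, drop = FALSE]
    }
  }
  x
}

#' Train a decision-path proximity forest
#'
#' A 1000-tree (by default) random forest — bootstrap sampling, Gini split
#' criterion, `sqrt(d)` candidate features per split, unlimited depth, minimum
#' leaf size 1 — whose per-tree leaf identities are exposed so the forest can
#' be repurposed as a similarity metric. Missing feature values (e.g. an
#' unknown tissue covariate) are excluded from split-gain computation and
#' routed down a stored majority branch, keeping every decision path
#' deterministic. Training is single-threaded and fully reproducible from
#' `seed`.
#'
#' @param x Numeric matrix or data frame of features (rows = records); `NA`
#'   encodes missing values.
#' @param y Class labels (factor or character).
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate features per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node Minimum node size to attempt a split on (default 1).
#' @param seed Integer seed.
#' @return Object of class `hp_forest`.
#' @export
train_forest <- function(x, y, n_trees = 1000L, mtry = NULL, min_node = 1L,
                         seed = 0L) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  if (nlevels(y) < 2L) {
    abort("need at least 2 classes to train a forest",
          class = "histoprox_contract_error")
  }
  if (length(y) != nrow(x)) abort("x and y lengths differ",
                                  class = "histoprox_contract_error")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- .cpp_train_forest(x, as.integer(y) - 1L, nlevels(y),
                             as.integer(n_trees), as.integer(mtry),
                             as.integer(min_node), as.integer(seed))
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), min_node = as.integer(min_node),
                 seed = as.integer(seed), classes = levels(y),
                 feature_names = colnames(x)),
            class = "hp_forest")
}

#' @export
print.hp_forest <- function(x, ...) {
  cat("<hp_forest>", x$n_trees, "trees,", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "), d =",
      length(x$feature_names %||% NA), ", seed", x$seed, "\n")
  invisible(x)
}

#' Per-tree leaf identities
#'
#' The leaf index is the deterministic end of each record's root-to-leaf
#' decision sequence; identical leaf index in a tree means the tree made an
#' identical sequence of decisions for the two records.
#'
#' @param forest An `hp_forest`.
#' @param x Feature matrix / data frame (or a single record vector).
#' @return Integer matrix `n_records x n_trees` of 0-based node ids.
#' @export
leaf_index <- function(forest, x) {
  stopifnot(inherits(forest, "hp_forest"))
  x <- as_feature_matrix(x, forest$feature_names)
  .cpp_leaf_ids(forest$trees, x)
}

#' Class activations (tree-vote fractions)
#'
#' @inheritParams leaf_index
#' @return Numeric matrix `n_records x n_classes`; rows are nonnegative and
#'   sum to 1. Column names are the class levels.
#' @export
predict_activations <- function(forest, x) {
  stopifnot(inherits(forest, "hp_forest"))
  x <- as_feature_matrix(x, forest$feature_names)
  votes <- .cpp_vote_matrix(forest$trees, .cpp_leaf_ids(forest$trees, x))
  k <- length(forest$classes)
  act <- t(apply(votes, 1L, function(v) tabulate(v + 1L, nbins = k)))
  act <- act / forest$n_trees
  colnames(act) <- forest$classes
  act
}

#' Predicted class labels
#'
#' @inheritParams leaf_index
#' @return Character vector of predicted classes (argmax activation, ties to
#'   the earlier class level).
#' @export
predict_class <- function(forest, x) {
  act <- predict_activations(forest, x)
  forest$classes[max.col(act, ties.method = "first")]
}

#' Decision-path proximity between records
#'
#' The number of trees (0 .. `n_trees`) in which two records traverse an
#' identical decision sequence to the same leaf. A record has maximal
#' proximity `n_trees` with itself; the count is symmetric. The normalized
#' score divides by `n_trees`.
#'
#' @param forest An `hp_forest`.
#' @param a,b Single records or matrices of records (rows paired by
#'   broadcasting: if `b` has multiple rows and `a` one, `a` is compared to
#'   each row of `b`).
#' @return Integer vector/matrix of co-leaf counts.
#' @export
proximity <- function(forest, a, b) {
  la <- leaf_index(forest, a)
  lb <- leaf_index(forest, b)
  out <- .cpp_proximity_counts(la, lb)
  if (nrow(la) == 1L && nrow(lb) == 1L) as.integer(out[1L, 1L])
  else if (nrow(la) == 1L) as.integer(out[1L, ])
  else out
}

#' Permutation feature importance (mean decrease in accuracy)
#'
#' Baseline held-out accuracy minus the mean accuracy after shuffling the
#' target column(s). A feature block (e.g. the ten tissue one-hot columns)
#' is shuffled jointly with one permutation, matching how a single clinical
#' covariate should be assessed.
#'
#' @param forest An `hp_forest`.
#' @param x,y Held-out records with labels.
#' @param features Character vector of feature names, or a named list of
#'   blocks (name -> character vector of member columns). Default: every
#'   individual feature.
#' @param n_repeats Shuffles per feature (>= 2).
#' @param seed Integer seed.
#' @return Tibble: `feature`, `importance` (mean decrease in accuracy),
#'   `sd`, `baseline_accuracy`.
#' @export
permutation_importance <- function(forest, x, y, features = NULL,
                                   n_repeats = 5L, seed = 0L) {
  stopifnot(inherits(forest, "hp_forest"))
  if (n_repeats < 2L) {
    abort("n_repeats must be >= 2", class = "histoprox_contract_error")
  }
  x <- as_feature_matrix(x, forest$feature_names)
  y <- as.character(y)
  if (is.null(features)) {
    features <- as.list(setNames(forest$feature_names, forest$feature_names))
  } else if (is.character(features)) {
    features <- as.list(setNames(features, features))
  }
  base_acc <- mean(predict_class(forest, x) == y)
  rows <- withr::with_seed(seed, purrr::imap(features, function(cols, nm) {
    ji <- match(cols, forest$feature_names)
    if (anyNA(ji)) {
      abort(paste0("unknown feature(s) in block '", nm, "'"),
            class = "histoprox_schema_error")
    }
    accs <- purrr::map_dbl(seq_len(n_repeats), function(r) {
      xs <- x
      perm <- sample.int(nrow(x))
      xs[, ji] <- x[perm, ji, drop = FALSE]
      mean(predict_class(forest, xs) == y)
    })
    tibble::tibble(feature = nm, importance = base_acc - mean(accs),
                   sd = sd(accs), baseline_accuracy = base_acc)
  }))
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$importance))
}

# --- ensemble ----------------------------------------------------------------

#' Bundle independently trained forests into an ensemble
#'
#' The default configuration is three members, each typically paired with an
#' independently seeded encoder feature block. Members must share the class
#' order.
#'
#' @param ... `hp_forest` members (or a single list of them).
#' @return Object of class `hp_ensemble`.
#' @export
forest_ensemble <- function(...) {
  members <- list(...)
  if (length(members) == 1L && !inherits(members[[1L]], "hp_forest")) {
    members <- members[[1L]]
  }
  stopifnot(all(purrr::map_lgl(members, inherits, "hp_forest")))
  cls <- purrr::map(members, "classes")
  if (!all(purrr::map_lgl(cls, identical, cls[[1L]]))) {
    abort("ensemble members disagree on class order",
          class = "histoprox_contract_error")
  }
  structure(list(members = members, classes = cls[[1L]]),
            class = "hp_ensemble")
}

#' @export
print.hp_ensemble <- function(x, ...) {
  cat("<hp_ensemble>", length(x$members), "members,",
      length(x$classes), "classes\n")
  invisible(x)
}

#' Ensemble class activations
#'
#' Mean of member activations; per-member activations are retained for
#' uncertainty assessment.
#'
#' @param ensemble An `hp_ensemble`.
#' @param x Feature records. With per-member feature blocks, pass a list of
#'   matrices (one per member); a single matrix is reused for every member.
#' @return List: `activations` (mean, `n x k`), `per_member` (list of
#'   member activation matrices).
#' @export
ensemble_predict <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "hp_ensemble"))
  xs <- if (is.list(x) && !is.data.frame(x)) x
        else rep(list(x), length(ensemble$members))
  stopifnot(length(xs) == length(ensemble$members))
  per <- purrr::map2(ensemble$members, xs, predict_activations)
  list(activations = Reduce(`+`, per) / length(per), per_member = per)
}

#' Prediction-uncertainty sanity check
#'
#' Bootstraps the trees within each ensemble member to resample the
#' activation vector, forming an interval for the top-class minus runner-up
#' activation margin. The prediction is flagged `uncertain` when the interval
#' at the requested level includes 0 — i.e. when tree-level disagreement makes
#' the winning class statistically indistinguishable from the runner-up.
#'
#' @param ensemble `hp_ensemble` (a single `hp_forest` is promoted to a
#'   one-member ensemble).
#' @param x A single record (or list of per-member records).
#' @param level Significance level for the margin interval (default 0.05).
#' @param n_boot Bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @return List: `significant` (logical), `uncertain` (logical), `margin`
#'   (point estimate), `interval` (two-sided), `activations`.
#' @export
uncertainty_check <- function(ensemble, x, level = 0.05, n_boot = 200L,
                              seed = 0L) {
  if (inherits(ensemble, "hp_forest")) ensemble <- forest_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "hp_ensemble"))
  xs <- if (is.list(x) && !is.data.frame(x)) x
        else rep(list(x), length(ensemble$members))
  k <- length(ensemble$classes)
  # per-member per-tree votes for the single record
  member_votes <- purrr::map2(ensemble$members, xs, function(f, xi) {
    xi <- as_feature_matrix(xi, f$feature_names)
    stopifnot(nrow(xi) == 1L)
    as.integer(.cpp_vote_matrix(f$trees, .cpp_leaf_ids(f$trees, xi))[1L, ])
  })
  point <- Reduce(`+`, purrr::map(member_votes, function(v) {
    tabulate(v + 1L, nbins = k) / length(v)
  })) / length(member_votes)
  ord <- order(point, decreasing = TRUE)
  margins <- withr::with_seed(seed, purrr::map_dbl(seq_len(n_boot), function(b) {
    act <- Reduce(`+`, purrr::map(member_votes, function(v) {
      vb <- v[sample.int(length(v), replace = TRUE)]
      tabulate(vb + 1L, nbins = k) / length(vb)
    })) / length(member_votes)
    act[ord[1L]] - act[ord[2L]]
  }))
  interval <- unname(quantile(margins, c(level / 2, 1 - level / 2),
                              type = 1L))
  significant <- interval[1L] > 0
  list(significant = significant, uncertain = !significant,
       margin = point[ord[1L]] - point[ord[2L]], interval = interval,
       activations = setNames(point, ensemble$classes))
}

# --- persistence -------------------------------------------------------------

#' Persist a forest as portable JSON
#'
#' Captures splits, thresholds, majority branches, leaf class counts, class
#' order, and seed; reloading guarantees bit-identical leaf indices.
#'
#' @param forest An `hp_forest`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_forest <- function(forest, path) {
  stopifnot(inherits(forest, "hp_forest"))
  payload <- list(
    n_trees = forest$n_trees, mtry = forest$mtry, min_node = forest$min_node,
    seed = forest$seed, classes = forest$classes,
    feature_names = forest$feature_names,
    trees = purrr::map(forest$trees, function(tr) {
      list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
           right = tr$right, majority = tr$majority, pred = tr$pred,
           counts = tr$counts)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  trees <- purrr::map(p$trees, function(tr) {
    cnt <- do.call(rbind, purrr::map(tr$counts, num))
    list(feature = as.integer(unlist(tr$feature)),
         threshold = num(tr$threshold),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         majority = as.integer(unlist(tr$majority)),
         pred = as.integer(unlist(tr$pred)),
         counts = cnt)
  })
  structure(list(trees = trees, n_trees = as.integer(p$n_trees),
                 mtry = as.integer(p$mtry), min_node = as.integer(p$min_node),
                 seed = as.integer(p$seed), classes = as.character(p$classes),
                 feature_names = if (length(p$feature_names)) as.character(p$feature_names) else NULL),
            class = "hp_forest")
}

# --- broom-style methods ------------------------------------------------------

#' Tidy a proximity forest
#'
#' One row per tree with its node and leaf counts and depth.
#'
#' @param x An `hp_forest`.
#' @param ... Unused.
#' @return Tibble: `tree`, `n_nodes`, `n_leaves`, `depth`.
#' @export
tidy.hp_forest <- function(x, ...) {
  rows <- purrr::imap(x$trees, function(tr, i) {
    depth <- local({
      d <- rep(0L, length(tr$feature))
      for (n in seq_along(tr$feature)) {
        if (tr$feature[n] >= 0L) {
          d[tr$left[n] + 1L] <- d[n] + 1L
          d[tr$right[n] + 1L] <- d[n] + 1L
        }
      }
      max(d)
    })
    tibble::tibble(tree = i, n_nodes = length(tr$feature),
                   n_leaves = sum(tr$feature < 0L), depth = depth)
  })
  dplyr::bind_rows(rows)
}

#' Glance at a proximity forest
#'
#' @param x An `hp_forest`.
#' @param ... Unused.
#' @return One-row tibble: `n_trees`, `n_classes`, `n_features`, `mtry`,
#'   `seed`, `mean_depth`.
#' @export
glance.hp_forest <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_trees = x$n_trees, n_classes = length(x$classes),
                 n_features = length(x$feature_names %||% NA),
                 mtry = x$mtry, seed = x$seed, mean_depth = mean(td$depth))
}
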