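# Evaluation protocol: ten-fold and leave-one-pathologist-out
# cross-validation, weighted one-vs-rest AUROC, precision@k curves,
# permutation null, and rank-sum replicate comparison.

#' Rank-statistic AUROC
#'
#' One-vs-rest AUROC computed from the Mann-Whitney rank statistic with
#' midrank ties: the probability a random positive outscores a random
#' negative (ties count 1/2).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical (or 0/1) positive-class indicator.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    abort("need both positive and negative examples",
          class = "histoprox_contract_error")
  }
  r <- rank(scores)                       # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Count-weighted average of per-class AUROCs
#'
#' @param per_class Tibble/data frame with columns `auroc` and `count`
#'   (instance count per class), or two numeric vectors.
#' @param counts Counts when `per_class` is a numeric vector.
#' @return Weighted mean AUROC.
#' @examples
#' weighted_auroc(c(0.9, 0.6), c(10, 30))  # 0.675
#' @export
weighted_auroc <- function(per_class, counts = NULL) {
  if (is.data.frame(per_class)) {
    a <- per_class$auroc; n <- per_class$count
  } else {
    a <- per_class; n <- counts
  }
  if (length(a) == 0L) abort("empty per-class AUROC list",
                             class = "histoprox_contract_error")
  stopifnot(length(a) == length(n), all(n > 0))
  sum(a * n) / sum(n)
}

#' Per-class and overall AUROC from class activations
#'
#' @param activations Matrix `n x k` with class columns.
#' @param labels True labels (must match column names).
#' @return List: `per_class` tibble (`class`, `auroc`, `count`), `overall`
#'   (count-weighted).
#' @export
multiclass_auroc <- function(activations, labels) {
  classes <- colnames(activations)
  labels <- as.character(labels)
  per <- purrr::map(classes, function(cl) {
    pos <- labels == cl
    if (sum(pos) == 0L || sum(!pos) == 0L) return(NULL)
    tibble::tibble(class = cl, auroc = auroc(activations[, cl], pos),
                   count = sum(pos))
  })
  per <- dplyr::bind_rows(per)
  list(per_class = per, overall = weighted_auroc(per))
}

stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      ii <- sample(which(y == cl))
      fold[ii] <- rep_len(seq_len(k), length(ii))
    }
  })
  fold
}

#' Replicated stratified k-fold cross-validation
#'
#' Runs `n_replicates` rounds of stratified `k`-fold cross-validation (one
#' seed per replicate, defaults 0..9), training a proximity forest per fold
#' and pooling held-out class activations to a per-replicate weighted AUROC.
#' Classes with fewer than 2 records are excluded with a warning.
#'
#' @param x Feature matrix / data frame.
#' @param y Class labels.
#' @param k Folds (default 10).
#' @param n_replicates Replicates (default 10).
#' @param seeds Integer seed per replicate (default `0:(n_replicates-1)`).
#' @param n_trees,mtry Forest settings.
#' @param task Optional task name recorded in the report.
#' @return `hp_eval_report` with `per_replicate`, `per_class` (first
#'   replicate), `overall` (mean), `overall_sd`.
#' @export
kfold_replicates <- function(x, y, k = 10L, n_replicates = 10L,
                             seeds = seq_len(n_replicates) - 1L,
                             n_trees = 1000L, mtry = NULL, task = "task") {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  small <- names(which(table(y) < 2L))
  if (length(small) > 0L) {
    warn(paste0("excluding class(es) with < 2 records: ",
                paste(small, collapse = ", ")))
    keep <- !(y %in% small)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  reps <- purrr::map(seq_along(seeds), function(r) {
    sd_r <- seeds[r]
    fold <- stratified_folds(y, k, seed = sd_r)
    acts <- matrix(NA_real_, length(y), length(unique(y)),
                   dimnames = list(NULL, sort(unique(y))))
    for (f in seq_len(k)) {
      te <- fold == f
      if (!any(te)) next
      forest <- train_forest(x[!te, , drop = FALSE], y[!te],
                             n_trees = n_trees, mtry = mtry, seed = sd_r)
      a <- predict_activations(forest, x[te, , drop = FALSE])
      acts[te, colnames(a)] <- a
    }
    res <- multiclass_auroc(acts, y)
    list(replicate = r, seed = sd_r, auroc = res$overall,
         per_class = res$per_class)
  })
  per_replicate <- dplyr::bind_rows(purrr::map(reps, function(r) {
    tibble::tibble(replicate = r$replicate, seed = r$seed, auroc = r$auroc)
  }))
  new_eval_report(task = task, protocol = "kfold",
                  per_replicate = per_replicate,
                  per_class = reps[[1L]]$per_class,
                  overall = mean(per_replicate$auroc),
                  overall_sd = sd(per_replicate$auroc))
}

# shared machinery: one leave-one-group-out round of proximity search
lopo_round <- function(x, y, groups, n_trees, mtry, seed, k_max,
                       fit_transform, shuffle_train_labels) {
  y <- as.character(y); groups <- as.character(groups)
  gs <- sort(unique(groups))
  per_query <- purrr::map(gs, function(g) {
    tr <- which(groups != g)
    te <- which(groups == g)
    stopifnot(!any(groups[tr] == g))          # leakage guard
    xt <- x
    if (!is.null(fit_transform)) xt <- fit_transform(tr)
    y_train <- y[tr]
    if (shuffle_train_labels) {
      y_train <- withr::with_seed(seed + match(g, gs),
                                  sample(y_train))
    }
    forest <- train_forest(xt[tr, , drop = FALSE], y_train,
                           n_trees = n_trees, mtry = mtry, seed = seed)
    lt <- leaf_index(forest, xt[tr, , drop = FALSE])
    lq <- leaf_index(forest, xt[te, , drop = FALSE])
    sims <- .cpp_proximity_counts(lq, lt)
    # evaluation labels are always the true labels
    corpus_lab <- y[tr]
    hits <- purrr::map(seq_along(te), function(qi) {
      ord <- order(-sims[qi, ], seq_along(tr))   # ties by corpus position
      matches <- corpus_lab[ord[seq_len(k_max)]] == y[te[qi]]
      tibble::tibble(group = g, query = te[qi], k = seq_len(k_max),
                     hit = cumsum(matches) / seq_len(k_max))
    })
    dplyr::bind_rows(hits)
  })
  dplyr::bind_rows(per_query)
}

#' Leave-one-pathologist-out search evaluation
#'
#' For each group (pathologist) g: train the forest — and any fold-fitted
#' feature transforms — on every record with `group != g`, then rank the
#' training corpus by decision-path proximity for each held-out query and
#' score precision@k (k = 1..`k_max`) against true labels. Repeats over
#' `seeds` replicates.
#'
#' @param x Feature matrix.
#' @param y Labels (search relevance = label match).
#' @param groups Group (pathologist) id per record; >= 2 distinct required.
#' @param n_trees,mtry Forest settings.
#' @param seeds Integer seed per replicate (default 0).
#' @param k_max Largest k reported (default 10).
#' @param fit_transform Optional `function(train_idx)` returning the feature
#'   matrix for all rows with any trainable transform fitted on the training
#'   rows only (e.g. a SIFT vocabulary).
#' @param shuffle_train_labels Shuffle training labels (permutation null).
#' @param task Task name for the report.
#' @return `hp_eval_report` with `per_replicate` (precision@1),
#'   `precision_at_k` (mean over queries per k), `per_group` (per-group
#'   precision@k), `overall` (mean precision@1), `overall_sd`.
#' @export
lopo_cv <- function(x, y, groups, n_trees = 1000L, mtry = NULL, seeds = 0L,
                    k_max = 10L, fit_transform = NULL,
                    shuffle_train_labels = FALSE, task = "search") {
  x <- as_feature_matrix(x)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) {
    abort("leave-one-group-out needs >= 2 distinct groups",
          class = "histoprox_contract_error")
  }
  runs <- purrr::map(seq_along(seeds), function(r) {
    pq <- lopo_round(x, y, groups, n_trees, mtry, seed = seeds[r],
                     k_max = k_max, fit_transform = fit_transform,
                     shuffle_train_labels = shuffle_train_labels)
    pq$replicate <- r
    pq$seed <- seeds[r]
    pq
  })
  all_pq <- dplyr::bind_rows(runs)
  prec_k <- all_pq |>
    dplyr::group_by(.data$replicate, .data$k) |>
    dplyr::summarise(precision = mean(.data$hit), .groups = "drop")
  per_replicate <- prec_k |>
    dplyr::filter(.data$k == 1L) |>
    dplyr::transmute(.data$replicate,
                     seed = seeds[.data$replicate],
                     precision_at_1 = .data$precision)
  per_group <- all_pq |>
    dplyr::group_by(.data$group, .data$k) |>
    dplyr::summarise(precision = mean(.data$hit), .groups = "drop")
  new_eval_report(task = task, protocol = "lopo",
                  per_replicate = per_replicate,
                  precision_at_k = prec_k |>
                    dplyr::group_by(.data$k) |>
                    dplyr::summarise(precision = mean(.data$precision),
                                     .groups = "drop"),
                  per_group = per_group,
                  overall = mean(per_replicate$precision_at_1),
                  overall_sd = if (nrow(per_replicate) > 1L) {
                    sd(per_replicate$precision_at_1)
                  } else NA_real_)
}

#' Permutation-null search evaluation
#'
#' The chance model for search: identical pipeline, but class labels are
#' shuffled (seeded) before training only — evaluation labels stay true —
#' so the resulting precision@k estimates the class-prior chance level.
#'
#' @inheritParams lopo_cv
#' @return `hp_eval_report` (protocol `"lopo"`, task suffixed
#'   `"permutation_null"`).
#' @export
permutation_null <- function(x, y, groups, n_trees = 1000L, mtry = NULL,
                             seeds = 0L, k_max = 10L, fit_transform = NULL,
                             task = "permutation_null") {
  lopo_cv(x, y, groups, n_trees = n_trees, mtry = mtry, seeds = seeds,
          k_max = k_max, fit_transform = fit_transform,
          shuffle_train_labels = TRUE, task = task)
}

#' Two-tailed Wilcoxon rank-sum comparison of replicate sets
#'
#' Mann-Whitney U with midrank ties. The p value is computed by the exact
#' null distribution when there are no ties and both samples have at most 12
#' observations, otherwise by the normal approximation with tie and
#' continuity corrections. `U` is reported for the first sample (number of
#' (a, b) pairs with a > b, ties counting 1/2); `U_prime = n*m - U`.
#'
#' @param a,b Numeric replicate vectors (lengths >= 2).
#' @return List: `U`, `U_prime`, `p_value`, `method` ("exact" or
#'   "normal_approx").
#' @examples
#' ranksum_compare(6:15, 1:10 / 10)  # complete separation: U = 100
#' @export
ranksum_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("both samples need >= 2 observations",
          class = "histoprox_contract_error")
  }
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n <= 12L && m <= 12L) {
    p <- 2 * min(pwilcox(U, n, m), pwilcox(U - 1, n, m, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
    sigma <- sqrt(n * m / 12 * ((n + m + 1) - tie_term))
    if (sigma == 0) {
      p <- 1                      # fully tied samples carry no evidence
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      p <- 2 * pnorm(-abs(z))
      p <- min(1, p)
    }
    method <- "normal_approx"
  }
  list(U = U, U_prime = n * m - U, p_value = p, method = method)
}

# --- report container --------------------------------------------------------

new_eval_report <- function(task, protocol, ...) {
  structure(c(list(task = task, protocol = protocol), list(...)),
            class = "hp_eval_report")
}

#' @export
print.hp_eval_report <- function(x, ...) {
  metric <- if (x$protocol == "kfold") "weighted AUROC" else "precision@1"
  cat("<hp_eval_report>", x$task, paste0("(", x$protocol, ")"), "\n")
  cat(" ", metric, ": ", sprintf("%.4f", x$overall),
      if (!is.null(x$overall_sd) && is.finite(x$overall_sd %||% NA)) {
        sprintf(" ± %.4f (%d replicates)", x$overall_sd,
                nrow(x$per_replicate))
      }, "\n", sep = "")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `hp_eval_report`.
#' @param ... Unused.
#' @return Per-replicate tibble with `task` and `protocol` columns attached.
#' @export
tidy.hp_eval_report <- function(x, ...) {
  dplyr::mutate(x$per_replicate, task = x$task, protocol = x$protocol,
                .before = 1L)
}

#' Glance at an evaluation report
#'
#' @param x An `hp_eval_report`.
#' @param ... Unused.
#' @return One-row tibble with the overall metric and replicate count.
#' @export
glance.hp_eval_report <- function(x, ...) {
  tibble::tibble(task = x$task, protocol = x$protocol, overall = x$overall,
                 overall_sd = x$overall_sd %||% NA_real_,
                 n_replicates = nrow(x$per_replicate))
}
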