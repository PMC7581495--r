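# Similarity search over a corpus by decision-path proximity, with the three
# sanity checks and the 5x5 prediction/feature heatmaps.

#' Build a proximity search index
#'
#' Precomputes per-tree leaf identities for every corpus record so query cost
#' does not require re-traversing the corpus side. Supports a single forest
#' or an ensemble (proximities summed across members, range
#' `0 .. members * n_trees`).
#'
#' @param model An `hp_forest` or `hp_ensemble`.
#' @param x Corpus feature matrix (rows = records) or list of per-member
#'   matrices for an ensemble with member-specific blocks.
#' @param ids Character corpus ids (default row names or `1..n`).
#' @param labels Optional corpus labels (used by evaluation).
#' @return Object of class `hp_search_index`.
#' @export
build_index <- function(model, x, ids = NULL, labels = NULL) {
  members <- if (inherits(model, "hp_ensemble")) model$members else list(model)
  stopifnot(all(purrr::map_lgl(members, inherits, "hp_forest")))
  xs <- if (is.list(x) && !is.data.frame(x)) x else rep(list(x), length(members))
  stopifnot(length(xs) == length(members))
  n <- nrow(as_feature_matrix(xs[[1L]]))
  ids <- ids %||% rownames(xs[[1L]]) %||% as.character(seq_len(n))
  leaf_tables <- purrr::map2(members, xs, leaf_index)
  structure(list(model = model, members = members, leaf_tables = leaf_tables,
                 ids = as.character(ids), labels = labels,
                 n_trees_total = sum(purrr::map_int(members, "n_trees"))),
            class = "hp_search_index")
}

#' @export
print.hp_search_index <- function(x, ...) {
  cat("<hp_search_index>", length(x$ids), "records,", length(x$members),
      "member forest(s),", x$n_trees_total, "trees total\n")
  invisible(x)
}

#' Query the index
#'
#' Computes the decision-path proximity of the query to every corpus record
#' and returns the top `k` by descending similarity, ties broken by ascending
#' corpus id. The forest's class activations and the three sanity flags are
#' attached.
#'
#' @param index An `hp_search_index`.
#' @param x Query record (or list of per-member records).
#' @param k Number of results (>= 1); if larger than the corpus the list is
#'   truncated with a warning.
#' @param expected_label Optional caller-supplied label for the
#'   prediction-vs-expectation check.
#' @param exclude_id Corpus id to exclude (self-exclusion during evaluation).
#' @param heatmap Optional `hp_heatmap` to attach (third sanity check).
#' @return Object of class `hp_query_result`: `ranked` tibble
#'   (`id`, `similarity`, `similarity_normalized`), `prediction`,
#'   `flags`, `uncertainty`.
#' @export
query_index <- function(index, x, k = 10L, expected_label = NULL,
                        exclude_id = NULL, heatmap = NULL) {
  stopifnot(inherits(index, "hp_search_index"), k >= 1L)
  xs <- if (is.list(x) && !is.data.frame(x)) x
        else rep(list(x), length(index$members))
  lq <- purrr::map2(index$members, xs, leaf_index)
  sims <- Reduce(`+`, purrr::map2(lq, index$leaf_tables, function(q, tab) {
    as.vector(.cpp_proximity_counts(q, tab))
  }))
  keep <- rep(TRUE, length(index$ids))
  if (!is.null(exclude_id)) keep <- index$ids != exclude_id
  ranked <- tibble::tibble(id = index$ids[keep], similarity = sims[keep]) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$id)
  if (k > nrow(ranked)) {
    warn(paste0("k = ", k, " exceeds corpus size ", nrow(ranked),
                "; returning all records"))
    k <- nrow(ranked)
  }
  ranked <- head(ranked, k)
  ranked$similarity_normalized <- ranked$similarity / index$n_trees_total

  pred <- ensemble_predict(as_ensemble(index$model), xs)
  unc <- uncertainty_check(as_ensemble(index$model), xs)
  flags <- sanity_flags(index$model, xs, expected_label = expected_label,
                        uncertainty = unc, heatmap = heatmap)
  structure(list(ranked = ranked, prediction = pred$activations[1L, ],
                 flags = flags, uncertainty = unc, heatmap = heatmap),
            class = "hp_query_result")
}

as_ensemble <- function(model) {
  if (inherits(model, "hp_ensemble")) model else forest_ensemble(list(model))
}

#' @export
print.hp_query_result <- function(x, ...) {
  cat("<hp_query_result> top", nrow(x$ranked), "matches; prediction:",
      paste(sprintf("%s=%.3f", names(x$prediction), x$prediction),
            collapse = " "), "\n")
  cat(" flags:", paste(names(x$flags)[unlist(x$flags)], collapse = " "),
      if (!any(unlist(x$flags))) "(all clear)", "\n")
  print(x$ranked, ...)
  invisible(x)
}

#' Three-level sanity check for a search
#'
#' Flag 1: the ensemble-uncertainty verdict (prediction margin not
#' statistically significant). Flag 2: disagreement between the predicted
#' class and a caller-supplied expected label (unset when no label given).
#' Flag 3: whether a prediction heatmap was generated and attached for human
#' review. Any raised flag means the search results should not be trusted.
#'
#' @param model `hp_forest` or `hp_ensemble`.
#' @param x Query record (or per-member list).
#' @param expected_label Optional label to compare the prediction against.
#' @param uncertainty Optional precomputed [uncertainty_check()] result.
#' @param heatmap Optional `hp_heatmap`.
#' @return Named list of logicals: `uncertainty_flag`,
#'   `prediction_check_flag`, `heatmap_available`.
#' @export
sanity_flags <- function(model, x, expected_label = NULL, uncertainty = NULL,
                         heatmap = NULL) {
  ens <- as_ensemble(model)
  unc <- uncertainty %||% uncertainty_check(ens, x)
  pred_class <- names(which.max(unc$activations))
  list(
    uncertainty_flag = isTRUE(unc$uncertain),
    prediction_check_flag = !is.null(expected_label) &&
      !is.na(expected_label) && !identical(pred_class, expected_label),
    heatmap_available = inherits(heatmap, "hp_heatmap")
  )
}

# --- heatmaps ----------------------------------------------------------------

impute_corners <- function(grid_tbl, value_cols) {
  # fill non-evaluated tiles with the per-column median of the 4 nearest
  # evaluated tiles (Euclidean grid distance, row-major tie-break)
  ev <- grid_tbl[grid_tbl$evaluated, , drop = FALSE]
  for (i in which(!grid_tbl$evaluated)) {
    d2 <- (ev$grid_row - grid_tbl$grid_row[i])^2 +
      (ev$grid_col - grid_tbl$grid_col[i])^2
    nn <- ev[order(d2, ev$slot), ][1:4, , drop = FALSE]
    for (cl in value_cols) grid_tbl[[cl]][i] <- median(nn[[cl]])
  }
  grid_tbl
}

#' Class-activation heatmap over the 5x5 patch grid
#'
#' Evaluates the encoder's class head on the 21 evaluated tiles, imputes the
#' 4 non-evaluated tiles with the per-class median of their 4 nearest
#' evaluated tiles, then renormalizes each tile's activations to sum to 1.
#'
#' @param encoder A trained (or stub) `hp_encoder`.
#' @param std An `hp_standard_image`.
#' @param covariates Optional covariate vector for the class head.
#' @return Object of class `hp_heatmap`: `tiles` tibble (`slot`, `grid_row`,
#'   `grid_col`, `imputed`, one column per class), `classes`, `kind`.
#' @export
prediction_heatmap <- function(encoder, std, covariates = NULL) {
  stopifnot(inherits(encoder, "hp_encoder"), inherits(std, "hp_standard_image"))
  ps <- patch_grid(std)
  classes <- encoder$training_meta$classes %||%
    paste0("class_", seq_len(encoder$n_classes))
  acts <- vapply(ps$patches, function(p) {
    encode_patch_class(encoder, p, covariates)
  }, numeric(encoder$n_classes))
  tiles <- ps$grid
  for (ci in seq_along(classes)) tiles[[classes[ci]]] <- NA_real_
  tiles[tiles$evaluated, classes] <- as.data.frame(t(acts))
  tiles <- impute_corners(tiles, classes)
  tot <- rowSums(as.matrix(tiles[, classes]))
  tiles[, classes] <- as.matrix(tiles[, classes]) / tot
  tiles$imputed <- !tiles$evaluated
  structure(list(tiles = tiles[, c("slot", "grid_row", "grid_col", "imputed",
                                   classes)],
                 classes = classes, kind = "prediction"),
            class = "hp_heatmap")
}

#' Single-deep-feature heatmap over the 5x5 grid
#'
#' Per-tile value of one 100-d head feature; same grid and imputation as
#' [prediction_heatmap()], without renormalization.
#'
#' @inheritParams prediction_heatmap
#' @param feature_idx Head feature index in `1..100`.
#' @return An `hp_heatmap` with a single `value` column.
#' @export
feature_heatmap <- function(encoder, std, feature_idx, covariates = NULL) {
  stopifnot(inherits(encoder, "hp_encoder"), inherits(std, "hp_standard_image"))
  if (feature_idx < 1L || feature_idx > ENC_HEAD_DIM) {
    abort("feature_idx must be in 1..100", class = "histoprox_contract_error")
  }
  ps <- patch_grid(std)
  vals <- purrr::map_dbl(ps$patches, function(p) {
    encode_patch(encoder, p, covariates)[feature_idx]
  })
  tiles <- ps$grid
  tiles$value <- NA_real_
  tiles$value[tiles$evaluated] <- vals
  tiles <- impute_corners(tiles, "value")
  tiles$imputed <- !tiles$evaluated
  structure(list(tiles = tiles[, c("slot", "grid_row", "grid_col", "imputed",
                                   "value")],
                 classes = NULL, kind = "feature",
                 feature_idx = as.integer(feature_idx)),
            class = "hp_heatmap")
}

#' @export
print.hp_heatmap <- function(x, ...) {
  cat("<hp_heatmap>", x$kind,
      if (x$kind == "feature") paste0("(feature ", x$feature_idx, ")"),
      "- 5x5 grid,", sum(x$tiles$imputed), "imputed tiles\n")
  invisible(x)
}

#' Precision at k
#'
#' Fraction of the top-`k` retrieved records whose label matches the query's
#' label. When the query itself is in the corpus it must be excluded from the
#' ranking (see `exclude_id` in [query_index()]).
#'
#' @param result An `hp_query_result` (or a tibble with an `id` column).
#' @param query_label The query's label.
#' @param corpus_labels Named vector mapping corpus id -> label.
#' @param k Cutoff; if fewer results are available, computed over those with
#'   attribute `truncated = TRUE`.
#' @return Numeric in `[0, 1]`.
#' @export
precision_at_k <- function(result, query_label, corpus_labels, k) {
  ranked <- if (inherits(result, "hp_query_result")) result$ranked else result
  ids <- head(ranked$id, k)
  truncated <- length(ids) < k
  out <- mean(corpus_labels[ids] == query_label)
  attr(out, "truncated") <- truncated
  out
}
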