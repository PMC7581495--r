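# Manifest I/O, feature extraction and fusion, the named method registry
# (feature-block ladders i..xv), and the cached pipeline runner.

#' Load a JSONL case manifest
#'
#' One JSON object per line with fields `id`, `image_path`, `text`,
#' `hashtags`, `pathologist_id`, and optional gold labels; unknown fields are
#' preserved. Duplicate ids are rejected; image paths are resolved relative
#' to the manifest at feature-extraction time (a missing file errors lazily,
#' naming the case).
#'
#' @param path Path to `manifest.jsonl`.
#' @return Tibble with one row per case; attribute `dir` holds the manifest
#'   directory.
#' @export
load_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(l, i) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE),
             error = function(e) {
               abort(paste0("malformed manifest row at line ", i, ": ",
                            conditionMessage(e)),
                     class = "histoprox_config_error")
             })
  })
  tbl <- dplyr::bind_rows(purrr::map(rows, function(r) {
    r <- purrr::map(r, function(v) if (length(v) > 1L) list(v) else v)
    if (!is.null(r$hashtags) && !is.list(r$hashtags)) {
      r$hashtags <- list(as.character(r$hashtags))
    }
    tibble::as_tibble(r)
  }))
  if (!"hashtags" %in% names(tbl)) tbl$hashtags <- list(character())
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate manifest id(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "histoprox_config_error")
  }
  attr(tbl, "dir") <- dirname(normalizePath(path))
  tbl
}

#' Write a manifest as JSONL
#'
#' @param manifest Tibble with at least `id`; list-columns are serialized as
#'   arrays.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  lines <- purrr::map_chr(seq_len(nrow(manifest)), function(i) {
    row <- as.list(manifest[i, ])
    row <- purrr::map(row, function(v) if (is.list(v)) unlist(v[[1L]]) else v)
    row <- purrr::discard(row, function(v) length(v) == 0L)
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

manifest_image <- function(manifest, i, dir = NULL) {
  dir <- dir %||% attr(manifest, "dir")
  p <- file.path(dir %||% ".", manifest$image_path[i])
  if (!file.exists(p)) {
    abort(paste0("image file missing for case '", manifest$id[i], "': ", p),
          class = "histoprox_read_error")
  }
  read_image_rgb(p)
}

#' Standardize every image in a manifest
#'
#' @param manifest Manifest tibble.
#' @param dir Image root (default: the manifest's `dir` attribute).
#' @return Named list of `hp_standard_image` objects, one per case id.
#' @export
standardize_cases <- function(manifest, dir = NULL) {
  out <- purrr::map(seq_len(nrow(manifest)), function(i) {
    standardize(manifest_image(manifest, i, dir), source_id = manifest$id[i])
  })
  setNames(out, manifest$id)
}

# --- feature extraction (tibbles keyed by id) --------------------------------

#' Extract the hand-engineered feature block for every case
#'
#' @param manifest Manifest tibble (or a named list of `hp_standard_image`).
#' @param dir Image root.
#' @param progress Print a dot every 25 cases.
#' @return Tibble: `id` + 2412 feature columns named per [feature_layout()].
#' @export
extract_hand_features <- function(manifest, dir = NULL, progress = FALSE) {
  with_std(manifest, dir, function(std, i) {
    if (progress && i %% 25L == 0L) cat(".")
    hand_features(std$crop512)
  })
}

with_std <- function(manifest, dir, f) {
  if (is.list(manifest) && !is.data.frame(manifest)) {
    ids <- names(manifest)
    vecs <- purrr::imap(unname(manifest), function(s, i) f(s, i))
  } else {
    ids <- manifest$id
    vecs <- purrr::map(seq_len(nrow(manifest)), function(i) {
      std <- standardize(manifest_image(manifest, i, dir),
                         source_id = manifest$id[i])
      f(std, i)
    })
  }
  m <- do.call(rbind, vecs)
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
}

#' Extract the covariate block (tissue one-hot with missingness + marker)
#'
#' Tissue columns are `NA` for every record whose tissue is missing (forest
#' consumption); [encode_covariates()] provides the all-zeros neural-network
#' view.
#'
#' @param manifest Manifest with `gold_tissue`/`gold_marker` or parsed
#'   `tissue`/`marker_mention` columns (gold preferred when both exist and
#'   `use_gold = TRUE`).
#' @param use_gold Prefer gold label columns when present.
#' @return Tibble: `id`, `tissue_<type>` (10 columns, 0/1 or `NA`), `marker`.
#' @export
extract_covariates <- function(manifest, use_gold = TRUE) {
  tis_col <- if (use_gold && "gold_tissue" %in% names(manifest)) "gold_tissue"
             else "tissue"
  mar_col <- if (use_gold && "gold_marker" %in% names(manifest)) "gold_marker"
             else "marker_mention"
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    tis <- manifest[[tis_col]][i]
    onehot <- if (is.na(tis)) rep(NA_real_, 10L)
              else as.numeric(tissue_types() == tis)
    c(setNames(onehot, paste0("tissue_", tissue_types())),
      marker = as.numeric(isTRUE(manifest[[mar_col]][i]) ||
                            identical(manifest[[mar_col]][i], 1)))
  })
  dplyr::bind_cols(tibble::tibble(id = manifest$id),
                   tibble::as_tibble(do.call(rbind, rows)))
}

#' Extract the 100-d sum-pooled deep-set block
#'
#' @param manifest Manifest (or named list of standardized images).
#' @param encoder An `hp_encoder`.
#' @param dir Image root.
#' @param covariates Optional matrix of per-case covariate vectors for the
#'   head input (rows matching the manifest).
#' @return Tibble: `id` + `deep_1..deep_100`.
#' @export
extract_deepset_features <- function(manifest, encoder, dir = NULL,
                                     covariates = NULL) {
  with_std(manifest, dir, function(std, i) {
    cov <- if (is.null(covariates)) NULL else covariates[i, ]
    setNames(set_sum(encoder, patch_grid(std), cov),
             paste0("deep_", seq_len(ENC_HEAD_DIM)))
  })
}

#' Extract the 2048-d sum-pooled generic-vision block
#'
#' @inheritParams extract_deepset_features
#' @param backbone Patch backbone, e.g. [generic_backbone_stub()].
#' @return Tibble: `id` + `gen_1..gen_2048`.
#' @export
extract_generic_features <- function(manifest, backbone = generic_backbone_stub(),
                                     dir = NULL) {
  with_std(manifest, dir, function(std, i) {
    setNames(pooled_generic(backbone, patch_grid(std)),
             paste0("gen_", seq_len(GENERIC_DIM)))
  })
}

#' Extract the bag-of-SIFT-clusters block
#'
#' @inheritParams extract_deepset_features
#' @param vocab Fitted [fit_sift_vocabulary()] (fit on training folds only).
#' @return Tibble: `id` + `sift_1..sift_k`.
#' @export
extract_sift_features <- function(manifest, vocab, dir = NULL) {
  k <- nrow(vocab$centroids)
  with_std(manifest, dir, function(std, i) {
    setNames(sift_bag(std$crop512, vocab), paste0("sift_", seq_len(k)))
  })
}

#' Fuse feature tibbles into one record matrix
#'
#' Joins per-block feature tibbles by `id` and returns the numeric matrix the
#' forest consumes, with a `block_layout` attribute naming each block's
#' column slice. Missing tissue stays `NA` (missing values, not zeros).
#'
#' @param ... Named feature tibbles (first column `id`), e.g.
#'   `hand = ..., tissue_marker = ...`.
#' @return Numeric matrix with rownames = ids and attribute `block_layout`.
#' @export
fuse_features <- function(...) {
  blocks <- list(...)
  stopifnot(length(blocks) > 0L, !is.null(names(blocks)))
  joined <- purrr::reduce(blocks, dplyr::inner_join, by = "id")
  m <- as.matrix(dplyr::select(joined, -"id"))
  rownames(m) <- joined$id
  lens <- purrr::map_int(blocks, function(b) ncol(b) - 1L)
  layout <- tibble::tibble(block = names(blocks), length = lens,
                           start = cumsum(c(1L, lens))[seq_along(lens)])
  attr(m, "block_layout") <- layout[, c("block", "start", "length")]
  m
}

# --- method registry (feature ladders i..xv) ---------------------------------

#' The named method registry
#'
#' The ladder of method configurations used for disease-state prediction and
#' search ablations: which feature blocks are fused, whether an ensemble of
#' three independently seeded encoder blocks is used, and whether prediction
#' comes straight from the encoder class head.
#'
#' @return Tibble: `method`, `blocks` (list), `ensemble`, `encoder_blocks`,
#'   `predictor`.
#' @export
method_registry <- function() {
  tibble::tibble(
    method = paste0("method_", c("i", "ii", "iii", "iv", "v", "vi", "vii",
                                 "viii", "ix", "x", "xi", "xii", "xiii",
                                 "xiv", "xv")),
    blocks = list(
      "hand",
      c("hand", "tissue"),
      c("hand", "tissue", "marker"),
      c("hand", "tissue", "marker", "sift"),
      "generic_center",
      character(),
      "deep_center",
      c("hand", "deepset"),
      c("hand", "tissue", "deepset"),
      c("hand", "tissue", "generic"),
      c("hand", "tissue", "deepset", "generic"),
      c("hand", "tissue", "deepset"),
      c("hand", "tissue", "deepset", "generic"),
      c("hand", "tissue", "marker", "deepset"),
      c("hand", "tissue", "marker", "deepset", "sift")),
    ensemble = c(rep(FALSE, 11L), rep(TRUE, 4L)),
    encoder_blocks = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L,
                       3L, 3L, 3L, 3L),
    predictor = c(rep("forest", 5L), "encoder_head", rep("forest", 9L))
  )
}

#' Run the pipeline for a named method
#'
#' Orchestrates: feature extraction for the method's blocks (encoder blocks
#' trained with independent seeds for ensembles), forest or ensemble
#' training, and evaluation under the requested protocol. Stage outputs are
#' cached by content hash under `cache_dir`, so reruns with identical inputs
#' are cache hits.
#'
#' @param manifest Manifest tibble (e.g. from [generate_dataset()]).
#' @param method Registry name (see [method_registry()]), or a character
#'   vector of block names for an ad-hoc single-forest method.
#' @param task `"disease"`, `"tissue"`, or `"stain"` (label column picked
#'   from gold labels).
#' @param protocol `"kfold"`, `"lopo"`, or `"none"` (train on everything,
#'   return the model).
#' @param n_trees,seed Forest settings.
#' @param dir Image root.
#' @param cache_dir Cache directory (`NULL` disables caching).
#' @param n_replicates,k Protocol settings.
#' @return List: `report` (`hp_eval_report` or `NULL`), `model`, `features`,
#'   `labels`, `method`.
#' @export
run_pipeline <- function(manifest, method = "method_iii", task = "disease",
                         protocol = "lopo", n_trees = 1000L, seed = 0L,
                         dir = NULL, cache_dir = NULL, n_replicates = 1L,
                         k = 10L) {
  dir <- dir %||% attr(manifest, "dir")
  reg <- method_registry()
  if (length(method) == 1L && method %in% reg$method) {
    row <- reg[reg$method == method, ]
    blocks <- row$blocks[[1L]]
    ensemble <- row$ensemble
    n_enc <- row$encoder_blocks
    predictor <- row$predictor
  } else {
    blocks <- method; ensemble <- FALSE; n_enc <- as.integer("deepset" %in% method)
    predictor <- "forest"
  }
  label_col <- switch(task, disease = "gold_disease", tissue = "gold_tissue",
                      stain = "gold_stain",
                      abort(paste0("unknown task '", task, "'"),
                            class = "histoprox_config_error"))
  y <- manifest[[label_col]]
  groups <- manifest$pathologist_id

  cache <- function(key, expr) {
    if (is.null(cache_dir)) return(expr())
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cache_dir, paste0(rlang::hash(key), ".rds"))
    if (file.exists(f)) return(readRDS(f))
    v <- expr()
    saveRDS(v, f)
    v
  }

  std <- NULL
  get_std <- function() {
    if (is.null(std)) std <<- standardize_cases(manifest, dir)
    std
  }
  block_tbl <- function(b, enc_seed = seed) {
    switch(b,
      hand = cache(list("hand", manifest$id),
                   function() extract_hand_features(get_std())),
      tissue = dplyr::select(extract_covariates(manifest), -"marker"),
      marker = dplyr::select(extract_covariates(manifest), "id", "marker"),
      sift = {
        vocab <- fit_sift_vocabulary(purrr::map(get_std(), "crop512"),
                                     seed = seed)
        extract_sift_features(get_std(), vocab)
      },
      generic = cache(list("generic", manifest$id, seed),
                      function() extract_generic_features(
                        get_std(), generic_backbone_stub(seed))),
      deepset = cache(list("deepset", manifest$id, enc_seed), function() {
        enc <- train_pipeline_encoder(manifest, get_std(), y, seed = enc_seed)
        extract_deepset_features(get_std(), enc)
      }),
      deep3 = {
        # the three most important deep features, ranked by permutation
        # importance of a forest on the deep-set block alone
        ds <- block_tbl("deepset", enc_seed)
        m <- as.matrix(dplyr::select(ds, -"id"))
        f_sel <- train_forest(m, y, n_trees = 100L, seed = seed)
        imp <- permutation_importance(f_sel, m, y, n_repeats = 3L,
                                      seed = seed)
        keep <- select_deep3(imp$importance[match(colnames(m), imp$feature)])
        dplyr::select(ds, "id", dplyr::all_of(colnames(m)[keep]))
      },
      generic_center = center_patch_block(get_std(), "generic", seed),
      deep_center = center_patch_block(get_std(), "deep", seed,
                                       manifest = manifest, y = y),
      abort(paste0("unknown feature block '", b, "'"),
            class = "histoprox_config_error"))
  }

  assemble <- function(enc_seed) {
    tbls <- purrr::map(blocks, block_tbl, enc_seed = enc_seed)
    do.call(fuse_features, setNames(tbls, blocks))
  }

  if (predictor == "encoder_head") {
    enc <- train_pipeline_encoder(manifest, get_std(), y, seed = seed)
    acts <- t(vapply(get_std(), function(s) {
      encode_patch_class(enc, center_patch(s))
    }, numeric(enc$n_classes)))
    colnames(acts) <- enc$training_meta$classes
    res <- multiclass_auroc(acts, y)
    report <- new_eval_report(task = task, protocol = "resubstitution",
                              per_replicate = tibble::tibble(replicate = 1L,
                                                             auroc = res$overall),
                              per_class = res$per_class,
                              overall = res$overall, overall_sd = NA_real_)
    return(list(report = report, model = enc, features = NULL, labels = y,
                method = method))
  }

  if (ensemble) {
    seeds_m <- seed + seq_len(max(1L, n_enc)) - 1L
    xs <- purrr::map(seeds_m, assemble)
    forests <- purrr::map2(xs, seeds_m, function(xm, sm) {
      train_forest(xm, y, n_trees = n_trees, seed = sm)
    })
    model <- forest_ensemble(forests)
    x <- xs[[1L]]
  } else {
    x <- assemble(seed)
    model <- NULL
  }

  report <- switch(protocol,
    none = NULL,
    kfold = kfold_replicates(x, y, k = k, n_replicates = n_replicates,
                             seeds = seed + seq_len(n_replicates) - 1L,
                             n_trees = n_trees, task = task),
    lopo = lopo_cv(x, y, groups, n_trees = n_trees,
                   seeds = seed + seq_len(n_replicates) - 1L, k_max = k,
                   task = task),
    abort(paste0("unknown protocol '", protocol, "'"),
          class = "histoprox_config_error"))

  if (is.null(model)) {
    model <- train_forest(x, y, n_trees = n_trees, seed = seed)
  }
  list(report = report, model = model, features = x, labels = y,
       method = method)
}

center_patch <- function(std) {
  r0 <- (STD_SIDE - PATCH_SIZE) %/% 2L
  std$crop512[(r0 + 1):(r0 + PATCH_SIZE), (r0 + 1):(r0 + PATCH_SIZE), ,
              drop = FALSE]
}

center_patch_block <- function(std_list, kind, seed, manifest = NULL, y = NULL) {
  ids <- names(std_list)
  if (kind == "generic") {
    backbone <- generic_backbone_stub(seed)
    m <- t(vapply(std_list, function(s) backbone(center_patch(s)),
                  numeric(GENERIC_DIM)))
    colnames(m) <- paste0("gen_", seq_len(GENERIC_DIM))
  } else {
    enc <- train_pipeline_encoder(manifest, std_list, y, seed = seed)
    m <- t(vapply(std_list, function(s) encode_patch(enc, center_patch(s)),
                  numeric(ENC_HEAD_DIM)))
    colnames(m) <- paste0("deep_", seq_len(ENC_HEAD_DIM))
  }
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
}

# desk-scale encoder training inside the pipeline: a few patches per image
train_pipeline_encoder <- function(manifest, std_list, y, seed = 0L,
                                   patches_per_image = 5L, epochs = 4L) {
  withr::with_seed(seed, {
    patches <- list(); labels <- character()
    for (i in seq_along(std_list)) {
      ps <- patch_grid(std_list[[i]])
      take <- sample(seq_along(ps$patches), patches_per_image)
      patches <- c(patches, ps$patches[take])
      labels <- c(labels, rep(y[i], patches_per_image))
    }
    train_encoder(patches, labels, epochs = epochs, seed = seed,
                  augment_cfg = NULL, mixup_prob = 0)
  })
}
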