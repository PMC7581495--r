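# Synthetic-corpus generator: renders stain/tissue/pathologist-tinted
# photomicrograph-like rasters whose disease-state signal is carried by
# nuclear texture statistics (blob density, size spread, pleomorphism), plus
# social-media-style case text that the rule-based labeler can invert.

#' Synthetic corpus configuration
#'
#' Defaults define the desk-scale study conditions: 300 images from 10
#' contributing pathologists, balanced over the three disease states, uniform
#' over the ten tissue types, stain mix 60% H&E-like / 30% IHC-like / 10%
#' other. The class signal is textural: nuclear blob density 100 / 225 / 400
#' per image for nontumor / low grade / malignant, with increasing size
#' spread and eccentricity variance (pleomorphism). Pathologist identity
#' perturbs global tint and gain (artifact strength 0.05), acting as a
#' confounder rather than a class signal.
#'
#' @param n_images Number of cases.
#' @param n_pathologists Number of contributing pathologists.
#' @param class_mix,tissue_mix,stain_mix Label proportions (must sum to 1).
#' @param densities Named blob counts per class.
#' @param size_mean Mean blob radius in px.
#' @param size_sd,ecc_sd Named per-class spread of radius and eccentricity.
#' @param artifact_strength Pathologist tint/gain jitter (0 disables).
#' @param text_noise Probability a text component is corrupted.
#' @param img_size Rendered image side in px (>= 512).
#' @param seed Integer seed.
#' @return A `hp_synth_config` list.
#' @export
synth_config <- function(n_images = 300L, n_pathologists = 10L,
                         class_mix = c(nontumor = 1, low_grade = 1, malignant = 1) / 3,
                         tissue_mix = setNames(rep(0.1, 10), tissue_types()),
                         stain_mix = c(HE = 0.6, IHC = 0.3, other = 0.1),
                         densities = c(nontumor = 100, low_grade = 225, malignant = 400),
                         size_mean = 7,
                         size_sd = c(nontumor = 1, low_grade = 2, malignant = 3.5),
                         ecc_sd = c(nontumor = 0.05, low_grade = 0.15, malignant = 0.35),
                         artifact_strength = 0.05, text_noise = 0,
                         img_size = 512L, seed = 0L) {
  stopifnot(n_images >= 1L, n_pathologists >= 1L, img_size >= 512L,
            abs(sum(class_mix) - 1) < 1e-8, abs(sum(tissue_mix) - 1) < 1e-8,
            abs(sum(stain_mix) - 1) < 1e-8)
  structure(list(n_images = as.integer(n_images),
                 n_pathologists = as.integer(n_pathologists),
                 class_mix = class_mix, tissue_mix = tissue_mix,
                 stain_mix = stain_mix, densities = densities,
                 size_mean = size_mean, size_sd = size_sd, ecc_sd = ecc_sd,
                 artifact_strength = artifact_strength,
                 text_noise = text_noise, img_size = as.integer(img_size),
                 seed = as.integer(seed)),
            class = "hp_synth_config")
}

stain_palette <- function(stain) {
  switch(stain,
    HE = list(bg = c(238, 215, 228), nuc = c(96, 60, 138)),
    IHC = list(bg = c(232, 222, 205), nuc = c(130, 85, 48)),
    other = list(bg = c(222, 222, 222), nuc = c(90, 90, 95)))
}

# deterministic per-pathologist tint and gain
pathologist_artifact <- function(pathologist_index, strength) {
  withr::with_seed(7000L + as.integer(pathologist_index), {
    list(tint = 1 + strength * rnorm(3), gain = 1 + strength * rnorm(1))
  })
}

#' Render one synthetic photomicrograph
#'
#' Background tinted by the stain palette and modulated by a tissue-specific
#' hue shift; elliptical "nuclei" stamped with class-dependent density, size
#' spread, and eccentricity; pathologist-specific global tint/gain applied
#' last. Uses the caller's RNG state — seed outside for reproducibility.
#'
#' @param class One of [disease_states()].
#' @param tissue One of [tissue_types()] (or `NA` for neutral hue).
#' @param stain One of [stain_types()].
#' @param artifact List from `pathologist_artifact()` or `NULL`.
#' @param cfg A [synth_config()].
#' @return `img_size x img_size x 3` array in `[0, 255]` with attribute
#'   `n_blobs`.
#' @export
render_image <- function(class, tissue, stain, artifact = NULL,
                         cfg = synth_config()) {
  pal <- stain_palette(stain)
  sz <- cfg$img_size
  img <- array(0, dim = c(sz, sz, 3L))
  # tissue hue: a small deterministic rotation of the background color
  tshift <- if (is.na(tissue)) c(0, 0, 0) else {
    i <- match(tissue, tissue_types())
    8 * c(cos(2 * pi * i / 10), cos(2 * pi * i / 10 + 2), cos(2 * pi * i / 10 + 4))
  }
  bg <- pal$bg + tshift
  for (c in 1:3) {
    img[, , c] <- bg[c] + matrix(rnorm(sz * sz, 0, 3), sz, sz)
  }
  n_blobs <- rpois(1, cfg$densities[[class]])
  a_mean <- cfg$size_mean
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 1, sz); cx <- runif(1, 1, sz)
    a <- max(2, rnorm(1, a_mean, cfg$size_sd[[class]]))
    ecc <- max(0.25, min(1, rnorm(1, 0.85, cfg$ecc_sd[[class]])))
    bb <- a * ecc
    th <- runif(1, 0, pi)
    shade <- runif(1, 0.75, 1.1)
    r0 <- max(1, floor(cy - a)); r1 <- min(sz, ceiling(cy + a))
    c0 <- max(1, floor(cx - a)); c1 <- min(sz, ceiling(cx + a))
    yy <- matrix((r0:r1) - cy, r1 - r0 + 1L, c1 - c0 + 1L)
    xx <- matrix((c0:c1) - cx, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
    u <- (cos(th) * xx + sin(th) * yy) / a
    v <- (-sin(th) * xx + cos(th) * yy) / bb
    mask <- (u^2 + v^2) <= 1
    if (!any(mask)) next
    for (c in 1:3) {
      sub <- img[r0:r1, c0:c1, c]
      sub[mask] <- pal$nuc[c] * shade
      img[r0:r1, c0:c1, c] <- sub
    }
  }
  if (!is.null(artifact)) {
    for (c in 1:3) img[, , c] <- img[, , c] * artifact$tint[c] * artifact$gain
  }
  img <- pmin(pmax(img, 0), 255)
  attr(img, "n_blobs") <- n_blobs
  img
}

tissue_hashtag <- function(tissue) {
  c(bone_soft_tissue = "bstpath", breast = "breastpath",
    dermatological = "dermpath", gastrointestinal = "gipath",
    genitourinary = "gupath", gynecological = "gynpath",
    head_neck = "entpath", hematological = "hemepath",
    neurological = "neuropath", pulmonary = "pulmpath")[[tissue]]
}

disease_phrases <- function(disease) {
  switch(disease,
    nontumor = c("inflammation in a biopsy", "normal tissue",
                 "granulation tissue", "colitis features"),
    low_grade = c("benign lesion", "carcinoma in situ",
                  "hyperplasia noted", "leiomyoma morphology"),
    malignant = c("invasive carcinoma", "malignant cells",
                  "adenocarcinoma infiltrating", "sarcoma suspected"))
}

#' Generate social-media-style case text from labels
#'
#' Emits hashtags and a short post that the rule-based labeler maps back to
#' the given labels with probability `1 - noise_rate` per component; marker
#' terms are inserted iff `marker_mention`. Uses the caller's RNG state.
#'
#' @param labels An `hp_case_labels` (or compatible list).
#' @param noise_rate Probability each label component is corrupted.
#' @return An [case_text()] object.
#' @export
generate_text <- function(labels, noise_rate = 0) {
  corrupt <- function(token) {
    if (noise_rate > 0 && runif(1) < noise_rate) "unremarkable field" else token
  }
  tags <- character()
  if (!is.na(labels$tissue)) tags <- c(tags, corrupt(tissue_hashtag(labels$tissue)))
  if (!is.na(labels$stain)) {
    tags <- c(tags, corrupt(switch(labels$stain, HE = "hestain",
                                   IHC = "ihcstain", other = "specialstain")))
  }
  phrase <- if (is.na(labels$disease)) "interesting case" else {
    corrupt(sample(disease_phrases(labels$disease), 1L))
  }
  post <- paste0("Case of the day: ", phrase, ".")
  if (isTRUE(labels$marker_mention)) {
    # marker terms chosen to not collide with the stain rule table
    post <- paste(post, sample(c("Desmin positive.", "Ki-67 elevated.",
                                 "CD34 highlights vessels."), 1L))
  }
  case_text(post_text = post, hashtags = tags[tags != "unremarkable field"])
}

# exact proportional allocation (largest remainder), deterministic
allocate_counts <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(mix))
}

#' Generate a synthetic corpus
#'
#' Draws labels from the configured mixes using an exact deterministic
#' allocation, renders every image, generates its case text, assigns
#' pathologists round-robin, writes PNGs plus a JSONL manifest, and returns
#' the manifest as a tibble (gold labels included for testing).
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed); images under
#'   `images/`, manifest at `manifest.jsonl`.
#' @return Tibble manifest: `id`, `image_path` (relative to `out_dir`),
#'   `text`, `hashtags` (list), `pathologist_id`, `gold_tissue`,
#'   `gold_disease`, `gold_stain`, `gold_marker`, `n_blobs`.
#' @export
generate_dataset <- function(cfg = synth_config(), out_dir = tempfile("synth")) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- cfg$n_images
  classes <- rep(names(cfg$class_mix), allocate_counts(n, cfg$class_mix))[seq_len(n)]
  withr::with_seed(cfg$seed, {
    classes <- sample(classes)      # case order carries no class information
    # assign tissue/stain within class strata so the mixes stay balanced
    # per class (tissue and stain carry no class information by construction)
    assign_stratified <- function(mix) {
      out <- character(n)
      for (cl in unique(classes)) {
        ii <- which(classes == cl)
        out[ii] <- sample(rep(names(mix),
                              allocate_counts(length(ii), mix))[seq_along(ii)])
      }
      out
    }
    tissues <- assign_stratified(cfg$tissue_mix)
    stains <- assign_stratified(cfg$stain_mix)
    marker <- rbinom(n, 1, 0.25) == 1
    pathologist <- rep_len(seq_len(cfg$n_pathologists), n)

    rows <- purrr::map(seq_len(n), function(i) {
      art <- if (cfg$artifact_strength > 0) {
        pathologist_artifact(pathologist[i], cfg$artifact_strength)
      } else NULL
      img <- render_image(classes[i], tissues[i], stains[i], art, cfg)
      rel <- file.path("images", sprintf("case_%04d.png", i))
      write_image_rgb(img, file.path(out_dir, rel))
      lab <- case_labels(tissue = tissues[i], disease = classes[i],
                         marker_mention = marker[i], stain = stains[i])
      txt <- generate_text(lab, cfg$text_noise)
      tibble::tibble(id = sprintf("case_%04d", i), image_path = rel,
                     text = txt$post_text, hashtags = list(txt$hashtags),
                     pathologist_id = sprintf("path_%02d", pathologist[i]),
                     gold_tissue = tissues[i], gold_disease = classes[i],
                     gold_stain = stains[i], gold_marker = marker[i],
                     n_blobs = attr(img, "n_blobs"))
    })
    manifest <- dplyr::bind_rows(rows)
    write_manifest(manifest, file.path(out_dir, "manifest.jsonl"))
    attr(manifest, "dir") <- out_dir
    manifest
  })
}
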