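# Shared fixtures, generated once per test run and cached in-session.

.fixture_env <- new.env(parent = emptyenv())

# small corpus: 24 images, 4 pathologists, balanced classes
small_corpus <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synth_config(n_images = 24L, n_pathologists = 4L, seed = 11L)
    man <- generate_dataset(cfg, out_dir = file.path(tempdir(), "hp_small"))
    .fixture_env$small <- list(cfg = cfg, manifest = man,
                               std = standardize_cases(man))
  }
  .fixture_env$small
}

small_hand_features <- function() {
  if (is.null(.fixture_env$small_hand)) {
    fx <- small_corpus()
    .fixture_env$small_hand <- extract_hand_features(fx$std)
  }
  .fixture_env$small_hand
}

# full-scale corpus at the documented study conditions (n = 300, 10
# pathologists, balanced 3 classes, seed 0) for the acceptance suite
full_corpus <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- synth_config(seed = 0L)
    man <- generate_dataset(cfg, out_dir = file.path(tempdir(), "hp_full"))
    .fixture_env$full <- list(cfg = cfg, manifest = man)
  }
  .fixture_env$full
}

full_features <- function() {
  if (is.null(.fixture_env$full_x)) {
    fx <- full_corpus()
    hand <- extract_hand_features(fx$manifest)
    .fixture_env$full_x <- fuse_features(
      hand = hand, cov = extract_covariates(fx$manifest))
  }
  .fixture_env$full_x
}

# deterministic textured test image: tinted background + seeded dark blobs
textured_image <- function(h = 512L, w = 512L, seed = 5L, n_dots = 150L) {
  withr::with_seed(seed, {
    img <- array(0, dim = c(h, w, 3L))
    base <- c(210, 190, 200)
    for (c in 1:3) img[, , c] <- base[c] + matrix(rnorm(h * w, 0, 4), h, w)
    for (d in seq_len(n_dots)) {
      cy <- sample.int(h - 12L, 1L) + 6L
      cx <- sample.int(w - 12L, 1L) + 6L
      r <- sample(3:6, 1L)
      ys <- (cy - r):(cy + r); xs <- (cx - r):(cx + r)
      mask <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2 <= r^2)
      for (c in 1:3) {
        sub <- img[ys, xs, c]
        sub[mask] <- c(70, 50, 110)[c]
        img[ys, xs, c] <- sub
      }
    }
    pmin(pmax(img, 0), 255)
  })
}

# tiny separable tabular problem for forest unit tests
toy_forest_data <- function(n = 120L, seed = 3L) {
  withr::with_seed(seed, {
    y <- sample(rep(c("a", "b"), length.out = n))
    x <- matrix(rnorm(n * 6L), n, 6L)
    x[, 1L] <- x[, 1L] + ifelse(y == "a", 2.5, -2.5)
    colnames(x) <- paste0("f", 1:6)
    list(x = x, y = y)
  })
}
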