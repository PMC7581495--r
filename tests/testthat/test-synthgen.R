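test_that("rendered images carry class signal in blob density, seeded", {
  cfg <- synth_config(n_images = 6, n_pathologists = 2, seed = 0)
  img_m <- withr::with_seed(3, render_image("malignant", "breast", "HE",
                                            cfg = cfg))
  img_n <- withr::with_seed(3, render_image("nontumor", "breast", "HE",
                                            cfg = cfg))
  expect_gt(attr(img_m, "n_blobs"), attr(img_n, "n_blobs"))
  expect_equal(dim(img_m), c(512L, 512L, 3L))
  expect_true(all(img_m >= 0 & img_m <= 255))

  # seed fixed -> bit-identical raster
  again <- withr::with_seed(3, render_image("malignant", "breast", "HE",
                                            cfg = cfg))
  expect_identical(img_m, again)

  # artifact strength 0: pathologist identity leaves pixels untouched
  a0 <- withr::with_seed(4, render_image("low_grade", "breast", "IHC",
                                         artifact = NULL, cfg = cfg))
  art <- histoprox:::pathologist_artifact(3, strength = 0)
  a1 <- withr::with_seed(4, render_image("low_grade", "breast", "IHC",
                                         artifact = art, cfg = cfg))
  expect_equal(a0, a1, ignore_attr = TRUE)
})

test_that("generated text inverts through the parser, with controlled noise", {
  labs <- case_labels(tissue = "pulmonary", disease = "malignant",
                      marker_mention = TRUE, stain = "IHC")
  tx <- withr::with_seed(1, generate_text(labs, noise_rate = 0))
  expect_equal(parse_tissue(tx), "pulmonary")
  expect_equal(parse_disease(tx), "malignant")
  expect_equal(parse_stain(tx), "IHC")
  expect_true(detect_marker(tx))

  # full corruption: parser returns missing or a mismatched label
  tx1 <- withr::with_seed(2, generate_text(labs, noise_rate = 1))
  t1 <- parse_tissue(tx1)
  expect_true(is.na(t1) || t1 != "pulmonary")

  # marker absent when not mentioned and stain words avoid the marker lexicon
  labs2 <- case_labels(tissue = "breast", disease = "nontumor",
                       marker_mention = FALSE, stain = "IHC")
  tx2 <- withr::with_seed(3, generate_text(labs2, noise_rate = 0))
  expect_false(detect_marker(tx2))
  expect_equal(parse_stain(tx2), "IHC")
})

test_that("dataset generation honors exact mixes, round-robin groups, determinism", {
  dir1 <- file.path(tempdir(), "synth_det1")
  dir2 <- file.path(tempdir(), "synth_det2")
  cfg <- synth_config(n_images = 60, n_pathologists = 5, seed = 9)
  man1 <- generate_dataset(cfg, dir1)
  man2 <- generate_dataset(cfg, dir2)

  expect_equal(unname(table(man1$gold_disease)), rep(20L, 3L),
               ignore_attr = TRUE)
  expect_equal(unname(table(man1$pathologist_id)), rep(12L, 5L),
               ignore_attr = TRUE)

  # same seed -> identical manifests and identical image bytes
  expect_equal(dplyr::select(man1, -"image_path"),
               dplyr::select(man2, -"image_path"), ignore_attr = TRUE)
  b1 <- readBin(file.path(dir1, man1$image_path[1]), "raw", 1e6)
  b2 <- readBin(file.path(dir2, man2$image_path[1]), "raw", 1e6)
  expect_identical(b1, b2)

  # manifest round-trips through JSONL
  rt <- load_manifest(file.path(dir1, "manifest.jsonl"))
  expect_equal(rt$id, man1$id)
  expect_equal(rt$gold_disease, man1$gold_disease)
  expect_equal(unlist(rt$hashtags[1]), unlist(man1$hashtags[1]))
})

test_that("class separability is monotone in the density gap", {
  # 3-point check on a tiny corpus: widen the nontumor/malignant density gap
  gaps <- list(c(170, 190, 210), c(120, 190, 260), c(60, 190, 320))
  prec <- purrr::map_dbl(seq_along(gaps), function(gi) {
    d <- gaps[[gi]]
    cfg <- synth_config(n_images = 18, n_pathologists = 3,
                        densities = c(nontumor = d[1], low_grade = d[2],
                                      malignant = d[3]),
                        seed = 2)
    man <- generate_dataset(cfg, file.path(tempdir(), paste0("gap", gi)))
    # gray-level summary features are enough to expose the texture signal
    x <- t(vapply(seq_len(nrow(man)), function(i) {
      img <- read_image_rgb(file.path(attr(man, "dir"), man$image_path[i]))
      g <- histoprox:::to_gray(img)
      c(mean(g), sd(as.vector(g)), mean(abs(diff(g))))
    }, numeric(3)))
    colnames(x) <- c("mean", "sd", "edge")
    rep <- lopo_cv(x, man$gold_disease, man$pathologist_id, n_trees = 100,
                   seeds = 0, k_max = 1)
    rep$overall
  })
  expect_true(all(diff(prec) >= -0.05))   # non-decreasing up to sampling noise
  expect_gt(prec[3], prec[1])
})

test_that("strong artifacts with no class signal expose pathologist leakage", {
  cfg <- synth_config(n_images = 30, n_pathologists = 3,
                      densities = c(nontumor = 150, low_grade = 150,
                                    malignant = 150),
                      size_sd = c(nontumor = 2, low_grade = 2, malignant = 2),
                      ecc_sd = c(nontumor = 0.1, low_grade = 0.1,
                                 malignant = 0.1),
                      artifact_strength = 0.25, seed = 6)
  man <- generate_dataset(cfg, file.path(tempdir(), "leak"))
  x <- t(vapply(seq_len(nrow(man)), function(i) {
    img <- read_image_rgb(file.path(attr(man, "dir"), man$image_path[i]))
    apply(img, 3, mean)                   # color means carry the tint artifact
  }, numeric(3)))
  colnames(x) <- c("r", "g", "b")
  # pathologist id is predictable from the tint...
  fp <- train_forest(x[1:24, ], man$pathologist_id[1:24], n_trees = 100,
                     seed = 0)
  acc_path <- mean(predict_class(fp, x[25:30, ]) == man$pathologist_id[25:30])
  expect_gt(acc_path, 0.6)
  # ...but the disease state is not (no class signal was rendered)
  fc <- train_forest(x[1:24, ], man$gold_disease[1:24], n_trees = 100,
                     seed = 0)
  acc_cls <- mean(predict_class(fc, x[25:30, ]) == man$gold_disease[25:30])
  expect_lt(acc_cls, 0.67)
})
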