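test_that("gray-world white balance equalizes channel means", {
  # uniform mid-gray image is a fixed point
  img <- array(128, dim = c(8, 8, 3))
  expect_identical(white_balance(img), img)

  # channel means (200, 150, 100) all map to the global mean 150
  img <- array(0, dim = c(16, 16, 3))
  img[, , 1] <- 200; img[, , 2] <- 150; img[, , 3] <- 100
  wb <- white_balance(img)
  expect_equal(apply(wb, 3, mean), rep(150, 3), tolerance = 1e-12)

  # random image: output channel means agree within 1 unit (clipping aside)
  img <- withr::with_seed(1, array(runif(32 * 32 * 3, 40, 200), dim = c(32, 32, 3)))
  wb <- white_balance(img)
  m <- apply(wb, 3, mean)
  expect_lt(max(m) - min(m), 1)
})

test_that("white balance warns and skips a zero-mean channel", {
  img <- array(100, dim = c(4, 4, 3))
  img[, , 3] <- 0
  expect_warning(out <- white_balance(img), "zero mean")
  expect_equal(out[, , 3], img[, , 3])
})

test_that("standardize scales min side to 512 and center-crops", {
  # 1024x2048 -> full 512x1024, crop spans columns 256..767 (0-based)
  img <- array(runif(64 * 128 * 3, 0, 255), dim = c(64, 128, 3))
  big <- standardize(histoprox:::resize_rgb(img, 1024, 2048))
  expect_equal(dim(big$full), c(512L, 1024L, 3L))
  expect_equal(dim(big$crop512), c(512L, 512L, 3L))
  expect_equal(big$crop512, big$full[, 257:768, , drop = FALSE])

  # square input: full == crop512
  sq <- standardize(textured_image(512, 512))
  expect_equal(sq$full, sq$crop512)

  # 600x800 -> long side rounds half-up to 683
  rect <- standardize(textured_image(600, 800))
  expect_equal(dim(rect$full)[1:2], c(512L, 683L))
})

test_that("standardize rejects too-small and malformed inputs", {
  expect_error(standardize(array(0, dim = c(32, 512, 3))),
               class = "histoprox_contract_error")
  expect_error(standardize(matrix(0, 512, 512)),
               class = "histoprox_read_error")
})

test_that("standardize is idempotent on its own output", {
  std <- standardize(textured_image(600, 800))
  again <- standardize(std$full)
  expect_equal(dim(again$full), dim(std$full))
  expect_equal(again$crop512, std$crop512, tolerance = 2)  # one resample pass
})

test_that("patch grid has 21 patches on a 5x5 lattice and covers the image", {
  g <- grid_offsets(512, 512)
  expect_equal(nrow(g), 25L)
  expect_setequal(unique(g$row0), c(0L, 72L, 144L, 216L, 288L))
  expect_equal(sum(g$evaluated), 21L)

  # wider image: larger column strides (less X overlap)
  g2 <- grid_offsets(512, 1024)
  expect_setequal(unique(g2$col0), c(0L, 200L, 400L, 600L, 800L))
  expect_gt(min(diff(sort(unique(g2$col0)))),
            min(diff(sort(unique(g$col0)))))

  std <- standardize(textured_image())
  ps <- patch_grid(std)
  expect_s3_class(ps, "hp_patch_set")
  expect_length(ps$patches, 21L)
  expect_true(all(vapply(ps$patches, function(p) all(dim(p) == c(224, 224, 3)),
                         logical(1))))
  # every patch fully inside, and union covers all pixels
  cov <- matrix(FALSE, 512, 512)
  for (i in seq_len(nrow(ps$offsets))) {
    r0 <- ps$offsets$row0[i]; c0 <- ps$offsets$col0[i]
    expect_true(r0 >= 0 && c0 >= 0 && r0 + 224 <= 512 && c0 + 224 <= 512)
    cov[(r0 + 1):(r0 + 224), (c0 + 1):(c0 + 224)] <- TRUE
  }
  expect_true(all(cov))
})

test_that("patch grid is a deterministic function of the geometry", {
  expect_identical(grid_offsets(512, 700), grid_offsets(512, 700))
})

test_that("augmentation honors identity, involution, and determinism", {
  patch <- textured_image(224, 224, seed = 9, n_dots = 40)
  off <- augment_config(p_rot90 = 0, p_small_rot = 0, p_flip = 0, p_zoom = 0,
                        p_brightness = 0, p_noise = 0)
  withr::with_seed(1, expect_identical(augment(patch, off), patch))

  # flip twice with the same axis restores the patch
  expect_identical(histoprox:::flip_rgb(histoprox:::flip_rgb(patch, "horizontal"), "horizontal"), patch)
  expect_identical(histoprox:::flip_rgb(histoprox:::flip_rgb(patch, "vertical"), "vertical"), patch)

  # fixed seed -> bit-identical augmented output
  cfg <- augment_config()
  a1 <- withr::with_seed(42, augment(patch, cfg))
  a2 <- withr::with_seed(42, augment(patch, cfg))
  expect_identical(a1, a2)

  # mixup returns a convex combination and its weight
  other <- textured_image(224, 224, seed = 10, n_dots = 40)
  mx <- withr::with_seed(3, augment(patch, off, mix_with = other))
  expect_true(mx$lambda >= 0 && mx$lambda <= 1)
  expect_equal(mx$patch, mx$lambda * patch + (1 - mx$lambda) * other,
               tolerance = 1e-12)
})
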