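# Image standardization, patch-grid sampling, and training-time augmentation.
#
# Rasters are exchanged as numeric arrays of dimension H x W x 3 with channel
# values on the 8-bit scale [0, 255]; coordinates are 0-based (row, col) with
# the origin at the top-left and half-open patch extents.

PATCH_SIZE <- 224L
STD_SIDE <- 512L
GRID_N <- 5L

#' Read an image file as an 8-bit RGB array
#'
#' Reads PNG or JPEG into the package's raster convention: a numeric
#' `H x W x 3` array with values in `[0, 255]`. Gray images are replicated
#' across channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg`, or `.jpeg` file.
#' @return Numeric array `H x W x 3` in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path), class = "histoprox_read_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      abort(paste0("unsupported image format: .", ext),
            class = "histoprox_read_error")
    ),
    error = function(e) {
      abort(paste0("failed to read image '", path, "': ", conditionMessage(e)),
            class = "histoprox_read_error")
    }
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) {
    abort("decoded raster is not 2- or 3-dimensional", class = "histoprox_read_error")
  }
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] != 3L) {
    abort("raster must have 3 color channels", class = "histoprox_read_error")
  }
  img * 255
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img Numeric array `H x W x 3` in `[0, 255]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}

#' Gray-world white balance
#'
#' Rescales each channel by (global mean / channel mean) so channel means are
#' equalized, correcting global color casts such as the blue shift of
#' under-lit photomicrographs. Output is clipped to `[0, 255]`, so means may
#' differ slightly after clipping.
#'
#' @param img Numeric array `H x W x 3` in `[0, 255]`.
#' @return White-balanced array of the same shape.
#' @examples
#' img <- array(128, dim = c(8, 8, 3))
#' identical(white_balance(img), img)
#' @export
white_balance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L, all(dim(img) > 0L))
  ch_means <- apply(img, 3L, mean)
  g_mean <- mean(ch_means)
  out <- img
  for (c in 1:3) {
    if (ch_means[c] <= 0) {
      warn(paste0("channel ", c, " has zero mean; white-balance gain skipped"))
      next
    }
    out[, , c] <- img[, , c] * (g_mean / ch_means[c])
  }
  pmin(pmax(out, 0), 255)
}

# Bilinear resample of one channel matrix to nrow2 x ncol2.
resize_bilinear_matrix <- function(m, nrow2, ncol2) {
  h <- nrow(m); w <- ncol(m)
  sy <- h / nrow2; sx <- w / ncol2
  # half-pixel-centre mapping, clamped to valid range
  ry <- pmin(pmax((seq_len(nrow2) - 0.5) * sy - 0.5, 0), h - 1)
  rx <- pmin(pmax((seq_len(ncol2) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- floor(ry); x0 <- floor(rx)
  wy <- ry - y0; wx <- rx - x0
  y0 <- pmin(y0 + 1, h); y1 <- pmin(y0 + 1, h)   # to 1-based with clamp
  x0 <- pmin(x0 + 1, w); x1 <- pmin(x0 + 1, w)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  d <- m[y1, x0, drop = FALSE]; e <- m[y1, x1, drop = FALSE]
  wyM <- matrix(wy, nrow2, ncol2)
  wxM <- matrix(wx, nrow2, ncol2, byrow = TRUE)
  (a * (1 - wyM) + d * wyM) * (1 - wxM) + (b * (1 - wyM) + e * wyM) * wxM
}

resize_rgb <- function(img, nrow2, ncol2) {
  out <- array(0, dim = c(nrow2, ncol2, 3L))
  for (c in 1:3) out[, , c] <- resize_bilinear_matrix(img[, , c], nrow2, ncol2)
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Standardize an image to the 512-px working geometry
#'
#' White-balances, bilinearly rescales so the shortest side is exactly 512 px
#' (aspect preserved, long side rounded half-up), and extracts the central
#' 512 x 512 crop (centering offset floored when the margin is odd).
#'
#' @param img Numeric `H x W x 3` array in `[0, 255]`, min side >= 64.
#' @param source_id Optional case identifier carried through the pipeline.
#' @return An object of class `hp_standard_image` with elements `full`
#'   (min side 512), `crop512` (512 x 512 x 3), and `source_id`.
#' @export
standardize <- function(img, source_id = NA_character_) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    abort("standardize() expects an H x W x 3 RGB raster",
          class = "histoprox_read_error")
  }
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (min(h, w) < 64L) {
    abort("image too small: min side must be >= 64 px",
          class = "histoprox_contract_error")
  }
  img <- white_balance(img)
  if (h <= w) {
    h2 <- STD_SIDE
    w2 <- as.integer(round_half_up(w * STD_SIDE / h))
  } else {
    w2 <- STD_SIDE
    h2 <- as.integer(round_half_up(h * STD_SIDE / w))
  }
  full <- if (h2 == h && w2 == w) img else resize_rgb(img, h2, w2)
  r0 <- floor((h2 - STD_SIDE) / 2)
  c0 <- floor((w2 - STD_SIDE) / 2)
  crop <- full[(r0 + 1):(r0 + STD_SIDE), (c0 + 1):(c0 + STD_SIDE), , drop = FALSE]
  structure(list(full = full, crop512 = crop, source_id = source_id),
            class = "hp_standard_image")
}

#' @export
print.hp_standard_image <- function(x, ...) {
  cat("<hp_standard_image> id:", x$source_id,
      " full:", paste(dim(x$full)[1:2], collapse = "x"),
      " crop: 512x512\n")
  invisible(x)
}

#' Grid offsets for the 21-patch set representation
#'
#' Candidate 224 x 224 patch offsets lie on a 5 x 5 grid with rows at
#' `linspace(0, H - 224, 5)` and columns at `linspace(0, W - 224, 5)`
#' (rounded half-up to integers). Four of the 25 slots — the interior
#' diagonal slots (2,2), (2,4), (4,2), (4,4) — are not evaluated, leaving 21
#' patches that still cover the full image for any standardized geometry.
#' Wider images give larger column strides, i.e. less horizontal overlap.
#'
#' @param h,w Full-image dimensions (min side must be 512).
#' @return A tibble with one row per 5x5 slot: `slot` (1..25, row-major),
#'   `grid_row`, `grid_col` (1..5), `row0`, `col0` (0-based top-left offsets),
#'   and `evaluated` (FALSE for the 4 dropped slots).
#' @export
grid_offsets <- function(h, w) {
  stopifnot(min(h, w) == STD_SIDE)
  rows <- as.integer(round_half_up(seq(0, h - PATCH_SIZE, length.out = GRID_N)))
  cols <- as.integer(round_half_up(seq(0, w - PATCH_SIZE, length.out = GRID_N)))
  g <- tidyr::expand_grid(grid_row = 1:GRID_N, grid_col = 1:GRID_N)
  g$slot <- (g$grid_row - 1L) * GRID_N + g$grid_col
  g$row0 <- rows[g$grid_row]
  g$col0 <- cols[g$grid_col]
  dropped <- c(7L, 9L, 17L, 19L)  # (2,2),(2,4),(4,2),(4,4) row-major
  g$evaluated <- !(g$slot %in% dropped)
  dplyr::select(g, "slot", "grid_row", "grid_col", "row0", "col0", "evaluated")
}

#' Sample the 21-patch set from a standardized image
#'
#' @param std An `hp_standard_image` from [standardize()].
#' @return An object of class `hp_patch_set`: list with `patches` (list of 21
#'   `224 x 224 x 3` arrays), `offsets` (tibble of the 21 evaluated slots),
#'   and `grid` (the full 25-slot tibble from [grid_offsets()]).
#' @export
patch_grid <- function(std) {
  stopifnot(inherits(std, "hp_standard_image"))
  h <- dim(std$full)[1L]; w <- dim(std$full)[2L]
  grid <- grid_offsets(h, w)
  offs <- dplyr::filter(grid, .data$evaluated)
  patches <- purrr::map2(offs$row0, offs$col0, function(r0, c0) {
    std$full[(r0 + 1):(r0 + PATCH_SIZE), (c0 + 1):(c0 + PATCH_SIZE), ,
             drop = FALSE]
  })
  structure(list(patches = patches, offsets = offs, grid = grid),
            class = "hp_patch_set")
}

#' @export
print.hp_patch_set <- function(x, ...) {
  cat("<hp_patch_set>", length(x$patches), "patches of 224x224\n")
  invisible(x)
}

# reflect-indexed bilinear sampler used by rotation/zoom augmentation
reflect_index <- function(i, n) {
  # reflect 0-based coordinates into [0, n-1]
  p <- 2 * (n - 1)
  i <- abs(i) %% p
  ifelse(i > (n - 1), p - i, i)
}

affine_sample <- function(img, angle_deg = 0, zoom = 1) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- angle_deg * pi / 180
  yy <- matrix(seq_len(h) - 1, h, w) - cy
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cx
  # inverse map: rotate by -theta and scale by 1/zoom
  sy <- ( cos(th) * yy - sin(th) * xx) / zoom + cy
  sx <- ( sin(th) * yy + cos(th) * xx) / zoom + cx
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  ya <- reflect_index(y0, h) + 1; yb <- reflect_index(y0 + 1, h) + 1
  xa <- reflect_index(x0, w) + 1; xb <- reflect_index(x0 + 1, w) + 1
  out <- img
  iaa <- cbind(as.vector(ya), as.vector(xa))
  iab <- cbind(as.vector(ya), as.vector(xb))
  iba <- cbind(as.vector(yb), as.vector(xa))
  ibb <- cbind(as.vector(yb), as.vector(xb))
  for (c in 1:3) {
    m <- img[, , c]
    v <- (m[iaa] * (1 - wy) + m[iba] * wy) * (1 - wx) +
         (m[iab] * (1 - wy) + m[ibb] * wy) * wx
    out[, , c] <- matrix(v, h, w)
  }
  out
}

#' Default augmentation configuration
#'
#' Training-time augmentation: right-angle rotation, small-angle rotation
#' (reflect padding), horizontal/vertical flips, zoom, brightness gain,
#' additive Gaussian noise, and Mixup. Magnitudes are on the 8-bit scale.
#'
#' @param p_rot90,p_small_rot,p_flip,p_zoom,p_brightness,p_noise Per-step
#'   application probabilities.
#' @param small_rot_deg Max absolute small-rotation angle (degrees).
#' @param zoom_range,brightness_range Two-element multiplicative ranges.
#' @param noise_sd Gaussian noise standard deviation (8-bit units).
#' @param mixup_alpha Beta(alpha, alpha) parameter for Mixup weights.
#' @return A named list of augmentation parameters.
#' @export
augment_config <- function(p_rot90 = 0.5, p_small_rot = 0.25, p_flip = 0.5,
                           p_zoom = 0.25, p_brightness = 0.5, p_noise = 0.5,
                           small_rot_deg = 15, zoom_range = c(0.9, 1.1),
                           brightness_range = c(0.9, 1.1), noise_sd = 2.5,
                           mixup_alpha = 0.2) {
  list(p_rot90 = p_rot90, p_small_rot = p_small_rot, p_flip = p_flip,
       p_zoom = p_zoom, p_brightness = p_brightness, p_noise = p_noise,
       small_rot_deg = small_rot_deg, zoom_range = zoom_range,
       brightness_range = brightness_range, noise_sd = noise_sd,
       mixup_alpha = mixup_alpha)
}

rot90_rgb <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2L]:1, , , drop = FALSE]
  }
  img
}

flip_rgb <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") img[, dim(img)[2L]:1, , drop = FALSE]
  else img[dim(img)[1L]:1, , , drop = FALSE]
}

#' Augment one patch
#'
#' Applies, in fixed order, right-angle rotation, small rotation, flip, zoom,
#' brightness, and Gaussian noise, each with its configured probability, using
#' the caller's RNG state (seed outside for reproducibility). If `mix_with` is
#' supplied, returns the Mixup convex combination and its weight `lambda`
#' drawn from `Beta(alpha, alpha)`.
#'
#' @param patch `224 x 224 x 3` array in `[0, 255]`.
#' @param config From [augment_config()].
#' @param mix_with Optional second patch for Mixup.
#' @return The augmented patch; with Mixup, a list `(patch, lambda)`.
#' @export
augment <- function(patch, config = augment_config(), mix_with = NULL) {
  p <- patch
  if (runif(1) < config$p_rot90) p <- rot90_rgb(p, sample.int(4L, 1L) - 1L)
  if (runif(1) < config$p_small_rot && config$small_rot_deg > 0) {
    p <- affine_sample(p, angle_deg = runif(1, -config$small_rot_deg,
                                            config$small_rot_deg))
  }
  if (runif(1) < config$p_flip) {
    p <- flip_rgb(p, sample(c("horizontal", "vertical"), 1L))
  }
  if (runif(1) < config$p_zoom) {
    z <- runif(1, config$zoom_range[1], config$zoom_range[2])
    if (z != 1) p <- affine_sample(p, zoom = z)
  }
  if (runif(1) < config$p_brightness) {
    p <- p * runif(1, config$brightness_range[1], config$brightness_range[2])
  }
  if (runif(1) < config$p_noise && config$noise_sd > 0) {
    p <- p + array(rnorm(length(p), 0, config$noise_sd), dim = dim(p))
  }
  p <- pmin(pmax(p, 0), 255)
  if (!is.null(mix_with)) {
    lam <- rbeta(1, config$mixup_alpha, config$mixup_alpha)
    list(patch = lam * p + (1 - lam) * mix_with, lambda = lam)
  } else {
    p
  }
}
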