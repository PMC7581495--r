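# Scale-invariant keypoint features: difference-of-Gaussian detector,
# 4x4x8 gradient-orientation descriptors, a small k-means vocabulary, and the
# L1-normalized bag-of-clusters histogram used as the "SIFT_k5" feature block.

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with reflected edges
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  n <- nrow(m); w <- ncol(m)
  idx <- function(i, nn) pmin(pmax(i, 1L), nn)  # clamp padding
  out <- matrix(0, n, w)
  for (t in seq_along(k)) out <- out + k[t] * m[idx(seq_len(n) + t - 1L - r, n), , drop = FALSE]
  m2 <- out
  out <- matrix(0, n, w)
  for (t in seq_along(k)) out <- out + k[t] * m2[, idx(seq_len(w) + t - 1L - r, w), drop = FALSE]
  out
}

grad_xy <- function(m) {
  n <- nrow(m); w <- ncol(m)
  gx <- (m[, c(2:w, w), drop = FALSE] - m[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

bilinear_at <- function(m, y, x) {
  n <- nrow(m); w <- ncol(m)
  y <- pmin(pmax(y, 1), n); x <- pmin(pmax(x, 1), w)
  y0 <- pmin(floor(y), n - 1L); x0 <- pmin(floor(x), w - 1L)
  wy <- y - y0; wx <- x - x0
  m[cbind(y0, x0)] * (1 - wy) * (1 - wx) +
    m[cbind(y0, x0 + 1)] * (1 - wy) * wx +
    m[cbind(y0 + 1, x0)] * wy * (1 - wx) +
    m[cbind(y0 + 1, x0 + 1)] * wy * wx
}

#' Detect scale-space keypoints
#'
#' Difference-of-Gaussian extrema over a small scale space (3 octaves, 3
#' scales per octave, base sigma 1.6), with a contrast threshold and a cap on
#' the number of keypoints (strongest response kept).
#'
#' @param gray Numeric matrix in `[0, 255]`.
#' @param contrast_threshold Minimum absolute DoG response (8-bit scale).
#' @param max_keypoints Cap on returned keypoints.
#' @return Tibble: `row`, `col` (1-based, base-image scale), `sigma`,
#'   `octave`, `response`.
#' @export
sift_keypoints <- function(gray, contrast_threshold = 2.0, max_keypoints = 200L) {
  n_oct <- 3L; n_scl <- 3L; sigma0 <- 1.6; kfac <- 2^(1 / n_scl)
  kps <- list()
  img <- gray
  for (o in seq_len(n_oct)) {
    if (min(dim(img)) < 16L) break
    sig <- sigma0 * kfac^(0:(n_scl + 1L))
    gs <- purrr::map(sig, function(s) gauss_blur(img, s))
    dog <- purrr::map(seq_len(n_scl + 1L), function(i) gs[[i + 1L]] - gs[[i]])
    for (s in 2:n_scl) {
      d <- dog[[s]]
      nr <- nrow(d); nc <- ncol(d)
      ri <- 2:(nr - 1); ci <- 2:(nc - 1)
      center <- d[ri, ci]
      nb_max <- nb_min <- NULL
      for (lay in (s - 1):(s + 1)) {
        dd <- dog[[lay]]
        for (oy in -1:1) for (ox in -1:1) {
          if (lay == s && oy == 0 && ox == 0) next
          v <- dd[ri + oy, ci + ox]
          nb_max <- if (is.null(nb_max)) v else pmax(nb_max, v)
          nb_min <- if (is.null(nb_min)) v else pmin(nb_min, v)
        }
      }
      is_ext <- (center > nb_max | center < nb_min) &
        abs(center) >= contrast_threshold
      if (any(is_ext)) {
        w <- which(is_ext, arr.ind = TRUE)
        kps[[length(kps) + 1L]] <- tibble::tibble(
          row = (w[, 1] + 1L) * 2^(o - 1L),
          col = (w[, 2] + 1L) * 2^(o - 1L),
          sigma = sigma0 * kfac^(s - 1L) * 2^(o - 1L),
          octave = o,
          response = abs(center[is_ext])
        )
      }
    }
    img <- resize_bilinear_matrix(img, floor(nrow(img) / 2), floor(ncol(img) / 2))
  }
  if (length(kps) == 0L) {
    return(tibble::tibble(row = integer(), col = integer(), sigma = numeric(),
                          octave = integer(), response = numeric()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(kps), dplyr::desc(.data$response))
  head(out, max_keypoints)
}

# 128-d descriptor: 4x4 spatial cells x 8 orientation bins, rotated to the
# keypoint's dominant orientation, trilinear-free (hard-binned) variant.
sift_descriptor_one <- function(gx, gy, row, col, sigma) {
  # dominant orientation from a Gaussian-weighted 36-bin histogram
  r <- max(3L, round(4.5 * sigma))
  ys <- pmin(pmax(round(row) + (-r:r), 1L), nrow(gx))
  xs <- pmin(pmax(round(col) + (-r:r), 1L), ncol(gx))
  subx <- gx[ys, xs]; suby <- gy[ys, xs]
  mag <- sqrt(subx^2 + suby^2)
  wgt <- outer(exp(-(-r:r)^2 / (2 * (1.5 * sigma)^2)),
               exp(-(-r:r)^2 / (2 * (1.5 * sigma)^2)))
  th <- atan2(suby, subx)
  ob <- pmin(floor((th + pi) / (2 * pi) * 36), 35) + 1L
  oh <- unname(tapply(as.vector(mag * wgt), factor(ob, levels = 1:36), sum,
                      default = 0))
  main <- (which.max(oh) - 0.5) / 36 * 2 * pi - pi

  # 16x16 sample grid in the rotated frame, cell width 0.75*sigma
  step <- 0.75 * sigma
  u <- rep(seq(-7.5, 7.5, length.out = 16), each = 16)
  v <- rep(seq(-7.5, 7.5, length.out = 16), times = 16)
  dy <- step * (sin(main) * u + cos(main) * v)
  dx <- step * (cos(main) * u - sin(main) * v)
  sy <- row + dy; sx <- col + dx
  gxs <- bilinear_at(gx, sy, sx); gys <- bilinear_at(gy, sy, sx)
  m <- sqrt(gxs^2 + gys^2) * exp(-(u^2 + v^2) / (2 * 8^2))
  a <- atan2(gys, gxs) - main
  a <- (a + 2 * pi) %% (2 * pi)
  obin <- pmin(floor(a / (2 * pi) * 8), 7L)
  cell <- (pmin(floor((u + 8) / 4), 3L)) * 4L + pmin(floor((v + 8) / 4), 3L)
  idx <- cell * 8L + obin + 1L
  d <- unname(tapply(m, factor(idx, levels = 1:128), sum, default = 0))
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d <- pmin(d, 0.2)
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d
}

#' Compute keypoint descriptors for a gray image
#'
#' @inheritParams sift_keypoints
#' @return List with `keypoints` (tibble) and `descriptors`
#'   (`n x 128` matrix; 0 rows when no keypoints).
#' @export
sift_describe <- function(gray, contrast_threshold = 2.0, max_keypoints = 200L) {
  kp <- sift_keypoints(gray, contrast_threshold, max_keypoints)
  if (nrow(kp) == 0L) {
    return(list(keypoints = kp, descriptors = matrix(0, 0, 128)))
  }
  g <- grad_xy(gray)
  desc <- t(vapply(seq_len(nrow(kp)), function(i) {
    sift_descriptor_one(g$gx, g$gy, kp$row[i], kp$col[i], kp$sigma[i])
  }, numeric(128)))
  list(keypoints = kp, descriptors = desc)
}

#' Fit the k-cluster SIFT vocabulary on training crops
#'
#' Pools keypoint descriptors over the supplied training crops and runs
#' seeded k-means; centroids are ordered by descending assigned-descriptor
#' count, so the first centroid is the most prevalent visual word. Fit only
#' on training-fold images to avoid leakage into held-out groups.
#'
#' @param crops List of `512 x 512 x 3` crops (or `hp_standard_image`s).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for k-means.
#' @return Object of class `hp_sift_vocab`: `centroids` (`k x 128`),
#'   `sizes`, `seed`, `fit_hash`.
#' @export
fit_sift_vocabulary <- function(crops, k = 5L, seed = 0L) {
  descs <- purrr::map(crops, function(cr) {
    if (inherits(cr, "hp_standard_image")) cr <- cr$crop512
    sift_describe(to_gray(cr))$descriptors
  })
  d <- do.call(rbind, descs)
  if (is.null(d) || nrow(d) < k) {
    abort(paste0("only ", if (is.null(d)) 0L else nrow(d), " descriptors found; ",
                 "need at least k = ", k,
                 " — supply more (or more textured) training crops"),
          class = "histoprox_contract_error")
  }
  km <- withr::with_seed(seed, kmeans(d, centers = k, nstart = 5L,
                                      iter.max = 50L))
  ord <- order(km$size, decreasing = TRUE)
  structure(list(centroids = km$centers[ord, , drop = FALSE],
                 sizes = km$size[ord], seed = seed,
                 fit_hash = rlang::hash(d)),
            class = "hp_sift_vocab")
}

#' @export
print.hp_sift_vocab <- function(x, ...) {
  cat("<hp_sift_vocab>", nrow(x$centroids), "centroids, sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Persist a SIFT vocabulary as JSON (centroids + seed + training hash)
#'
#' @param vocab An `hp_sift_vocab`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "hp_sift_vocab"))
  jsonlite::write_json(list(centroids = unname(as.matrix(vocab$centroids)),
                            sizes = vocab$sizes, seed = vocab$seed,
                            fit_hash = vocab$fit_hash),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centroids = matrix(as.numeric(p$centroids),
                                    nrow = nrow(p$centroids)),
                 sizes = as.integer(p$sizes), seed = as.integer(p$seed),
                 fit_hash = p$fit_hash),
            class = "hp_sift_vocab")
}

#' Bag-of-clusters histogram for one crop
#'
#' Assigns each keypoint descriptor to its nearest vocabulary centroid and
#' returns the L1-normalized k-bin histogram; the zero vector when the crop
#' has no keypoints.
#'
#' @param crop `512 x 512 x 3` array (or `hp_standard_image`).
#' @param vocab Fitted [fit_sift_vocabulary()] object.
#' @return Numeric vector of length `k` summing to 1 (or all zero).
#' @export
sift_bag <- function(crop, vocab) {
  stopifnot(inherits(vocab, "hp_sift_vocab"))
  if (inherits(crop, "hp_standard_image")) crop <- crop$crop512
  d <- sift_describe(to_gray(crop))$descriptors
  k <- nrow(vocab$centroids)
  if (nrow(d) == 0L) return(rep(0, k))
  # squared distances to centroids
  cc <- vocab$centroids
  d2 <- outer(rowSums(d^2), rep(1, k)) - 2 * d %*% t(cc) +
    outer(rep(1, nrow(d)), rowSums(cc^2))
  assign <- max.col(-d2, ties.method = "first")
  h <- tabulate(assign, nbins = k)
  h / sum(h)
}
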