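# Task-agnostic hand-engineered feature bank: 2412 dimensions over the
# 512 x 512 center crop. Block layout is fixed and exposed programmatically.

#' Hand-engineered feature block layout
#'
#' The fixed composition of the 2412-dimensional feature bank:
#' per-channel 256-bin RGB and HSV histograms, a 256-bin gray histogram,
#' rotation-invariant uniform local binary patterns at (P,R) in
#' \{(8,1),(16,2),(24,3)\} over a 6-level half-resolution pyramid (the "LBP
#' pyramid"), 36-bin gradient-orientation histograms over the same pyramid,
#' 13 gray-level co-occurrence (Haralick) statistics at 4 offsets, 7 moment
#' invariants, and mean/sd/entropy for 7 channels. Lengths sum to 2412.
#'
#' @return Tibble with columns `block`, `start`, `length` (1-based slices).
#' @examples
#' sum(feature_layout()$length) == 2412
#' @export
feature_layout <- function() {
  blocks <- tibble::tribble(
    ~block,          ~length,
    "rgb_hist",       768L,
    "hsv_hist",       768L,
    "gray_hist",      256L,
    "lbp_pyramid",    324L,
    "sobel_orient",   216L,
    "glcm",            52L,
    "hu_moments",       7L,
    "channel_stats",   21L
  )
  blocks$start <- cumsum(c(1L, blocks$length))[seq_len(nrow(blocks))]
  blocks[, c("block", "start", "length")]
}

HAND_DIM <- 2412L

hist_norm <- function(x, breaks) {
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                     length(breaks) - 1L),
                nbins = length(breaks) - 1L)
  s <- sum(h)
  if (s > 0) h / s else rep(0, length(h))
}

hist256 <- function(ch) {
  # ch in [0, 255]
  h <- tabulate(pmin(floor(ch), 255) + 1L, nbins = 256L)
  h / sum(h)
}

to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

rgb_to_hsv_channels <- function(img) {
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = hsv[1, ], s = hsv[2, ], v = hsv[3, ])
}

# --- local binary patterns ---------------------------------------------------

# rotation-invariant uniform LBP histogram (P + 2 bins, L1-normalized)
lbp_riu2_hist <- function(gray, P, R) {
  n <- nrow(gray); m <- ncol(gray)
  ri <- (R + 1):(n - R); ci <- (R + 1):(m - R)
  if (length(ri) < 1L || length(ci) < 1L) return(rep(0, P + 2L))
  center <- gray[ri, ci, drop = FALSE]
  bits <- vector("list", P)
  for (k in 0:(P - 1L)) {
    a <- 2 * pi * k / P
    dy <- -R * sin(a); dx <- R * cos(a)
    y0 <- floor(dy + 1e-9); x0 <- floor(dx + 1e-9)
    wy <- dy - y0; wx <- dx - x0
    if (wy < 1e-9) wy <- 0
    if (wx < 1e-9) wx <- 0
    y1 <- if (wy > 0) y0 + 1L else y0   # avoid indexing past the margin
    x1 <- if (wx > 0) x0 + 1L else x0   # when the offset is integral
    sub <- function(oy, ox) gray[ri + oy, ci + ox, drop = FALSE]
    nb <- (1 - wy) * (1 - wx) * sub(y0, x0) +
          (1 - wy) * wx       * sub(y0, x1) +
          wy       * (1 - wx) * sub(y1, x0) +
          wy       * wx       * sub(y1, x1)
    # small tolerance keeps exact ties (flat regions) stable under the
    # floating-point wobble of interpolation
    bits[[k + 1L]] <- (nb - center >= -1e-6) * 1L
  }
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, purrr::map(seq_len(P), function(k) {
    abs(bits[[k]] - bits[[if (k == P) 1L else k + 1L]])
  }))
  code <- ifelse(trans <= 2L, ones, P + 1L)
  h <- tabulate(code + 1L, nbins = P + 2L)
  h / sum(h)
}

half_pyramid <- function(gray, n_levels = 6L) {
  levels <- vector("list", n_levels)
  cur <- resize_bilinear_matrix(gray, floor(nrow(gray) / 2), floor(ncol(gray) / 2))
  for (i in seq_len(n_levels)) {
    levels[[i]] <- cur
    if (i < n_levels) {
      cur <- resize_bilinear_matrix(cur, max(4L, floor(nrow(cur) / 2)),
                                    max(4L, floor(ncol(cur) / 2)))
    }
  }
  levels
}

sobel_gradients <- function(gray) {
  n <- nrow(gray); m <- ncol(gray)
  pad <- rbind(gray[1, , drop = FALSE], gray, gray[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, m, drop = FALSE])
  s <- function(oy, ox) pad[(2 + oy):(n + 1 + oy), (2 + ox):(m + 1 + ox), drop = FALSE]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy)
}

orientation_hist36 <- function(gray) {
  g <- sobel_gradients(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  keep <- mag > 1e-9
  if (!any(keep)) return(rep(0, 36))
  th <- atan2(g$gy[keep], g$gx[keep])          # [-pi, pi]
  bin <- pmin(floor((th + pi) / (2 * pi) * 36), 35) + 1L
  h <- unname(tapply(mag[keep], factor(bin, levels = 1:36), sum, default = 0))
  h / sum(h)
}

# --- gray-level co-occurrence (Haralick) -------------------------------------

glcm_matrix <- function(q, dy, dx, n_levels) {
  n <- nrow(q); m <- ncol(q)
  r1 <- max(1, 1 - dy):min(n, n - dy)
  c1 <- max(1, 1 - dx):min(m, m - dx)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  counts <- tabulate((a - 1L) * n_levels + b, nbins = n_levels * n_levels)
  p <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  p <- p + t(p)                                 # symmetric GLCM
  p / sum(p)
}

haralick13 <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  eps <- 1e-12
  # p_{x+y}(k), k = 2..2ng ; p_{x-y}(k), k = 0..ng-1
  pxy_sum <- unname(tapply(as.vector(p), as.vector(i + j), sum))
  pxy_dif <- unname(tapply(as.vector(p), as.vector(abs(i - j)), sum))
  ks <- as.numeric(names(tapply(as.vector(p), as.vector(i + j), sum)))
  kd <- as.numeric(names(tapply(as.vector(p), as.vector(abs(i - j)), sum)))
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sdx > eps && sdy > eps) {
    (sum(i * j * p) - mux * muy) / (sdx * sdy)
  } else 0
  variance <- sum((i - mux)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_avg <- sum(ks * pxy_sum)
  sum_ent <- -sum(pxy_sum * log(pxy_sum + eps))
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  entropy <- -sum(p * log(p + eps))
  dif_avg <- sum(kd * pxy_dif)
  dif_var <- sum((kd - dif_avg)^2 * pxy_dif)
  dif_ent <- -sum(pxy_dif * log(pxy_dif + eps))
  hx <- -sum(px * log(px + eps)); hy <- -sum(py * log(py + eps))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log(pxpy + eps))
  hxy2 <- -sum(pxpy * log(pxpy + eps))
  imc1 <- if (max(hx, hy) > eps) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm, contrast, correlation, variance, idm, sum_avg, sum_var, sum_ent,
    entropy, dif_var, dif_ent, imc1, imc2)
}

glcm_block <- function(gray, n_levels = 32L) {
  q <- pmin(floor(gray / 256 * n_levels), n_levels - 1L) + 1L
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))  # 0,45,90,135 deg
  unlist(purrr::map(offsets, function(o) {
    haralick13(glcm_matrix(q, o[1], o[2], n_levels))
  }))
}

# --- moment invariants -------------------------------------------------------

hu_moments <- function(gray) {
  n <- nrow(gray); m <- ncol(gray)
  y <- matrix(seq_len(n) - 1, n, m)
  x <- matrix(seq_len(m) - 1, n, m, byrow = TRUE)
  m00 <- sum(gray)
  if (m00 <= 0) return(rep(0, 7))
  xb <- sum(x * gray) / m00; yb <- sum(y * gray) / m00
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * gray)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
  # signed log scale keeps magnitudes comparable across images
  ifelse(abs(h) > 1e-300, -sign(h) * log10(abs(h)), 0)
}

shannon_entropy256 <- function(x01) {
  h <- tabulate(pmin(floor(x01 * 256), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Compute the 2412-dimensional hand-engineered feature bank
#'
#' @param crop A `512 x 512 x 3` array in `[0, 255]` (the standardized center
#'   crop), or an `hp_standard_image` whose `crop512` is used.
#' @return Named numeric vector of length 2412; names are
#'   `<block>_<index>` following [feature_layout()].
#' @export
hand_features <- function(crop) {
  if (inherits(crop, "hp_standard_image")) crop <- crop$crop512
  d <- dim(crop)
  if (length(d) != 3L || d[1] != 512L || d[2] != 512L || d[3] != 3L) {
    abort("hand_features() expects a 512 x 512 x 3 crop",
          class = "histoprox_contract_error")
  }
  gray <- to_gray(crop)
  hsv <- rgb_to_hsv_channels(crop)

  rgb_hist <- c(hist256(crop[, , 1]), hist256(crop[, , 2]), hist256(crop[, , 3]))
  hsv_hist <- c(hist256(hsv$h * 255.999), hist256(hsv$s * 255.999),
                hist256(hsv$v * 255.999))
  gray_hist <- hist256(gray)

  pyr <- half_pyramid(gray, 6L)
  lbp <- unlist(purrr::map(pyr, function(g) {
    c(lbp_riu2_hist(g, 8L, 1L), lbp_riu2_hist(g, 16L, 2L), lbp_riu2_hist(g, 24L, 3L))
  }))
  sob <- unlist(purrr::map(pyr, orientation_hist36))

  glcm <- glcm_block(gray)
  hu <- hu_moments(gray)

  chans <- list(crop[, , 1] / 255, crop[, , 2] / 255, crop[, , 3] / 255,
                hsv$h, hsv$s, hsv$v, gray / 255)
  stats3 <- unlist(purrr::map(chans, function(ch) {
    c(mean(ch), sd(as.vector(ch)), shannon_entropy256(pmin(pmax(ch, 0), 1)))
  }))

  v <- c(rgb_hist, hsv_hist, gray_hist, lbp, sob, glcm, hu, stats3)
  stopifnot(length(v) == HAND_DIM)
  v[!is.finite(v)] <- 0
  layout <- feature_layout()
  names(v) <- unlist(purrr::map2(layout$block, layout$length,
                                 function(b, l) paste0(b, "_", seq_len(l))))
  v
}
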