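# Pluggable patch encoder: a deterministic convolutional featurizer over the
# 224 x 224 patch, a trainable fully-connected network with a 100-unit
# approximately-binary head and a 3-way softmax class head (covariates
# concatenated into the head input), the 21-patch sum-pooled set
# representation, and a 2048-d generic-vision stub backbone.

ENC_HEAD_DIM <- 100L
GENERIC_DIM <- 2048L

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Fixed convolutional front end: the patch is bilinearly downsampled to
# 32 x 32, a small filter bank (smoothing, horizontal/vertical Sobel,
# Laplacian) is applied to the gray plane, and responses plus raw color are
# average-pooled over a 4x4 spatial grid. Linear and bias-free, so a zero
# patch maps to the zero vector. 7 planes x 16 cells = 112 dims.
patch_summary <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L) {
    abort("patch must be H x W x 3", class = "histoprox_contract_error")
  }
  small <- resize_rgb(patch, 32L, 32L) / 255
  gray <- to_gray(small * 255) / 255
  g <- sobel_gradients(gray)
  lap <- {
    n <- nrow(gray); m <- ncol(gray)
    pad <- rbind(gray[1, , drop = FALSE], gray, gray[n, , drop = FALSE])
    pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, m, drop = FALSE])
    s <- function(oy, ox) pad[(2 + oy):(n + 1 + oy), (2 + ox):(m + 1 + ox)]
    s(-1, 0) + s(1, 0) + s(0, -1) + s(0, 1) - 4 * gray
  }
  planes <- list(small[, , 1], small[, , 2], small[, , 3],
                 gray, abs(g$gx) / 4, abs(g$gy) / 4, abs(lap))
  pool4 <- function(m) {
    idx <- rep(1:4, each = 8L)
    as.vector(t(rowsum(t(rowsum(m, idx)), idx))) / 64
  }
  unlist(purrr::map(planes, pool4), use.names = FALSE)
}

PATCH_SUMMARY_DIM <- 112L

init_mat <- function(nr, nc, scale) matrix(rnorm(nr * nc, 0, scale), nr, nc)

#' Construct a patch encoder
#'
#' The encoder maps a `224 x 224 x 3` patch to a 100-dimensional
#' approximately-binary feature vector (`head100`) and a 3-way class
#' activation (softmax). Two kinds are available: `"stub"` — a deterministic
#' seeded random projection of the convolutional patch summary, used for
#' plumbing tests and as the untrained starting point — and the same
#' architecture returned trained by [train_encoder()]. The approximately
#' binary behaviour comes from a steep sigmoid `sigmoid(tau * z)` plus a
#' binarization penalty `lambda * mean(x * (1 - x))` during training.
#'
#' @param kind `"stub"` (deterministic untrained weights).
#' @param seed Integer seed for weight initialization.
#' @param n_hidden Width of the trainable hidden layer.
#' @param tau Steepness of the head sigmoid (default 4).
#' @param lambda Binarization penalty weight (default 0.01).
#' @param n_classes Number of classes for the class head (default 3).
#' @param n_covariates Length of the covariate vector appended to the head
#'   input (default 11: tissue one-hot 10 + marker 1).
#' @return Object of class `hp_encoder`.
#' @export
new_patch_encoder <- function(kind = "stub", seed = 0L, n_hidden = 32L,
                              tau = 4, lambda = 0.01, n_classes = 3L,
                              n_covariates = 11L) {
  p <- PATCH_SUMMARY_DIM
  w <- withr::with_seed(seed, list(
    W1 = init_mat(n_hidden, p, sqrt(2 / p)),
    b1 = rep(0, n_hidden),
    # head weights scaled down by tau so the steep sigmoid starts in its
    # active region rather than saturated
    W2 = init_mat(ENC_HEAD_DIM, n_hidden + n_covariates,
                  sqrt(2 / (n_hidden + n_covariates)) / tau),
    b2 = rep(0, ENC_HEAD_DIM),
    W3 = init_mat(n_classes, ENC_HEAD_DIM, sqrt(2 / ENC_HEAD_DIM)),
    b3 = rep(0, n_classes)
  ))
  structure(list(kind = kind, weights = w, seed = as.integer(seed),
                 n_hidden = as.integer(n_hidden), tau = tau, lambda = lambda,
                 n_classes = as.integer(n_classes),
                 n_covariates = as.integer(n_covariates),
                 feat_mu = rep(0, p), feat_sd = rep(1, p),
                 training_meta = list(trained = FALSE)),
            class = "hp_encoder")
}

#' @export
print.hp_encoder <- function(x, ...) {
  cat("<hp_encoder>", x$kind,
      if (isTRUE(x$training_meta$trained)) "(trained)" else "(untrained)",
      "seed", x$seed, "\n")
  invisible(x)
}

# forward pass on a matrix of patch summaries (p x n) + covariates (c x n)
encoder_forward <- function(enc, S, C = NULL) {
  n <- ncol(S)
  if (is.null(C)) C <- matrix(0, enc$n_covariates, n)
  w <- enc$weights
  S <- (S - enc$feat_mu) / enc$feat_sd
  pre1 <- w$W1 %*% S + w$b1
  h <- relu(pre1)
  hin <- rbind(h, C)
  z <- w$W2 %*% hin + w$b2
  x100 <- sigmoid(enc$tau * z)
  logits <- w$W3 %*% x100 + w$b3
  probs <- softmax_cols(logits)
  list(pre1 = pre1, h = h, hin = hin, z = z, x100 = x100,
       logits = logits, probs = probs)
}

#' Encode one patch to the 100-d head
#'
#' @param enc An `hp_encoder`.
#' @param patch `224 x 224 x 3` array in `[0, 255]`.
#' @param covariates Optional covariate vector (length `n_covariates`);
#'   zeros when omitted or when tissue is missing.
#' @return Numeric vector of length 100, every entry in `[0, 1]`.
#' @export
encode_patch <- function(enc, patch, covariates = NULL) {
  stopifnot(inherits(enc, "hp_encoder"))
  S <- matrix(patch_summary(patch), ncol = 1L)
  C <- if (is.null(covariates)) NULL else matrix(covariates, ncol = 1L)
  as.vector(encoder_forward(enc, S, C)$x100)
}

#' Per-patch class activations
#'
#' @inheritParams encode_patch
#' @return Numeric vector over classes; nonnegative, sums to 1.
#' @export
encode_patch_class <- function(enc, patch, covariates = NULL) {
  stopifnot(inherits(enc, "hp_encoder"))
  S <- matrix(patch_summary(patch), ncol = 1L)
  C <- if (is.null(covariates)) NULL else matrix(covariates, ncol = 1L)
  as.vector(encoder_forward(enc, S, C)$probs)
}

#' Sum-pooled set representation of the 21-patch grid
#'
#' Elementwise sum of the 21 per-patch 100-d head vectors; order-independent
#' and defined for any image size after standardization. Each entry lies in
#' `[0, 21]`.
#'
#' @param enc An `hp_encoder`.
#' @param patchset An `hp_patch_set` from [patch_grid()].
#' @param covariates Optional covariate vector shared by all patches.
#' @return Numeric vector of length 100.
#' @export
set_sum <- function(enc, patchset, covariates = NULL) {
  stopifnot(inherits(enc, "hp_encoder"))
  if (!inherits(patchset, "hp_patch_set") || length(patchset$patches) != 21L) {
    abort("set_sum() requires the 21-patch set", class = "histoprox_contract_error")
  }
  S <- vapply(patchset$patches, patch_summary, numeric(PATCH_SUMMARY_DIM))
  C <- if (is.null(covariates)) NULL
       else matrix(covariates, enc$n_covariates, ncol(S))
  rowSums(encoder_forward(enc, S, C)$x100)
}

#' Generic-vision 2048-d pooled backbone (deterministic stub)
#'
#' A seeded, bias-free random projection of the convolutional patch summary
#' standing in for a pretrained generic-vision network's global-average-pool
#' output. Any 2048-d patch-to-vector backbone with the same signature can be
#' plugged in instead.
#'
#' @param seed Integer seed.
#' @return Function `patch -> numeric[2048]` with attribute `dim`.
#' @export
generic_backbone_stub <- function(seed = 0L) {
  W <- withr::with_seed(seed, init_mat(GENERIC_DIM, PATCH_SUMMARY_DIM,
                                       1 / sqrt(PATCH_SUMMARY_DIM)))
  f <- function(patch) as.vector(W %*% patch_summary(patch))
  attr(f, "out_dim") <- GENERIC_DIM
  f
}

#' Sum-pooled generic-vision features over the 21-patch grid
#'
#' @param backbone A patch-to-vector function, e.g. [generic_backbone_stub()];
#'   `NULL` raises a configuration error.
#' @param patchset An `hp_patch_set`.
#' @return Numeric vector (length 2048 for the stub backbone).
#' @export
pooled_generic <- function(backbone, patchset) {
  if (is.null(backbone)) {
    abort("no generic backbone configured (pass generic_backbone_stub() or a pretrained plug-in)",
          class = "histoprox_config_error")
  }
  stopifnot(inherits(patchset, "hp_patch_set"))
  vecs <- purrr::map(patchset$patches, backbone)
  Reduce(`+`, vecs)
}

#' Train the patch encoder on labeled patches
#'
#' Minimizes cross-entropy on patch-level disease-state labels (patches
#' inherit the label of their source image — weak labeling) plus the
#' binarization penalty, with the standard augmentations and Mixup target
#' mixing, by minibatch gradient descent with momentum. Single-threaded and
#' fully deterministic given `seed`.
#'
#' @param patches List of `224 x 224 x 3` arrays.
#' @param labels Factor/character class label per patch (>= 2 classes).
#' @param covariates Optional matrix `n_patches x n_covariates` (zeros when
#'   missing).
#' @param epochs,batch_size,learning_rate,momentum Optimization settings.
#' @param augment_cfg [augment_config()] settings; `NULL` disables
#'   augmentation.
#' @param mixup_prob Probability a batch element is Mixup-combined.
#' @param seed Integer seed (weights, shuffling, augmentation).
#' @param encoder Optional starting `hp_encoder`; default a fresh one.
#' @return A trained `hp_encoder`; `training_meta` records the seed, config,
#'   per-epoch loss trace (`loss_trace`, entry 1 = pre-training loss), and
#'   class order.
#' @export
train_encoder <- function(patches, labels, covariates = NULL, epochs = 8L,
                          batch_size = 32L, learning_rate = 0.05,
                          momentum = 0.9, augment_cfg = augment_config(),
                          mixup_prob = 0.2, seed = 0L, encoder = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) {
    abort("need >= 2 classes to train the encoder",
          class = "histoprox_contract_error")
  }
  n <- length(patches)
  stopifnot(length(labels) == n)
  enc <- encoder %||% new_patch_encoder(seed = seed,
                                        n_classes = nlevels(labels))
  k <- enc$n_classes
  C <- if (is.null(covariates)) matrix(0, n, enc$n_covariates)
       else as.matrix(covariates)
  Tmat <- diag(k)[, as.integer(labels), drop = FALSE]   # k x n one-hot

  S0 <- vapply(patches, patch_summary, numeric(PATCH_SUMMARY_DIM))
  if (!isTRUE(enc$training_meta$trained)) {
    enc$feat_mu <- rowMeans(S0)
    enc$feat_sd <- pmax(apply(S0, 1L, sd), 1e-6)
  }
  ce_loss <- function(probs, targets) {
    -mean(colSums(targets * log(probs + 1e-12)))
  }
  fwd0 <- encoder_forward(enc, S0, t(C))
  loss_trace <- ce_loss(fwd0$probs, Tmat) +
    enc$lambda * mean(fwd0$x100 * (1 - fwd0$x100))

  w <- enc$weights
  vel <- purrr::map(w, function(m) m * 0)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, n)]
        bt <- Tmat[, bi, drop = FALSE]
        if (is.null(augment_cfg)) {
          S <- S0[, bi, drop = FALSE]
        } else {
          S <- vapply(bi, function(i) {
            patch_summary(augment(patches[[i]], augment_cfg))
          }, numeric(PATCH_SUMMARY_DIM))
        }
        # Mixup on the summary representation with target mixing
        if (mixup_prob > 0 && length(bi) > 1L) {
          mix <- runif(length(bi)) < mixup_prob
          if (any(mix)) {
            partner <- sample(seq_along(bi))
            lam <- rbeta(length(bi), augment_cfg$mixup_alpha %||% 0.2,
                         augment_cfg$mixup_alpha %||% 0.2)
            for (jj in which(mix)) {
              S[, jj] <- lam[jj] * S[, jj] + (1 - lam[jj]) * S[, partner[jj]]
              bt[, jj] <- lam[jj] * bt[, jj] + (1 - lam[jj]) * bt[, partner[jj]]
            }
          }
        }
        bc <- t(C[bi, , drop = FALSE])
        enc$weights <- w
        fw <- encoder_forward(enc, S, bc)
        m <- length(bi)
        dlog <- (fw$probs - bt) / m
        gW3 <- dlog %*% t(fw$x100)
        gb3 <- rowSums(dlog)
        dx <- t(w$W3) %*% dlog +
          enc$lambda * (1 - 2 * fw$x100) / (ENC_HEAD_DIM * m)
        dz <- dx * enc$tau * fw$x100 * (1 - fw$x100)
        gW2 <- dz %*% t(fw$hin)
        gb2 <- rowSums(dz)
        dh <- (t(w$W2) %*% dz)[seq_len(enc$n_hidden), , drop = FALSE]
        dpre1 <- dh * (fw$pre1 > 0)
        gW1 <- dpre1 %*% t((S - enc$feat_mu) / enc$feat_sd)
        gb1 <- rowSums(dpre1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                      W3 = gW3, b3 = gb3)
        for (nm in names(w)) {
          vel[[nm]] <- momentum * vel[[nm]] - learning_rate * grads[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
      }
      enc$weights <- w
      fe <- encoder_forward(enc, S0, t(C))
      loss_trace <- c(loss_trace,
                      ce_loss(fe$probs, Tmat) +
                        enc$lambda * mean(fe$x100 * (1 - fe$x100)))
    }
  })
  enc$weights <- w
  enc$kind <- "trained"
  enc$training_meta <- list(trained = TRUE, seed = as.integer(seed),
                            epochs = as.integer(epochs),
                            batch_size = as.integer(batch_size),
                            learning_rate = learning_rate,
                            classes = levels(labels),
                            loss_trace = loss_trace)
  enc
}

#' Select the three most important deep features
#'
#' Indices of the three largest importances; ties broken by the lower index.
#'
#' @param importances Numeric vector of per-feature importances (length >= 3;
#'   typically 100).
#' @return Integer vector of 3 indices (1-based, ascending).
#' @export
select_deep3 <- function(importances) {
  if (length(importances) < 3L) {
    abort("need at least 3 features", class = "histoprox_contract_error")
  }
  sort(order(-importances, seq_along(importances))[1:3])
}
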