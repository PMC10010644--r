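# Visual encoder: image -> spatial feature grid a = {a_1..a_N}.
#
# The default backbone is a compact 3-block CNN: a fixed average-pooling
# stem downsamples the input, three 3x3 convolution blocks (ReLU, the first
# two followed by 2x2 average pooling) produce a feature map, and adaptive
# average pooling reduces it to a D x D grid that is flattened row-major to
# an (N = D^2, C) matrix.  Convolutions are expressed as sums of shifted
# row-gathers so the same autodiff ops that train the decoder can fine-tune
# the encoder.  Well-known large backbones are accepted as pluggable
# feature functions with their documented channel counts.

BACKBONE_CHANNELS <- c(small_cnn = 64L, densenet121 = 1024L, vgg16 = 512L,
                       resnet101 = 2048L, inceptionv3 = 2048L)

#' Channel count of a named backbone
#' @param backbone Backbone name.
#' @return Integer channel count C of its final convolutional map.
#' @export
backbone_channels <- function(backbone) {
  if (!backbone %in% names(BACKBONE_CHANNELS)) {
    stop("unknown backbone: ", backbone)
  }
  unname(BACKBONE_CHANNELS[backbone])
}

# 3x3 "same" neighbor indices for a row-major H x H grid; 0 = zero pad.
conv3_indices <- function(H) {
  p <- seq_len(H * H)
  r <- (p - 1L) %/% H + 1L
  cc <- (p - 1L) %% H + 1L
  idx <- list()
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= H
    v <- integer(H * H)
    v[ok] <- (rr[ok] - 1L) * H + ccc[ok]
    idx[[k]] <- v
  }
  idx
}

# 2x2 average pooling indices: list of 4 gather vectors of length (H/2)^2.
pool2_indices <- function(H) {
  Ho <- H %/% 2L
  p <- seq_len(Ho * Ho)
  r <- (p - 1L) %/% Ho + 1L
  cc <- (p - 1L) %% Ho + 1L
  r0 <- 2L * (r - 1L); c0 <- 2L * (cc - 1L)
  list((r0) * H + c0 + 1L,
       (r0) * H + c0 + 2L,
       (r0 + 1L) * H + c0 + 1L,
       (r0 + 1L) * H + c0 + 2L)
}

# Adaptive average pooling matrix (D^2 x H^2), row-major on both sides.
adaptive_pool_matrix <- function(H, D) {
  M <- matrix(0, D * D, H * H)
  bounds <- function(i) {
    s <- floor((i - 1L) * H / D) + 1L
    e <- ceiling(i * H / D)
    s:e
  }
  for (ri in seq_len(D)) for (ci in seq_len(D)) {
    rows <- bounds(ri); cols <- bounds(ci)
    w <- 1 / (length(rows) * length(cols))
    for (r in rows) for (cc in cols) {
      M[(ri - 1L) * D + ci, (r - 1L) * H + cc] <- w
    }
  }
  M
}

#' Create a visual encoder
#'
#' @param backbone `"small_cnn"` (default, trained from scratch) or one of
#'   `"densenet121"`, `"vgg16"`, `"resnet101"`, `"inceptionv3"`; for the
#'   latter a `feature_fn` computing the backbone's convolutional feature
#'   map must be supplied (pretrained weights are not shipped).
#' @param D Side of the pooled location grid (N = D^2 locations).
#' @param image_size Input image side in pixels.
#' @param channels Per-block channel counts of the small CNN.
#' @param global_channels Width of the global-context sub-vector: a learned
#'   projection of the location features is max-pooled over the grid and
#'   appended to every location, so small high-response regions stay
#'   visible in grid-level statistics.  The feature dimension is
#'   `C = channels[3] + global_channels`.
#' @param stem Integer downsampling factor of the fixed average-pooling stem.
#' @param seed Seed for weight initialization.
#' @param feature_fn Function `image -> (H, W, C)` array for pluggable
#'   backbones.
#' @return An object of class `rc_encoder` with fields `cfg`, `params` and
#'   `C` (feature channels).
#' @export
encoder_new <- function(backbone = "small_cnn", D = 7L, image_size = 224L,
                        channels = c(8L, 16L, 64L), stem = 4L,
                        global_channels = 0L, seed = 1L,
                        feature_fn = NULL) {
  C <- if (backbone == "small_cnn") channels[3L] + global_channels else
    backbone_channels(backbone)
  if (backbone != "small_cnn" && is.null(feature_fn)) {
    stop("backbone '", backbone, "' needs a feature_fn; ",
         "pretrained weights are not shipped")
  }
  cfg <- list(backbone = backbone, D = as.integer(D),
              image_size = as.integer(image_size),
              channels = as.integer(channels), stem = as.integer(stem),
              global_channels = as.integer(global_channels),
              C = as.integer(C))
  params <- list()
  cache <- new.env(parent = emptyenv())
  if (backbone == "small_cnn") {
    s0 <- image_size %/% stem
    if (s0 * stem != image_size || s0 %% 4L != 0L) {
      stop("image_size must be divisible by 4*stem")
    }
    ch <- channels
    params <- with_local_seed(seed, function() list(
      W1 = ag_param(ag_init_w(9L, ch[1])), b1 = ag_param(numeric(ch[1])),
      W2 = ag_param(ag_init_w(9L * ch[1], ch[2])),
      b2 = ag_param(numeric(ch[2])),
      W3 = ag_param(ag_init_w(9L * (ch[2] + 2L), ch[3])),
      b3 = ag_param(numeric(ch[3])),
      Wg = if (global_channels > 0L)
        ag_param(ag_init_w(ch[3], global_channels)),
      bg = if (global_channels > 0L) ag_param(numeric(global_channels))
    ))
    params <- params[!vapply(params, is.null, TRUE)]
    cache$idx1 <- conv3_indices(s0)
    cache$pool1 <- pool2_indices(s0)
    cache$idx2 <- conv3_indices(s0 %/% 2L)
    cache$pool2 <- pool2_indices(s0 %/% 2L)
    cache$idx3 <- conv3_indices(s0 %/% 4L)
    cache$adapt <- adaptive_pool_matrix(s0 %/% 4L, D)
    # coordinate channels at the last block: chest anatomy is spatially
    # stable, so position-gated responses (e.g. "bright within the lung
    # field") become linearly expressible despite the shallow stack
    s2 <- s0 %/% 4L
    pp <- seq_len(s2 * s2)
    cache$coord3 <- cbind(2 * (((pp - 1L) %/% s2) + 0.5) / s2 - 1,
                          2 * (((pp - 1L) %% s2) + 0.5) / s2 - 1)
  }
  state <- new.env(parent = emptyenv())
  state$finetune <- FALSE
  structure(list(cfg = cfg, params = params, cache = cache, state = state,
                 feature_fn = feature_fn, C = cfg$C),
            class = "rc_encoder")
}

#' @export
print.rc_encoder <- function(x, ...) {
  cat("<rc_encoder>", x$cfg$backbone, " D =", x$cfg$D, " C =", x$cfg$C,
      " finetune =", x$state$finetune, "\n")
  invisible(x)
}

#' Toggle encoder fine-tuning
#'
#' When disabled (default), no encoder parameter receives gradients during
#' a training step; when enabled, the convolution blocks participate in
#' backpropagation.  The fixed pooling stem is never trained.
#'
#' @param encoder An `rc_encoder`.
#' @param enabled Logical.
#' @return The encoder, invisibly.
#' @export
set_finetune <- function(encoder, enabled) {
  for (p in encoder$params) p$tracked <- isTRUE(enabled)
  encoder$state$finetune <- isTRUE(enabled)
  invisible(encoder)
}

# Fixed stem: optional reference subtraction, block-average downsample,
# then row-major flatten to a column.
encoder_stem <- function(encoder, image) {
  image <- drop_image(image, encoder$cfg$image_size)
  if (!is.null(encoder$state$reference)) {
    image <- image - encoder$state$reference
  }
  st <- encoder$cfg$stem
  S <- encoder$cfg$image_size
  s0 <- S %/% st
  P <- matrix(0, s0, S)
  for (r in seq_len(s0)) P[r, ((r - 1L) * st + 1L):(r * st)] <- 1 / st
  ds <- P %*% image %*% t(P)
  matrix(as.vector(t(ds)), ncol = 1L)
}

#' Set the encoder's reference image
#'
#' Chest radiographs are roughly spatially aligned, so subtracting a
#' reference (typically the mean training image) before encoding removes
#' the shared anatomy and makes focal abnormalities the dominant signal at
#' every stage of the feature stack.
#'
#' @param encoder An `rc_encoder`.
#' @param reference `(size, size)` matrix (e.g. the mean of the training
#'   images), or `NULL` to disable.
#' @return The encoder, invisibly.
#' @export
encoder_set_reference <- function(encoder, reference) {
  if (!is.null(reference)) {
    reference <- drop_image(reference, encoder$cfg$image_size)
  }
  encoder$state$reference <- reference
  invisible(encoder)
}

drop_image <- function(image, S) {
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[1] == 1L) image <- image[1L, , ]
    else if (dim(image)[3] == 1L) image <- image[, , 1L]
  }
  if (!is.matrix(image) || nrow(image) != S || ncol(image) != S) {
    stop("expected image of shape (1, ", S, ", ", S, ")")
  }
  image
}

ag_conv3x3 <- function(x, W, b, idx, in_ch) {
  terms <- vector("list", 9L)
  for (k in 1:9) {
    wk <- ag_rows(W, ((k - 1L) * in_ch + 1L):(k * in_ch))
    terms[[k]] <- ag_mm(ag_rows(x, idx[[k]]), wk)
  }
  ag_add(ag_sum_nodes(terms), b)
}

ag_pool2 <- function(x, pidx) {
  ag_scale(ag_sum_nodes(lapply(pidx, function(i) ag_rows(x, i))), 0.25)
}

# Build the (N, C) feature node from a precomputed stem column.
encoder_graph <- function(encoder, stem_col) {
  p <- encoder$params
  ca <- encoder$cache
  ch <- encoder$cfg$channels
  x <- ag_const(stem_col)
  x <- ag_relu(ag_conv3x3(x, p$W1, p$b1, ca$idx1, 1L))
  x <- ag_pool2(x, ca$pool1)
  x <- ag_relu(ag_conv3x3(x, p$W2, p$b2, ca$idx2, ch[1]))
  x <- ag_pool2(x, ca$pool2)
  x <- ag_cbind(list(x, ag_const(ca$coord3)))
  x <- ag_relu(ag_conv3x3(x, p$W3, p$b3, ca$idx3, ch[2] + 2L))
  loc <- ag_mm(ag_const(ca$adapt), x)              # (N, channels[3])
  if (is.null(p$Wg)) return(loc)
  gproj <- ag_relu(ag_add(ag_mm(loc, p$Wg), p$bg)) # (N, G)
  gmax <- ag_max_cols(gproj)                       # (1, G)
  N <- nrow(ca$adapt)
  ag_cbind(list(loc, ag_rows(gmax, rep(1L, N))))   # (N, C)
}

#' Encode an image into a spatial feature grid
#'
#' @param encoder An `rc_encoder`.
#' @param image `(size, size)` matrix or `(1, size, size)` array with
#'   values in \[0,1\].
#' @param sample_id Optional id carried in the result.
#' @return A `feature_grid` list: `features` (`(N, C)` matrix, row-major
#'   locations), `D`, `C`, `sample_id`.
#' @export
encode_image <- function(encoder, image, sample_id = NULL) {
  img <- drop_image(image, encoder$cfg$image_size)
  if (min(img) < -1e-8 || max(img) > 1 + 1e-8) {
    stop("image values must lie in [0, 1]")
  }
  if (encoder$cfg$backbone != "small_cnn") {
    fmap <- encoder$feature_fn(img)
    stopifnot(length(dim(fmap)) == 3L)
    H <- dim(fmap)[1]
    M <- adaptive_pool_matrix(H, encoder$cfg$D)
    flat <- matrix(0, H * H, dim(fmap)[3])
    for (chn in seq_len(dim(fmap)[3])) {
      flat[, chn] <- as.vector(t(fmap[, , chn]))
    }
    feats <- M %*% flat
  } else {
    old <- vapply(encoder$params, function(p) isTRUE(p$tracked), TRUE)
    for (p in encoder$params) p$tracked <- FALSE
    on.exit({
      for (k in seq_along(encoder$params)) {
        encoder$params[[k]]$tracked <- old[[k]]
      }
    })
    feats <- encoder_graph(encoder, encoder_stem(encoder, img))$val
  }
  structure(list(features = feats, D = encoder$cfg$D, C = encoder$cfg$C,
                 sample_id = sample_id),
            class = "feature_grid")
}

#' Flatten a D x D x C feature block to an (N, C) matrix
#'
#' Row i (1-based) corresponds to spatial location
#' `((i-1) div D, (i-1) mod D)` in 0-based row-major order.
#'
#' @param grid A `feature_grid` (returned unchanged as matrix) or a
#'   `(D, D, C)` array.
#' @return `(D^2, C)` matrix.
#' @export
flatten_features <- function(grid) {
  if (inherits(grid, "feature_grid")) return(grid$features)
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  D <- dim(grid)[1]
  C <- dim(grid)[3]
  out <- matrix(0, D * D, C)
  for (chn in seq_len(C)) out[, chn] <- as.vector(t(grid[, , chn]))
  out
}

#' Inverse of [flatten_features()]
#' @param mat `(D^2, C)` matrix.
#' @param D Grid side.
#' @return `(D, D, C)` array.
#' @export
unflatten_features <- function(mat, D) {
  C <- ncol(mat)
  arr <- array(0, dim = c(D, D, C))
  for (chn in seq_len(C)) arr[, , chn] <- matrix(mat[, chn], D, D,
                                                 byrow = TRUE)
  arr
}

#' Pretrain the encoder on pathology labels
#'
#' Mirrors the classifier-pretrained encoder of full-scale systems: a
#' position-specific linear head on the flattened feature grid predicts
#' the lesion labels with binary cross-entropy, training the convolution
#' blocks.  Because every grid location owns its head weights, small
#' lesions contribute undiluted gradients and the learned features become
#' locally label-discriminative, which is what the captioner's first words
#' and its attention rely on.  The head is discarded; only the encoder
#' weights are kept.
#'
#' @param encoder An `rc_encoder` (small CNN backbone; modified in place).
#' @param samples List of lists with `image` and `labels` (character).
#' @param kinds Label vocabulary (the `"none"` class is represented by the
#'   all-zero target).
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Shuffling seed.
#' @param verbose Print per-epoch loss.
#' @return The encoder, invisibly, with per-epoch loss in the `history`
#'   attribute.
#' @export
encoder_pretrain <- function(encoder, samples, kinds, epochs = 60L,
                             batch_size = 16L, lr = 2e-3, seed = 1L,
                             verbose = FALSE) {
  if (encoder$cfg$backbone != "small_cnn") {
    stop("pretraining applies to the small_cnn backbone")
  }
  kinds <- setdiff(kinds, "none")
  K <- length(kinds)
  stopifnot(K > 0)
  set_finetune(encoder, TRUE)
  N <- encoder$cfg$D^2
  head_W <- with_local_seed(seed, function()
    ag_param(ag_init_w(N * encoder$cfg$C, K)))
  head_b <- ag_param(numeric(K))
  params <- c(encoder$params, list(head_W = head_W, head_b = head_b))
  adam <- ag_adam_init(params)
  stems <- lapply(samples, function(s) encoder_stem(encoder, s$image))
  targets <- lapply(samples, function(s)
    matrix(as.numeric(kinds %in% s$labels), 1L))
  n <- length(samples)
  history <- numeric(epochs)
  with_local_seed(seed, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, n)]
        ag_reset()
        losses <- lapply(take, function(i) {
          A <- encoder_graph(encoder, stems[[i]])
          img_logit <- ag_add(ag_mm(ag_vec_row(A), head_W), head_b)
          ag_bce_logits(img_logit, targets[[i]])
        })
        loss <- ag_scale(ag_sum_nodes(losses), 1 / length(take))
        ag_backward(loss)
        adam <<- ag_adam_step(params, adam, lr)
        ep_loss <- ep_loss + as.vector(loss$val) * length(take)
      }
      history[ep] <<- ep_loss / n
      if (verbose) message(sprintf("encoder epoch %d/%d  bce %.4f",
                                   ep, epochs, history[ep]))
    }
  })
  attr(encoder, "history") <- history
  invisible(encoder)
}

encoder_export <- function(encoder) {
  list(cfg = encoder$cfg,
       params = lapply(encoder$params, function(p) p$val),
       finetune = encoder$state$finetune,
       reference = encoder$state$reference)
}

encoder_import <- function(ex) {
  enc <- encoder_new(backbone = ex$cfg$backbone, D = ex$cfg$D,
                     image_size = ex$cfg$image_size,
                     channels = ex$cfg$channels, stem = ex$cfg$stem,
                     global_channels = ex$cfg$global_channels)
  for (k in names(ex$params)) enc$params[[k]]$val <- ex$params[[k]]
  set_finetune(enc, isTRUE(ex$finetune))
  encoder_set_reference(enc, ex$reference)
  enc
}
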