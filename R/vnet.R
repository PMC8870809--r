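# Desk-scale 3D V-NET: an encoder-decoder fully convolutional network with
# residual stages, skip connections, channel doubling per level and a
# single-channel sigmoid output, trained with SGD (momentum) on the soft
# dice loss. The forward and backward passes are hand-written on top of the
# package's Rcpp convolution kernels; there is no autodiff. Layer layout per
# level l (channels C_l = base * 2^(l-1)):
#
#   stem: conv3 in->C_1                     (once, before level 1)
#   enc stage l: residual block of n_l conv3 C_l->C_l
#   down l:      conv2 stride 2 C_l->C_{l+1}
#   up l:        transposed conv2 stride 2 C_{l+1}->C_l
#   dec l:       conv3 (2C_l)->C_l on [up, skip], then a 1-conv residual block
#   head:        conv1 C_1->1, sigmoid
#
# Activations are leaky ReLU (slope 0.1). The head bias starts at -2 so the
# initial prediction is close to the mostly-background truth, which speeds
# up the first epochs under the dice loss.

#' V-NET configuration
#'
#' Defaults follow the clinical training setup — 4 levels, 8 channels in
#' the first level, two input channels (CT, PET), one sigmoid output
#' channel, SGD with learning rate 0.001 and momentum 0.9 — at desk scale:
#' the full-scale run used the 128 x 128 x 256 input grid and 100 epochs,
#' the desk default trains on downscaled phantoms for at most 30 epochs.
#'
#' @param levels Resolution levels (>= 1).
#' @param base_channels Channels at the first level; doubled per level.
#' @param in_channels Input channels (CT + PET = 2).
#' @param kernel Convolution kernel size at full resolution.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param epochs Training epochs (desk default 30; full scale 100).
#' @param batch_size Cases per SGD update.
#' @param seed Seed for weight initialization and data order.
#' @param augment_per_case Augmented copies generated per training case.
#' @param enc_convs Convolutions per encoder stage, length `levels`.
#' @return An object of class `vnet_config`.
#' @export
vnet_config <- function(levels = 4L, base_channels = 8L, in_channels = 2L,
                        kernel = 3L, learning_rate = 0.001, momentum = 0.9,
                        epochs = 30L, batch_size = 2L, seed = 1L,
                        augment_per_case = 1L,
                        enc_convs = pmin(seq_len(levels), 2L)) {
  stopifnot(levels >= 1, base_channels >= 1, in_channels >= 1,
            kernel %% 2 == 1, learning_rate > 0, momentum >= 0,
            momentum < 1, epochs >= 1, batch_size >= 1,
            length(enc_convs) == levels, all(enc_convs >= 1))
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 kernel = as.integer(kernel),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 augment_per_case = as.integer(augment_per_case),
                 enc_convs = as.integer(enc_convs)),
            class = "vnet_config")
}

vnet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L)

he_init <- function(cout, fan_in) {
  matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}

#' Build a V-NET model
#'
#' Initializes all convolution weights (He initialization) and biases.
#' Inputs to the model must have spatial dimensions divisible by
#' 2^(levels - 1).
#'
#' @param cfg A [vnet_config()].
#' @return An object of class `vnet_model` (config + parameter list).
#' @export
build_vnet <- function(cfg) {
  stopifnot(inherits(cfg, "vnet_config"))
  ch <- vnet_channels(cfg)
  k3 <- cfg$kernel^3
  p <- list()
  with_preserved_rng(cfg$seed, {
    p$W_stem <- he_init(ch[1], cfg$in_channels * k3)
    p$b_stem <- numeric(ch[1])
    for (l in seq_len(cfg$levels)) {
      for (i in seq_len(cfg$enc_convs[l])) {
        p[[sprintf("W_enc%d_%d", l, i)]] <- he_init(ch[l], ch[l] * k3)
        p[[sprintf("b_enc%d_%d", l, i)]] <- numeric(ch[l])
      }
      if (l < cfg$levels) {
        p[[sprintf("W_down%d", l)]] <- he_init(ch[l + 1], ch[l] * 8)
        p[[sprintf("b_down%d", l)]] <- numeric(ch[l + 1])
        p[[sprintf("W_up%d", l)]] <- he_init(ch[l], ch[l + 1] * 8)
        p[[sprintf("b_up%d", l)]] <- numeric(ch[l])
        p[[sprintf("W_decr%d", l)]] <- he_init(ch[l], 2 * ch[l] * k3)
        p[[sprintf("b_decr%d", l)]] <- numeric(ch[l])
        p[[sprintf("W_decb%d", l)]] <- he_init(ch[l], ch[l] * k3)
        p[[sprintf("b_decb%d", l)]] <- numeric(ch[l])
      }
    }
    p$W_head <- he_init(1L, ch[1])
    p$b_head <- -2.0   # background-prior initialization
  })
  structure(list(cfg = cfg, params = p), class = "vnet_model")
}

#' Number of trainable parameters
#' @param model A `vnet_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.vnet_model <- function(x, ...) {
  cat(sprintf("<vnet_model> %d levels, %d base channels, %d parameters\n",
              x$cfg$levels, x$cfg$base_channels, n_params(x)))
  invisible(x)
}

LRELU_A <- 0.1
lrelu <- function(x) pmax(x, 0) + LRELU_A * pmin(x, 0)
lrelu_grad <- function(dy, pre) dy * ifelse(pre > 0, 1, LRELU_A)

check_vnet_input <- function(cfg, d) {
  div <- 2L^(cfg$levels - 1L)
  if (any(d[1:3] %% div != 0L))
    stop(sprintf("input spatial shape (%s) must be divisible by %d for %d levels",
                 paste(d[1:3], collapse = "x"), div, cfg$levels))
  if (d[4] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[4]))
}

# Forward pass. x: array (X, Y, Z, in_channels). Returns the sigmoid
# prediction and, when train = TRUE, every intermediate needed by the
# backward pass.
vnet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$kernel; pad <- (k - 1L) %/% 2L
  cache <- if (train) list(x_dim = dim(x)) else NULL
  d <- dim(x)
  check_vnet_input(cfg, d)

  conv <- function(x, W, b, k, stride, pad, cin, tag) {
    r <- conv3d_fwd_cpp(x, dim(x)[1:3], cin, W, as.numeric(b), k, stride, pad,
                        train)
    if (train) {
      cache[[paste0(tag, "_col")]] <<- r$col
      cache[[paste0(tag, "_indim")]] <<- dim(x)
      cache[[paste0(tag, "_pre")]] <<- r$y
    }
    r$y
  }
  ch <- vnet_channels(cfg)

  h <- lrelu(conv(x, p$W_stem, p$b_stem, k, 1L, pad, cfg$in_channels, "stem"))
  skips <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    blk_in <- h
    for (i in seq_len(cfg$enc_convs[l])) {
      tag <- sprintf("enc%d_%d", l, i)
      h <- lrelu(conv(h, p[[paste0("W_", tag)]], p[[paste0("b_", tag)]],
                      k, 1L, pad, ch[l], tag))
    }
    h <- blk_in + h                       # residual stage
    skips[[l]] <- h
    if (l < cfg$levels) {
      tag <- sprintf("down%d", l)
      h <- lrelu(conv(h, p[[paste0("W_", tag)]], p[[paste0("b_", tag)]],
                      2L, 2L, 0L, ch[l], tag))
    }
  }
  for (l in rev(seq_len(cfg$levels - 1L))) {
    tag <- sprintf("up%d", l)
    pre <- upconv3d_fwd_cpp(h, dim(h)[1:3], ch[l + 1],
                            p[[paste0("W_", tag)]],
                            as.numeric(p[[paste0("b_", tag)]]))
    if (train) {
      cache[[paste0(tag, "_pre")]] <- pre
      cache[[paste0(tag, "_x")]] <- h
      cache[[paste0(tag, "_indim")]] <- dim(h)
    }
    u <- lrelu(pre)
    cat_in <- array(c(u, skips[[l]]), c(dim(u)[1:3], 2L * ch[l]))
    tag <- sprintf("decr%d", l)
    h1 <- lrelu(conv(cat_in, p[[paste0("W_", tag)]], p[[paste0("b_", tag)]],
                     k, 1L, pad, 2L * ch[l], tag))
    tag <- sprintf("decb%d", l)
    h <- h1 + lrelu(conv(h1, p[[paste0("W_", tag)]], p[[paste0("b_", tag)]],
                         k, 1L, pad, ch[l], tag))
    if (train) cache[[sprintf("dec%d_h1dim", l)]] <- dim(h1)
  }
  logit <- conv(h, p$W_head, p$b_head, 1L, 1L, 0L, ch[1], "head")
  pred <- 1 / (1 + exp(-logit))
  if (train) {
    cache$pred <- pred
    cache$skip_dims <- lapply(skips, dim)
  }
  list(pred = array(pred, d[1:3]), cache = cache)
}

# Backward pass from d(loss)/d(pred); returns gradients named like params.
vnet_backward <- function(model, cache, dpred) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$kernel; pad <- (k - 1L) %/% 2L
  ch <- vnet_channels(cfg)
  g <- list()

  conv_bwd <- function(dy, tag, W, cin, k, stride, pad) {
    r <- conv3d_bwd_cpp(as.numeric(dy), cache[[paste0(tag, "_col")]], W,
                        cache[[paste0(tag, "_indim")]], cin, k, stride, pad)
    g[[paste0("W_", tag)]] <<- r$dW
    g[[paste0("b_", tag)]] <<- as.numeric(r$db)
    r$dx
  }

  # head: sigmoid then 1x1x1 conv
  pv <- as.numeric(cache$pred)
  dlogit <- as.numeric(dpred) * pv * (1 - pv)
  dh <- conv_bwd(dlogit, "head", p$W_head, ch[1], 1L, 1L, 0L)

  for (l in seq_len(cfg$levels - 1L)) {
    # decoder residual block: h = h1 + lrelu(convB(h1))
    tag <- sprintf("decb%d", l)
    db <- lrelu_grad(dh, cache[[paste0(tag, "_pre")]])
    dh1 <- dh + conv_bwd(db, tag, p[[paste0("W_", tag)]], ch[l], k, 1L, pad)
    # reduce conv on the concatenated [up, skip]
    tag <- sprintf("decr%d", l)
    dr <- lrelu_grad(dh1, cache[[paste0(tag, "_pre")]])
    dcat <- conv_bwd(dr, tag, p[[paste0("W_", tag)]], 2L * ch[l], k, 1L, pad)
    sp <- dim(dcat)[1:3]
    nch <- prod(sp)
    dcat <- array(dcat, c(nch, 2L * ch[l]))
    du <- array(dcat[, seq_len(ch[l])], c(sp, ch[l]))
    dskip_part <- array(dcat[, ch[l] + seq_len(ch[l])], c(sp, ch[l]))
    cache[[sprintf("dskip%d", l)]] <- dskip_part
    # transposed conv
    tag <- sprintf("up%d", l)
    dup <- lrelu_grad(du, cache[[paste0(tag, "_pre")]])
    r <- upconv3d_bwd_cpp(as.numeric(dup), as.numeric(cache[[paste0(tag, "_x")]]),
                          cache[[paste0(tag, "_indim")]], ch[l + 1],
                          p[[paste0("W_", tag)]])
    g[[paste0("W_", tag)]] <- r$dW
    g[[paste0("b_", tag)]] <- as.numeric(r$db)
    dh <- r$dx
  }

  # encoder, deepest level first
  for (l in rev(seq_len(cfg$levels))) {
    dstage <- dh
    if (l < cfg$levels) {
      # gradient arriving through the skip connection
      dstage <- dstage + cache[[sprintf("dskip%d", l)]]
    }
    # residual stage: out = in + convs(in)
    dchain <- dstage
    for (i in rev(seq_len(cfg$enc_convs[l]))) {
      tag <- sprintf("enc%d_%d", l, i)
      dpre <- lrelu_grad(dchain, cache[[paste0(tag, "_pre")]])
      dchain <- conv_bwd(dpre, tag, p[[paste0("W_", tag)]], ch[l], k, 1L, pad)
    }
    din <- dstage + dchain
    if (l > 1L) {
      tag <- sprintf("down%d", l - 1L)
      dpre <- lrelu_grad(din, cache[[paste0(tag, "_pre")]])
      dh <- conv_bwd(dpre, tag, p[[paste0("W_", tag)]], ch[l - 1L], 2L, 2L, 0L)
    } else {
      dpre <- lrelu_grad(din, cache$stem_pre)
      conv_bwd(dpre, "stem", p$W_stem, cfg$in_channels, k, 1L, pad)
    }
  }
  g
}

#' Soft dice loss
#'
#' `1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`,
#' the differentiable segmentation loss; the epsilon (default 1e-6) guards
#' the empty-vs-empty case, where the loss is 0. On binary inputs with
#' eps -> 0 this is exactly 1 - dice. Symmetric in its arguments and
#' insensitive to the background/tumor class imbalance.
#'
#' @param pred,truth [prob_mask()]s or numeric arrays in \[0,1\] of one
#'   shape.
#' @param eps Stabilizing constant.
#' @return Loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, truth, eps = 1e-6) {
  pv <- if (inherits(pred, "prob_mask")) pred$values else pred
  tv <- if (inherits(truth, "prob_mask")) truth$values else truth
  if (!identical(dim(pv), dim(tv))) stop("pred and truth shapes differ")
  1 - (2 * sum(pv * tv) + eps) / (sum(pv) + sum(tv) + eps)
}

soft_dice_grad <- function(pred, truth, eps = 1e-6) {
  num <- 2 * sum(pred * truth) + eps
  den <- sum(pred) + sum(truth) + eps
  -(2 * truth * den - num) / den^2
}

#' Predict a tumor probability map
#'
#' Runs the network on a preprocessed, intensity-scaled CT/PET pair.
#'
#' @param model A trained `vnet_model`.
#' @param input A `scaled_input` from [scale_intensities()].
#' @return A [prob_mask()] on the input grid.
#' @export
predict_vnet <- function(model, input) {
  stopifnot(inherits(model, "vnet_model"), inherits(input, "scaled_input"))
  x <- array(c(input$ct, input$pet), c(dim(input$ct), 2L))
  out <- vnet_forward(model, x, train = FALSE)
  prob_mask(out$pred, input$spacing, input$origin)
}

#' Save / load model weights
#'
#' Weights go to an RDS checkpoint; a JSON sidecar records the
#' configuration, seed and parameter count.
#'
#' @param model A `vnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored `vnet_model` (load).
#' @export
save_vnet <- function(model, path) {
  saveRDS(model, path)
  meta <- c(unclass(model$cfg), list(n_params = n_params(model)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_vnet
#' @export
load_vnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vnet_model"))
  model
}
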