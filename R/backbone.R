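# DenseNet backbone with squeeze-and-excitation channel gating.  The
# fused feature vector is reshaped (bijectively) into a small C0 x h0 x
# w0 feature map, passed through a stem convolution and three dense
# blocks; the output of each dense block is re-weighted channel-wise by
# an SE block, then average-pooled (stride 2 after blocks 1 and 2,
# globally after block 3) before the fully connected binary head.
# Feature maps are stored as (h*w) x C matrices, pixels in column-major
# order.

#' DenseNet-SE configuration
#'
#' @param reshape integer `c(C0, h0, w0)`: the fused vector of length
#'   `C0*h0*w0` is reshaped to this map.
#' @param stem_channels channels after the stem convolution.
#' @param block_layers integer vector of layers per dense block.
#' @param growth growth rate `g`: channels added by each dense layer.
#' @param se_reduction SE bottleneck reduction ratio `r`.
#' @param use_se gate each dense block's output with an SE block.
#' @param n_classes output classes (2: estrus vs non-estrus).
#' @return list of class `densenet_config`. Block output channels follow
#'   `in + layers * growth`.
#' @export
densenet_config <- function(reshape = c(4L, 8L, 8L), stem_channels = 8L,
                            block_layers = c(4L, 4L, 4L), growth = 12L,
                            se_reduction = 16L, use_se = TRUE,
                            n_classes = 2L) {
  stopifnot(length(reshape) == 3, length(block_layers) == 3, growth >= 1)
  structure(list(reshape = as.integer(reshape),
                 stem_channels = as.integer(stem_channels),
                 block_layers = as.integer(block_layers),
                 growth = as.integer(growth),
                 se_reduction = as.integer(se_reduction),
                 use_se = isTRUE(use_se),
                 n_classes = as.integer(n_classes)),
            class = "densenet_config")
}

# channel counts entering each dense block / after each block
densenet_channel_plan <- function(cfg) {
  ch_in <- cfg$stem_channels
  plan <- list()
  for (b in 1:3) {
    ch_out <- ch_in + cfg$block_layers[b] * cfg$growth
    plan[[b]] <- c(in_ch = ch_in, out_ch = ch_out)
    ch_in <- ch_out
  }
  plan
}

#' Initialize the DenseNet-SE backbone
#'
#' @param cfg a [densenet_config()].
#' @param seed integer seed.
#' @return list of class `densenet_model` with `cfg` and `params`.
#' @export
init_densenet <- function(cfg = densenet_config(), seed = 1L) {
  plan <- densenet_channel_plan(cfg)
  params <- withr::with_seed(as.integer(seed), {
    p <- list(
      stem_w = rand_mat(9L * cfg$reshape[1], cfg$stem_channels,
                        1 / sqrt(9 * cfg$reshape[1])),
      stem_b = matrix(0, 1, cfg$stem_channels)
    )
    for (b in 1:3) {
      ch <- plan[[b]][["in_ch"]]
      for (l in seq_len(cfg$block_layers[b])) {
        cin <- ch + (l - 1L) * cfg$growth
        p[[paste0("b", b, "l", l, "_w")]] <-
          rand_mat(9L * cin, cfg$growth, 1 / sqrt(9 * cin))
        p[[paste0("b", b, "l", l, "_b")]] <- matrix(0, 1, cfg$growth)
      }
      cout <- plan[[b]][["out_ch"]]
      mid <- max(1L, cout %/% cfg$se_reduction)
      p[[paste0("se", b, "_w1")]] <- rand_mat(cout, mid, 1 / sqrt(cout))
      p[[paste0("se", b, "_b1")]] <- matrix(0, 1, mid)
      p[[paste0("se", b, "_w2")]] <- rand_mat(mid, cout, 1 / sqrt(mid))
      p[[paste0("se", b, "_b2")]] <- matrix(0, 1, cout)
    }
    cfin <- plan[[3]][["out_ch"]]
    p$head_w <- rand_mat(cfin, cfg$n_classes, 1 / sqrt(cfin))
    p$head_b <- matrix(0, 1, cfg$n_classes)
    p
  })
  structure(list(cfg = cfg, params = params), class = "densenet_model")
}

#' Reshape a fused feature vector into a feature map
#'
#' Bijective reshape: element `i` of the vector fills the
#' `(h0*w0) x C0` map column-major (all pixels of channel 1 first).
#' `reshape_fused()` and [flatten_map()] are exact inverses.
#'
#' @param fused numeric vector of length `C0*h0*w0`.
#' @param cfg a [densenet_config()].
#' @return `(h0*w0) x C0` matrix.
#' @export
reshape_fused <- function(fused, cfg) {
  rs <- cfg$reshape
  if (length(fused) != prod(rs)) {
    rlang::abort(sprintf("fused vector has length %d but the map needs %d",
                         length(fused), prod(rs)))
  }
  matrix(as.vector(fused), rs[2] * rs[3], rs[1])
}

#' Flatten a feature map back to a vector
#' @param map `(h*w) x C` matrix.
#' @return numeric vector (inverse of [reshape_fused()]).
#' @export
flatten_map <- function(map) as.vector(map)

# Tape SE block: x node (h*w) x C; returns gated map node.
ad_se_block <- function(x, p, pre) {
  z <- ad_mean_rows(x)  # squeeze: global average per channel
  s <- ad_sigmoid(ad_add_bias(ad_matmul(
    ad_relu(ad_add_bias(ad_matmul(z, p[[paste0(pre, "_w1")]]),
                        p[[paste0(pre, "_b1")]])),
    p[[paste0(pre, "_w2")]]), p[[paste0(pre, "_b2")]]))
  ad_mul_rowvec(x, s)
}

#' Squeeze-and-excitation channel gating
#'
#' Global average pooling per channel, a two-layer bottleneck MLP
#' (reduce by `r`, restore), sigmoid gate `s` in `(0,1)^C`, output
#' `s (x) x` channel-wise. Never increases any channel's magnitude and
#' never flips activation signs.
#'
#' @param x `(h*w) x C` feature map.
#' @param w1,b1,w2,b2 SE parameters (`C x C/r`, `1 x C/r`, `C/r x C`,
#'   `1 x C`).
#' @return gated feature map, same shape; attribute `gate` holds the
#'   per-channel weights.
#' @export
se_block <- function(x, w1, b1, w2, b2) {
  if (ncol(x) != nrow(w1)) rlang::abort("channel count does not match SE weights")
  p <- list(se_w1 = ad_const(w1), se_b1 = ad_const(b1),
            se_w2 = ad_const(w2), se_b2 = ad_const(b2))
  z <- matrix(colMeans(x), 1)
  gate <- 1 / (1 + exp(-(pmax(sweep(z %*% w1, 2, as.vector(b1), "+"), 0) %*% w2 +
                           matrix(as.vector(b2), 1, ncol(w2)))))
  out <- ad_value(ad_se_block(ad_const(x), p, "se"))
  attr(out, "gate") <- as.vector(gate)
  out
}

# Tape dense block: each layer convolves the concatenation of the block
# input and all previous layer outputs, emitting `growth` channels.
ad_dense_block <- function(x, p, b, n_layers, h, w) {
  acc <- x
  for (l in seq_len(n_layers)) {
    y <- ad_relu(ad_conv2d(acc, p[[paste0("b", b, "l", l, "_w")]],
                           p[[paste0("b", b, "l", l, "_b")]], h, w))
    acc <- ad_concat_cols(acc, y)
  }
  acc
}

#' Run a dense block on a feature map
#'
#' Each internal layer consumes the concatenation of the block input and
#' all previous layer outputs (3x3 convolution + ReLU, `growth` output
#' channels), so the block output has `in + layers*growth` channels.
#'
#' @param x `(h*w) x C` feature map.
#' @param model a [init_densenet()] object.
#' @param block block index (1-3).
#' @param h,w spatial dimensions of `x`.
#' @return `(h*w) x (C + layers*growth)` feature map.
#' @export
dense_block <- function(x, model, block, h, w) {
  stopifnot(inherits(model, "densenet_model"))
  plan <- densenet_channel_plan(model$cfg)
  if (ncol(x) != plan[[block]][["in_ch"]]) {
    rlang::abort("input channels do not match the block's channel plan")
  }
  p <- lapply(model$params, ad_const)
  ad_value(ad_dense_block(ad_const(x), p, block,
                          model$cfg$block_layers[block], h, w))
}

# Full backbone forward on the tape.  fused: 1 x dim node.
ad_densenet_forward <- function(fused, p, cfg) {
  rs <- cfg$reshape
  h <- rs[2]; w <- rs[3]
  x <- ad_reshape(fused, h * w, rs[1])
  x <- ad_relu(ad_conv2d(x, p$stem_w, p$stem_b, h, w))
  for (b in 1:3) {
    x <- ad_dense_block(x, p, b, cfg$block_layers[b], h, w)
    if (cfg$use_se) x <- ad_se_block(x, p, paste0("se", b))
    if (b < 3) {
      x <- ad_pool2d(x, h, w)
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  ad_add_bias(ad_matmul(ad_mean_rows(x), p$head_w), p$head_b)
}

#' Classify a fused feature vector
#'
#' Full backbone forward pass: reshape, stem convolution, three
#' dense-SE-pool stages, global average pooling, fully connected head.
#'
#' @param fused numeric vector of length `prod(cfg$reshape)`.
#' @param model a [init_densenet()] object.
#' @return numeric vector of `n_classes` logits; `which.max - 1` is the
#'   predicted label (1 = estrus).
#' @export
classify_fused <- function(fused, model) {
  stopifnot(inherits(model, "densenet_model"))
  p <- lapply(model$params, ad_const)
  as.vector(ad_value(ad_densenet_forward(ad_const(as_feature_row(fused)),
                                         p, model$cfg)))
}
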