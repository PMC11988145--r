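# Fusion of the pooled image and audio feature vectors.  The adaptive
# path concatenates the two features, passes them through a small ReLU
# MLP, and emits a sigmoid-bounded attention weight A on the image
# modality; the fused representation is the convex combination
# A * proj_img(X) + (1 - A) * proj_aud(Y) of the two features projected
# to a common dimension.  Fixed-weight and plain-concatenation fusion
# are provided as ablation baselines and are exact special cases of the
# same wiring.

#' Fusion configuration
#'
#' @param image_dim,audio_dim input feature dimensions.
#' @param common_dim shared projection dimension of the fused vector.
#' @param hidden hidden width of the attention MLP.
#' @param depth number of ReLU layers in the MLP stack (`k`).
#' @param weight_mode `"scalar"` (default) emits one attention weight
#'   per sample; `"vector"` emits one weight per fused dimension.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(image_dim = 128L, audio_dim = 128L,
                          common_dim = 256L, hidden = 128L, depth = 2L,
                          weight_mode = c("scalar", "vector")) {
  stopifnot(image_dim >= 1, audio_dim >= 1, common_dim >= 1, depth >= 1)
  structure(list(image_dim = as.integer(image_dim),
                 audio_dim = as.integer(audio_dim),
                 common_dim = as.integer(common_dim),
                 hidden = as.integer(hidden), depth = as.integer(depth),
                 weight_mode = match.arg(weight_mode)),
            class = "fusion_config")
}

#' Initialize fusion parameters
#'
#' @param cfg a [fusion_config()].
#' @param seed integer seed.
#' @return list of class `fusion_module` with `cfg` and `params`
#'   (modality projections plus the attention MLP).
#' @export
init_fusion <- function(cfg = fusion_config(), seed = 1L) {
  zdim <- cfg$image_dim + cfg$audio_dim
  adim <- if (cfg$weight_mode == "scalar") 1L else cfg$common_dim
  params <- withr::with_seed(as.integer(seed), {
    p <- list(
      proj_img_w = rand_mat(cfg$image_dim, cfg$common_dim, 1 / sqrt(cfg$image_dim)),
      proj_img_b = matrix(0, 1, cfg$common_dim),
      proj_aud_w = rand_mat(cfg$audio_dim, cfg$common_dim, 1 / sqrt(cfg$audio_dim)),
      proj_aud_b = matrix(0, 1, cfg$common_dim),
      w_input = rand_mat(zdim, cfg$hidden, 1 / sqrt(zdim)),
      b_input = matrix(0, 1, cfg$hidden)
    )
    for (l in seq_len(cfg$depth)) {
      p[[paste0("w", l)]] <- rand_mat(cfg$hidden, cfg$hidden, 1 / sqrt(cfg$hidden))
      p[[paste0("b", l)]] <- matrix(0, 1, cfg$hidden)
    }
    # zero-initialized output layer: the attention weight starts at
    # sigmoid(0) = 0.5, so adaptive fusion begins as balanced fixed
    # fusion and learns to deviate
    p$w_output <- matrix(0, cfg$hidden, adim)
    p$b_output <- matrix(0, 1, adim)
    p
  })
  structure(list(cfg = cfg, params = params), class = "fusion_module")
}

# Tape forward of the attention weight A.  x, y: 1 x dim nodes.
ad_attention_weight <- function(x, y, p, cfg) {
  z <- ad_concat_cols(x, y)
  h <- ad_relu(ad_add_bias(ad_matmul(z, p$w_input), p$b_input))
  for (l in seq_len(cfg$depth)) {
    h <- ad_relu(ad_add_bias(ad_matmul(h, p[[paste0("w", l)]]),
                             p[[paste0("b", l)]]))
  }
  ad_sigmoid(ad_add_bias(ad_matmul(h, p$w_output), p$b_output))
}

# Tape forward of the fused vector.  mode: "adaptive", "concat" or
# numeric w_img in [0,1] for fixed weighting.  Returns list(fused, a)
# where a is NULL for concat.
ad_fuse <- function(x, y, p, cfg, mode) {
  if (identical(mode, "concat")) {
    return(list(fused = ad_concat_cols(x, y), a = NULL))
  }
  xp <- ad_add_bias(ad_matmul(x, p$proj_img_w), p$proj_img_b)
  yp <- ad_add_bias(ad_matmul(y, p$proj_aud_w), p$proj_aud_b)
  if (identical(mode, "adaptive")) {
    a <- ad_attention_weight(x, y, p, cfg)
    if (cfg$weight_mode == "scalar") {
      av <- ad_reshape(a, 1L, 1L)
      fused <- ad_add(ad_mul(xp, ad_broadcast_cols(av, cfg$common_dim)),
                      ad_mul(yp, ad_broadcast_cols(
                        ad_sub(ad_const(matrix(1, 1, 1)), av), cfg$common_dim)))
    } else {
      one <- ad_const(matrix(1, 1, cfg$common_dim))
      fused <- ad_add(ad_mul(xp, a), ad_mul(yp, ad_sub(one, a)))
    }
    list(fused = fused, a = a)
  } else {
    w <- as.numeric(mode)
    fused <- ad_add(ad_scale(xp, w), ad_scale(yp, 1 - w))
    list(fused = fused, a = NULL)
  }
}

as_feature_row <- function(x) matrix(as.vector(x), nrow = 1)

#' Adaptive cross-attention fusion of image and audio features
#'
#' Computes the attention weight `A = sigmoid(W_out H^(k) + b_out)` from
#' the concatenated features via the ReLU MLP, then fuses the projected
#' features as `A * proj_img(X) + (1 - A) * proj_aud(Y)`.
#'
#' @param x image feature vector.
#' @param y audio feature vector.
#' @param fusion a [init_fusion()] module.
#' @return list of class `fusion_result` with `fused` (numeric vector of
#'   length `common_dim`) and `attention` (`A`, the weight on the image
#'   modality; scalar under the default `weight_mode = "scalar"`).
#' @export
adaptive_fuse <- function(x, y, fusion) {
  stopifnot(inherits(fusion, "fusion_module"))
  cfg <- fusion$cfg
  if (length(x) != cfg$image_dim || length(y) != cfg$audio_dim) {
    rlang::abort("feature dimensions do not match the fusion config")
  }
  p <- lapply(fusion$params, ad_const)
  res <- ad_fuse(ad_const(as_feature_row(x)), ad_const(as_feature_row(y)),
                 p, cfg, "adaptive")
  structure(list(fused = as.vector(ad_value(res$fused)),
                 attention = as.vector(ad_value(res$a))),
            class = "fusion_result")
}

#' Fixed-weight fusion baseline
#'
#' `fused = w_img * proj_img(X) + w_aud * proj_aud(Y)` with fixed
#' weights on the simplex; the ablation baseline the adaptive weight is
#' compared against.
#'
#' @inheritParams adaptive_fuse
#' @param w_img,w_aud nonnegative weights with `w_img + w_aud = 1`.
#' @return a `fusion_result`; the `attention` field records `w_img`.
#' @export
fixed_fuse <- function(x, y, fusion, w_img, w_aud) {
  stopifnot(inherits(fusion, "fusion_module"))
  if (w_img < 0 || w_aud < 0 || abs(w_img + w_aud - 1) > 1e-9) {
    rlang::abort("weights must be nonnegative and sum to 1")
  }
  p <- lapply(fusion$params, ad_const)
  res <- ad_fuse(ad_const(as_feature_row(x)), ad_const(as_feature_row(y)),
                 p, fusion$cfg, w_img)
  structure(list(fused = as.vector(ad_value(res$fused)), attention = w_img),
            class = "fusion_result")
}

#' Concatenation fusion baseline
#'
#' Plain concatenation `[X, Y]` (image block first), dimension
#' `dim(X) + dim(Y)`; no projection, no weighting.
#'
#' @param x image feature vector.
#' @param y audio feature vector.
#' @return numeric vector of length `length(x) + length(y)`.
#' @export
concat_fuse <- function(x, y) {
  c(as.vector(x), as.vector(y))
}
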