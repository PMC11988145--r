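# Vision-Transformer-style image feature extractor: convolutional patch
# embedding (kernel = stride = patch size, i.e. a linear map per patch),
# learned positional embeddings added to the patch tokens, then a stack
# of pre-norm encoder layers (multi-head self-attention + FFN, each with
# a residual connection), mean-pooled to a single feature vector.

#' Patch grid specification for the image encoder
#'
#' @param image_size integer `c(H, W)` of the (resized) input image.
#' @param patch_size integer `c(P_H, P_W)`; must divide `image_size`.
#' @param embed_dim token embedding dimension `D`.
#' @return list of class `patch_grid` with `n_patches = H*W/(P_H*P_W)`.
#' @export
patch_grid <- function(image_size = c(224, 224), patch_size = c(16, 16),
                       embed_dim = 128L) {
  stopifnot(length(image_size) == 2, length(patch_size) == 2, embed_dim >= 1)
  if (image_size[1] %% patch_size[1] != 0 || image_size[2] %% patch_size[2] != 0) {
    rlang::abort("patch size must divide image size")
  }
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_patches = as.integer(prod(image_size) / prod(patch_size))),
            class = "patch_grid")
}

#' Transformer encoder configuration
#'
#' @param depth number of encoder layers.
#' @param n_heads attention heads; must divide the embedding dimension.
#' @param ffn_hidden FFN inner width (default twice the embedding dim,
#'   set at initialization when `NULL`).
#' @param pool `"mean"` (default) pools tokens by averaging; `"cls"`
#'   prepends a learned classification token and uses its final state.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(depth = 4L, n_heads = 4L, ffn_hidden = NULL,
                           pool = c("mean", "cls")) {
  stopifnot(depth >= 1, n_heads >= 1)
  structure(list(depth = as.integer(depth), n_heads = as.integer(n_heads),
                 ffn_hidden = ffn_hidden, pool = match.arg(pool)),
            class = "encoder_config")
}

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize an image encoder
#'
#' Weights are drawn from centered Gaussians with fan-in scaling; the
#' positional table starts at small random values. Fully deterministic
#' given `seed`.
#'
#' @param grid a [patch_grid()].
#' @param cfg an [encoder_config()].
#' @param seed integer seed.
#' @return list of class `image_encoder` with `grid`, `cfg`, `params`.
#' @export
init_image_encoder <- function(grid, cfg = encoder_config(), seed = 1L) {
  d <- grid$embed_dim
  if (d %% cfg$n_heads != 0) rlang::abort("n_heads must divide embed_dim")
  if (is.null(cfg$ffn_hidden)) cfg$ffn_hidden <- 2L * d
  pdim <- prod(grid$patch_size)
  n_tok <- grid$n_patches + (cfg$pool == "cls")
  params <- withr::with_seed(as.integer(seed), {
    p <- list(
      patch_w = rand_mat(pdim, d, 1 / sqrt(pdim)),
      patch_b = matrix(0, 1, d),
      pos = rand_mat(n_tok, d, 0.02)
    )
    if (cfg$pool == "cls") p$cls <- rand_mat(1, d, 0.02)
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("l", l, ".")
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1, d)
      p[[paste0(pre, "ln1_b")]] <- matrix(0, 1, d)
      p[[paste0(pre, "wq")]] <- rand_mat(d, d, 1 / sqrt(d))
      p[[paste0(pre, "wk")]] <- rand_mat(d, d, 1 / sqrt(d))
      p[[paste0(pre, "wv")]] <- rand_mat(d, d, 1 / sqrt(d))
      p[[paste0(pre, "wo")]] <- rand_mat(d, d, 1 / sqrt(d))
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1, d)
      p[[paste0(pre, "ln2_b")]] <- matrix(0, 1, d)
      p[[paste0(pre, "w1")]] <- rand_mat(d, cfg$ffn_hidden, 1 / sqrt(d))
      p[[paste0(pre, "b1")]] <- matrix(0, 1, cfg$ffn_hidden)
      p[[paste0(pre, "w2")]] <- rand_mat(cfg$ffn_hidden, d, 1 / sqrt(cfg$ffn_hidden))
      p[[paste0(pre, "b2")]] <- matrix(0, 1, d)
    }
    p$lnf_g <- matrix(1, 1, d)
    p$lnf_b <- matrix(0, 1, d)
    p
  })
  structure(list(grid = grid, cfg = cfg, params = params),
            class = "image_encoder")
}

#' Extract and embed image patches
#'
#' Splits the image into non-overlapping patches (grid scanned
#' column-major, pixels within a patch column-major) and applies the
#' shared linear patch embedding — the convolutional embedding with
#' kernel equal to stride.
#'
#' @param img numeric matrix matching `grid$image_size`.
#' @param grid a [patch_grid()].
#' @param params optional encoder parameter list (from
#'   [init_image_encoder()]); when omitted, the raw `N x (P_H*P_W)`
#'   patch matrix is returned instead of embedded tokens.
#' @return `N x D` token matrix (or `N x (P_H*P_W)` patch matrix).
#' @export
patchify_embed <- function(img, grid, params = NULL) {
  pm <- extract_patches(img, grid)
  if (is.null(params)) return(pm)
  sweep(pm %*% params$patch_w, 2L, as.vector(params$patch_b), "+")
}

# N x (P_H*P_W) patch matrix, grid scanned column-major.
extract_patches <- function(img, grid) {
  h <- grid$image_size[1]; w <- grid$image_size[2]
  ph <- grid$patch_size[1]; pw <- grid$patch_size[2]
  if (nrow(img) != h || ncol(img) != w) {
    rlang::abort("image dimensions do not match the patch grid")
  }
  gh <- h %/% ph; gw <- w %/% pw
  out <- matrix(0, gh * gw, ph * pw)
  k <- 0L
  for (gc in seq_len(gw)) for (gr in seq_len(gh)) {
    k <- k + 1L
    out[k, ] <- as.vector(img[((gr - 1L) * ph + 1L):(gr * ph),
                              ((gc - 1L) * pw + 1L):(gc * pw)])
  }
  out
}

#' Add positional embeddings to a token sequence
#'
#' @param tokens `N x D` matrix.
#' @param pos `N x D` learned positional table.
#' @return elementwise sum, `N x D`.
#' @export
add_positional <- function(tokens, pos) {
  if (!all(dim(tokens) == dim(pos))) rlang::abort("token/positional shape mismatch")
  tokens + pos
}

#' Scaled dot-product self-attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`; each output row is a convex
#' combination of the rows of `V`.
#'
#' @param q,k,v query/key/value matrices (`N x d_k`, `N x d_k`, `N x d_v`).
#' @param d_k key dimension used in the scaling.
#' @return `N x d_v` matrix.
#' @export
self_attention <- function(q, k, v, d_k = ncol(k)) {
  if (d_k <= 0) rlang::abort("d_k must be positive")
  stopifnot(ncol(q) == ncol(k), nrow(k) == nrow(v))
  ad_value(ad_attention(ad_const(q), ad_const(k), ad_const(v), d_k))
}

# tape version
ad_attention <- function(q, k, v, d_k) {
  scores <- ad_scale(ad_matmul(q, ad_transpose(k)), 1 / sqrt(d_k))
  ad_matmul(ad_softmax_rows(scores), v)
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = ReLU(x W1 + b1) W2 + b2`, applied row-wise.
#'
#' @param x `N x D` input.
#' @param w1,b1,w2,b2 parameter matrices (`b1`, `b2` as row vectors).
#' @return `N x D` output.
#' @export
transformer_ffn <- function(x, w1, b1, w2, b2) {
  stopifnot(ncol(x) == nrow(w1), ncol(w1) == nrow(w2))
  ad_value(ad_ffn(ad_const(x), ad_const(w1), ad_const(b1),
                  ad_const(w2), ad_const(b2)))
}

ad_ffn <- function(x, w1, b1, w2, b2) {
  ad_add_bias(ad_matmul(ad_relu(ad_add_bias(ad_matmul(x, w1), b1)), w2), b2)
}

# Multi-head self-attention on the tape. x: N x D node; P: node list.
ad_mhsa <- function(x, p, pre, n_heads) {
  d <- ncol(x$val)
  dk <- d %/% n_heads
  q <- ad_matmul(x, p[[paste0(pre, "wq")]])
  k <- ad_matmul(x, p[[paste0(pre, "wk")]])
  v <- ad_matmul(x, p[[paste0(pre, "wv")]])
  heads <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    idx <- ((hh - 1L) * dk + 1L):(hh * dk)
    heads[[hh]] <- ad_attention(ad_slice_cols(q, idx), ad_slice_cols(k, idx),
                                ad_slice_cols(v, idx), dk)
  }
  out <- heads[[1]]
  if (n_heads > 1) for (hh in 2:n_heads) out <- ad_concat_cols(out, heads[[hh]])
  ad_matmul(out, p[[paste0(pre, "wo")]])
}

# Full encoder forward on the tape.  patches: plain N x (ph*pw) matrix;
# p: named list of parameter nodes; returns a 1 x D feature node.
ad_vit_forward <- function(patches, p, cfg) {
  x <- ad_add_bias(ad_matmul(ad_const(patches), p$patch_w), p$patch_b)
  if (cfg$pool == "cls") x <- ad_concat_rows(p$cls, x)
  x <- ad_add(x, p$pos)
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("l", l, ".")
    h <- ad_layernorm(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    x <- ad_add(x, ad_mhsa(h, p, pre, cfg$n_heads))
    h <- ad_layernorm(x, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    x <- ad_add(x, ad_ffn(h, p[[paste0(pre, "w1")]], p[[paste0(pre, "b1")]],
                          p[[paste0(pre, "w2")]], p[[paste0(pre, "b2")]]))
  }
  x <- ad_layernorm(x, p$lnf_g, p$lnf_b)
  if (cfg$pool == "cls") {
    ad_slice_rows_1(x)
  } else {
    ad_mean_rows(x)
  }
}

#' Encode a preprocessed image into a feature vector
#'
#' Full encoder forward pass: patchify, embed, add positional
#' embeddings, run the encoder stack, pool tokens. Deterministic given
#' the encoder weights.
#'
#' @param img numeric matrix matching the encoder's patch grid (resize
#'   with [resize_image()] first if needed).
#' @param encoder an [init_image_encoder()] object.
#' @return numeric feature vector of length `embed_dim`, with attribute
#'   `modality = "image"`.
#' @export
encode_image <- function(img, encoder) {
  stopifnot(inherits(encoder, "image_encoder"))
  patches <- extract_patches(img, encoder$grid)
  p <- lapply(encoder$params, ad_const)
  out <- ad_value(ad_vit_forward(patches, p, encoder$cfg))
  structure(as.vector(out), modality = "image")
}
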