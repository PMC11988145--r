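test_that("patch grids count tokens as H*W/(P_H*P_W)", {
  expect_equal(patch_grid(c(64, 64), c(16, 16), 32)$n_patches, 16)
  expect_equal(patch_grid(c(224, 224), c(16, 16))$n_patches, 196)
  expect_error(patch_grid(c(100, 64), c(16, 16)), "divide")
})

test_that("patch embedding is the shared linear map per patch", {
  grid <- patch_grid(c(16, 16), c(8, 8), 12)
  enc <- init_image_encoder(grid, encoder_config(depth = 1, n_heads = 2),
                            seed = 1L)
  img <- matrix(rnorm(256), 16, 16)
  tok <- patchify_embed(img, grid, enc$params)
  expect_equal(dim(tok), c(4L, 12L))
  # zero image with zero bias gives all-zero tokens
  z <- patchify_embed(matrix(0, 16, 16), grid, enc$params)
  expect_equal(max(abs(z)), 0)
  # manual check of one patch
  patches <- patchify_embed(img, grid)
  expect_equal(tok[2, ], as.vector(patches[2, , drop = FALSE] %*%
                                     enc$params$patch_w))
})

test_that("positional addition is an elementwise sum with equivariance", {
  tok <- matrix(rnorm(12), 4, 3)
  pos <- matrix(rnorm(12), 4, 3)
  expect_equal(add_positional(tok, pos), tok + pos)
  expect_equal(add_positional(tok, pos * 0), tok)
  perm <- c(3, 1, 4, 2)
  expect_equal(add_positional(tok, pos)[perm, ],
               add_positional(tok[perm, ], pos[perm, ]))
  expect_error(add_positional(tok, pos[1:3, ]), "mismatch")
})

test_that("the encoder is positionally sensitive", {
  grid <- patch_grid(c(16, 16), c(8, 8), 16)
  enc <- init_image_encoder(grid, encoder_config(depth = 2, n_heads = 2),
                            seed = 3L)
  img <- matrix(rnorm(256), 16, 16)
  f <- encode_image(img, enc)
  # permute the image patches (swap top-left and bottom-right patch)
  img2 <- img
  img2[1:8, 1:8] <- img[9:16, 9:16]
  img2[9:16, 9:16] <- img[1:8, 1:8]
  f2 <- encode_image(img2, enc)
  expect_gt(max(abs(f - f2)), 1e-6)
})

test_that("self-attention outputs are convex combinations of value rows", {
  set.seed(4)
  # single token: softmax of a scalar is 1, output is V itself
  v1 <- matrix(rnorm(5), 1, 5)
  expect_equal(self_attention(matrix(rnorm(3), 1, 3),
                              matrix(rnorm(3), 1, 3), v1), v1)
  # identical keys: uniform weights, output = column mean of V
  q <- matrix(rnorm(12), 4, 3)
  k <- matrix(rep(rnorm(3), each = 4), 4, 3)
  v <- matrix(rnorm(20), 4, 5)
  out <- self_attention(q, k, v)
  expect_equal(out, matrix(colMeans(v), 4, 5, byrow = TRUE))
  # attention rows sum to 1 and outputs stay in the convex hull of V
  q2 <- matrix(rnorm(24), 8, 3); k2 <- matrix(rnorm(24), 8, 3)
  a <- sowfuse:::ad_value(sowfuse:::ad_softmax_rows(sowfuse:::ad_scale(
    sowfuse:::ad_matmul(sowfuse:::ad_const(q2),
                        sowfuse:::ad_transpose(sowfuse:::ad_const(k2))),
    1 / sqrt(3))))
  expect_lt(max(abs(rowSums(a) - 1)), 1e-9)
  out2 <- self_attention(q2, k2, v[rep(1:4, 2), ])
  vmax <- apply(v[rep(1:4, 2), ], 2, max)
  vmin <- apply(v[rep(1:4, 2), ], 2, min)
  expect_true(all(sweep(out2, 2, vmax) <= 1e-12))
  expect_true(all(sweep(out2, 2, vmin) >= -1e-12))
  expect_error(self_attention(q2, k2, v[rep(1:4, 2), ], d_k = 0), "positive")
})

test_that("the FFN computes ReLU(xW1+b1)W2+b2 exactly", {
  set.seed(5)
  w1 <- matrix(rnorm(12), 3, 4); b1 <- matrix(rnorm(4), 1, 4)
  w2 <- matrix(rnorm(12), 4, 3); b2 <- matrix(rnorm(3), 1, 3)
  x0 <- matrix(0, 2, 3)
  expect_equal(transformer_ffn(x0, w1, b1, w2, b2),
               matrix(pmax(b1, 0) %*% w2 + matrix(b2, 1), 2, 3, byrow = TRUE))
  # identity wiring for nonnegative input
  i3 <- diag(3)
  xpos <- matrix(abs(rnorm(6)), 2, 3)
  expect_equal(transformer_ffn(xpos, i3, matrix(0, 1, 3), i3,
                               matrix(0, 1, 3)), xpos)
  # hidden activations are nonnegative
  x <- matrix(rnorm(6), 2, 3)
  hidden <- pmax(sweep(x %*% w1, 2, as.vector(b1), "+"), 0)
  expect_true(all(hidden >= 0))
  expect_equal(transformer_ffn(x, w1, b1, w2, b2),
               sweep(hidden %*% w2, 2, as.vector(b2), "+"))
})

test_that("encoder output has dimension D, deterministically", {
  grid <- patch_grid(c(16, 16), c(8, 8), 16)
  enc <- init_image_encoder(grid, encoder_config(depth = 2, n_heads = 2),
                            seed = 6L)
  img <- matrix(rnorm(256), 16, 16)
  f <- encode_image(img, enc)
  expect_length(f, 16)
  expect_identical(attr(f, "modality"), "image")
  expect_identical(f, encode_image(img, enc))
  # a change confined to one patch changes the feature
  img2 <- img
  img2[1:8, 1:8] <- img2[1:8, 1:8] + 0.5
  expect_gt(max(abs(encode_image(img2, enc) - f)), 1e-8)
})

test_that("zeroed sublayer outputs reduce each encoder layer to the identity", {
  grid <- patch_grid(c(16, 16), c(8, 8), 16)
  enc <- init_image_encoder(grid, encoder_config(depth = 2, n_heads = 2),
                            seed = 7L)
  # zero the residual-branch output weights: attention Wo and FFN W2/b2
  for (l in 1:2) {
    enc$params[[paste0("l", l, ".wo")]][] <- 0
    enc$params[[paste0("l", l, ".w2")]][] <- 0
    enc$params[[paste0("l", l, ".b2")]][] <- 0
  }
  img <- matrix(rnorm(256), 16, 16)
  f <- encode_image(img, enc)
  # expected: mean over tokens of the final layernorm of tokens + pos
  tok <- patchify_embed(img, grid, enc$params) + enc$params$pos
  ln <- sowfuse:::ad_value(sowfuse:::ad_layernorm(
    sowfuse:::ad_const(tok), sowfuse:::ad_const(enc$params$lnf_g),
    sowfuse:::ad_const(enc$params$lnf_b)))
  expect_equal(as.vector(f), colMeans(ln), tolerance = 1e-12)
})

test_that("CLS-token pooling produces a feature of the same dimension", {
  grid <- patch_grid(c(16, 16), c(8, 8), 16)
  enc <- init_image_encoder(grid, encoder_config(depth = 1, n_heads = 2,
                                                 pool = "cls"), seed = 8L)
  f <- encode_image(matrix(rnorm(256), 16, 16), enc)
  expect_length(f, 16)
})
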