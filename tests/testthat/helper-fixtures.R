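# Shared fixtures, all generated in code.

# tiny synthetic spec suitable for fast per-test generation
tiny_spec <- function(n_pairs = 8L, seed = 1L, ...) {
  synthetic_spec(n_pairs = n_pairs, image_size = c(32L, 32L),
                 sample_rate = 4000L, duration = 0.25,
                 chirp_band = c(1500, 1900), seed = seed, ...)
}

# small architecture for training-path tests
tiny_arch <- function() {
  list(
    grid = patch_grid(c(16L, 16L), c(8L, 8L), 16L),
    encoder = encoder_config(depth = 1L, n_heads = 2L),
    audio = audio_cnn_config(input_len = 192L, channels = c(4L, 8L, 8L),
                             kernel = 5L, pool = 4L, out_dim = 16L),
    fusion = fusion_config(image_dim = 16L, audio_dim = 16L,
                           common_dim = 16L, hidden = 16L, depth = 2L),
    backbone = densenet_config(reshape = c(1L, 4L, 4L), stem_channels = 4L,
                               block_layers = c(1L, 1L, 1L), growth = 4L,
                               se_reduction = 2L),
    audio_rate = 1000
  )
}

# prepared samples from a tiny dataset, cached per session
tiny_prepared <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- tiny_spec(n_pairs = 24L, seed = 42L)
      ds <- generate_dataset(spec)
      split <- split_dataset(ds$manifest, seed = 42L)
      arch <- tiny_arch()
      model <- condition_model("adaptive", arch, 1L)
      cache <<- list(
        prepared = prepare_dataset(ds, split, model, arch$audio_rate),
        arch = arch, dataset = ds, split = split
      )
    }
    cache
  }
})

# a deterministic smooth "clean" thermal-like image
smooth_image <- function(h = 32L, w = 32L) {
  ry <- matrix(seq_len(h), h, w)
  rx <- matrix(seq_len(w), h, w, byrow = TRUE)
  0.4 + 0.3 * exp(-(((rx - w / 2) / (w / 4))^2 + ((ry - h / 2) / (h / 5))^2))
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
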