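# Audio feature extractor: three 1-D convolutional layers over the
# filtered waveform (the third dilated to widen the receptive field at
# no parameter cost), each followed by ReLU and average pooling, then
# global average pooling over time and a linear map to the feature
# dimension.  Convolutions use circular padding, so the extractor is
# exactly invariant to circular time shifts that are multiples of the
# cumulative pooling stride.

#' Audio CNN configuration
#'
#' @param input_len waveform length in samples fed to the network
#'   (default 16000, i.e. 1 s at 16 kHz); must be divisible by the
#'   product of the pool factors.
#' @param channels integer `c(c1, c2, c3)` output channels per layer.
#' @param kernel kernel size (odd), shared by the three layers.
#' @param pool average-pooling factor after each layer.
#' @param dilation dilation of the third convolution (`>= 1`).
#' @param out_dim output feature dimension.
#' @return list of class `audio_cnn_config`.
#' @export
audio_cnn_config <- function(input_len = 16000L, channels = c(16L, 32L, 64L),
                             kernel = 9L, pool = 4L, dilation = 2L,
                             out_dim = 128L) {
  stopifnot(length(channels) == 3, kernel %% 2 == 1, dilation >= 1,
            input_len %% pool^3 == 0)
  structure(list(input_len = as.integer(input_len),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dilation = as.integer(dilation),
                 out_dim = as.integer(out_dim)),
            class = "audio_cnn_config")
}

#' Initialize the audio CNN
#'
#' @param cfg an [audio_cnn_config()].
#' @param seed integer seed.
#' @return list of class `audio_encoder` with `cfg` and `params`.
#' @export
init_audio_cnn <- function(cfg = audio_cnn_config(), seed = 1L) {
  k <- cfg$kernel
  c0 <- c(1L, cfg$channels)
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    for (l in 1:3) {
      p[[paste0("conv", l, "_w")]] <-
        rand_mat(k * c0[l], c0[l + 1], 1 / sqrt(k * c0[l]))
      p[[paste0("conv", l, "_b")]] <- matrix(0, 1, c0[l + 1])
    }
    p$out_w <- rand_mat(cfg$channels[3], cfg$out_dim, 1 / sqrt(cfg$channels[3]))
    p$out_b <- matrix(0, 1, cfg$out_dim)
    p
  })
  structure(list(cfg = cfg, params = params), class = "audio_encoder")
}

# Tape forward.  x: plain input_len x 1 matrix; p: parameter node list.
ad_audio_forward <- function(x, p, cfg) {
  k <- cfg$kernel
  h <- ad_conv1d(ad_const(x), p$conv1_w, p$conv1_b, k)
  h <- ad_pool_rows(ad_relu(h), cfg$pool)
  h <- ad_conv1d(h, p$conv2_w, p$conv2_b, k)
  h <- ad_pool_rows(ad_relu(h), cfg$pool)
  h <- ad_conv1d(h, p$conv3_w, p$conv3_b, k, dilation = cfg$dilation)
  h <- ad_pool_rows(ad_relu(h), cfg$pool)
  ad_add_bias(ad_matmul(ad_mean_rows(h), p$out_w), p$out_b)
}

#' Center-crop or zero-pad a waveform to a fixed length
#'
#' @param x numeric vector.
#' @param len target length.
#' @return numeric vector of length `len`.
#' @export
fit_to_length <- function(x, len) {
  n <- length(x)
  if (n == len) return(x)
  if (n > len) {
    start <- (n - len) %/% 2L
    x[(start + 1L):(start + len)]
  } else {
    pad <- len - n
    left <- pad %/% 2L
    c(numeric(left), x, numeric(pad - left))
  }
}

#' Encode an audio clip into a feature vector
#'
#' Mixes to mono, center-crops or zero-pads to the configured input
#' length, and runs the three-layer dilated CNN. Deterministic given
#' the weights. The caller is responsible for band-pass filtering and
#' resampling (see [denoise_audio()], [decimate_audio()]).
#'
#' @param clip an [audio_clip()] (or bare numeric vector).
#' @param encoder an [init_audio_cnn()] object.
#' @return numeric feature vector of length `out_dim`, attribute
#'   `modality = "audio"`.
#' @export
encode_audio <- function(clip, encoder) {
  stopifnot(inherits(encoder, "audio_encoder"))
  x <- if (inherits(clip, "audio_clip")) as_mono(clip)$samples else clip
  cfg <- encoder$cfg
  if (length(x) < cfg$kernel) rlang::abort("input shorter than one kernel span")
  x <- matrix(fit_to_length(x, cfg$input_len), ncol = 1)
  p <- lapply(encoder$params, ad_const)
  structure(as.vector(ad_value(ad_audio_forward(x, p, cfg))),
            modality = "audio")
}

#' Receptive field of the audio CNN, in input samples
#'
#' Closed form for the stacked conv/pool pipeline: each convolution with
#' kernel `k` and dilation `d` adds `d*(k-1)*jump` samples and each
#' pooling stage of factor `p` adds `(p-1)*jump` before multiplying the
#' index jump by `p`.
#'
#' @param cfg an [audio_cnn_config()], or a single-layer description via
#'   `kernel`/`dilation` overrides.
#' @return receptive-field length in samples.
#' @export
receptive_field <- function(cfg) {
  stopifnot(inherits(cfg, "audio_cnn_config"))
  rf <- 1; jump <- 1
  dil <- c(1L, 1L, cfg$dilation)
  for (l in 1:3) {
    rf <- rf + dil[l] * (cfg$kernel - 1) * jump
    rf <- rf + (cfg$pool - 1) * jump
    jump <- jump * cfg$pool
  }
  rf
}

#' Receptive field of a single dilated convolution
#'
#' `d * (k - 1) + 1` samples.
#'
#' @param kernel kernel size.
#' @param dilation dilation factor.
#' @return receptive-field length in samples.
#' @export
conv_receptive_field <- function(kernel, dilation = 1L) {
  dilation * (kernel - 1) + 1
}

#' Number of trainable parameters of an encoder or model
#'
#' @param x an object with a `params` list of matrices, or a bare list.
#' @return integer parameter count.
#' @export
count_params <- function(x) {
  p <- if (is.list(x) && !is.null(x$params)) x$params else x
  sum(vapply(p, length, integer(1)))
}
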