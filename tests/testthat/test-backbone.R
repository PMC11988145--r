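test_that("the fused-vector reshape is bijective", {
  cfg <- densenet_config(reshape = c(4L, 8L, 8L))
  v <- rnorm(256)
  m <- reshape_fused(v, cfg)
  expect_equal(dim(m), c(64L, 4L))
  expect_equal(flatten_map(m), v)
  expect_equal(reshape_fused(numeric(256), cfg), matrix(0, 64, 4))
  expect_error(reshape_fused(rnorm(250), cfg), "length 250")
})

test_that("SE gating shrinks channels without flipping signs", {
  set.seed(1)
  c_ch <- 6L
  x <- matrix(rnorm(16 * c_ch), 16, c_ch)
  w1 <- matrix(rnorm(c_ch * 3), c_ch, 3); b1 <- matrix(0, 1, 3)
  w2 <- matrix(rnorm(3 * c_ch), 3, c_ch); b2 <- matrix(0, 1, c_ch)
  out <- se_block(x, w1, b1, w2, b2)
  gate <- attr(out, "gate")
  expect_true(all(gate > 0 & gate < 1))
  expect_equal(unclass(out), sweep(x, 2, gate, "*"), ignore_attr = TRUE)
  # per-channel magnitude never increases; signs never flip
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  expect_true(all(sign(out) == sign(x) | x == 0))
  # zero input maps to zero output
  z <- se_block(matrix(0, 16, c_ch), w1, b1, w2, b2)
  expect_equal(max(abs(z)), 0)
  expect_error(se_block(x[, 1:3], w1, b1, w2, b2), "channel")
})

test_that("a trained SE gate opens for the informative channel", {
  # toy channel-relevance task: channel 1 carries the class signal,
  # channel 2 is pure noise; after a few steps of training an SE-gated
  # mean readout, the gate on channel 1 should exceed the gate on 2.
  run_one <- function(seed) {
    withr::with_seed(seed, {
      p <- list(w1 = matrix(rnorm(2), 2, 1) * 0.5, b1 = matrix(0, 1, 1),
                w2 = matrix(rnorm(2), 1, 2) * 0.5, b2 = matrix(0, 1, 2),
                head = matrix(rnorm(4) * 0.5, 2, 2))
      ms <- lapply(p, function(m) m * 0); vs <- ms; t_step <- 0
      for (step in 1:100) {
        lab <- sample(0:1, 1)
        x <- cbind(rnorm(8, mean = ifelse(lab == 1, 1.5, -1.5), sd = 0.5),
                   rnorm(8, sd = 1))
        nodes <- lapply(p, sowfuse:::ad_param)
        xn <- sowfuse:::ad_const(x)
        gated <- sowfuse:::ad_se_block(
          xn, list(se_w1 = nodes$w1, se_b1 = nodes$b1,
                   se_w2 = nodes$w2, se_b2 = nodes$b2), "se")
        logits <- sowfuse:::ad_matmul(sowfuse:::ad_mean_rows(gated), nodes$head)
        loss <- sowfuse:::ad_cross_entropy(logits, lab + 1L)
        sowfuse:::ad_backward(loss)
        t_step <- t_step + 1
        for (nm in names(p)) {
          g <- nodes[[nm]]$grad
          if (is.null(g)) next
          ms[[nm]] <- 0.9 * ms[[nm]] + 0.1 * g
          vs[[nm]] <- 0.999 * vs[[nm]] + 0.001 * g^2
          p[[nm]] <- p[[nm]] - 0.05 * (ms[[nm]] / (1 - 0.9^t_step)) /
            (sqrt(vs[[nm]] / (1 - 0.999^t_step)) + 1e-8)
        }
      }
      x_test <- cbind(rnorm(8, 1.5, 0.5), rnorm(8))
      gate <- attr(se_block(x_test, p$w1, p$b1, p$w2, p$b2), "gate")
      gate[1] > gate[2]
    })
  }
  expect_gte(sum(vapply(1:5, run_one, logical(1))), 4)
})

test_that("dense blocks concatenate all previous layers", {
  cfg <- densenet_config(reshape = c(4L, 4L, 4L), stem_channels = 4L,
                         block_layers = c(4L, 2L, 2L), growth = 12L,
                         se_reduction = 4L)
  model <- init_densenet(cfg, seed = 2L)
  x <- matrix(rnorm(16 * 4), 16, 4)
  out <- dense_block(x, model, 1L, 4L, 4L)
  expect_equal(ncol(out), 4L + 4L * 12L)  # in + layers * growth = 52
  # the block input is carried through unchanged in the first columns
  expect_equal(out[, 1:4], x)
  # without dense concatenation a chain would emit only `growth` channels
  expect_false(ncol(out) == cfg$growth)
  # zero input with zero biases stays zero
  z <- dense_block(matrix(0, 16, 4), model, 1L, 4L, 4L)
  expect_equal(max(abs(z)), 0)
  expect_error(dense_block(matrix(0, 16, 5), model, 1L, 4L, 4L),
               "channel plan")
})

test_that("channel bookkeeping holds at every block boundary", {
  cfg <- densenet_config(reshape = c(4L, 8L, 8L), stem_channels = 8L,
                         block_layers = c(4L, 4L, 4L), growth = 12L)
  plan <- sowfuse:::densenet_channel_plan(cfg)
  expect_equal(plan[[1]][["in_ch"]], 8)
  expect_equal(plan[[1]][["out_ch"]], 56)
  expect_equal(plan[[2]][["in_ch"]], 56)
  expect_equal(plan[[2]][["out_ch"]], 104)
  expect_equal(plan[[3]][["out_ch"]], 152)
  model <- init_densenet(cfg, seed = 3L)
  expect_equal(dim(model$params$head_w), c(152L, 2L))
})

test_that("classification produces two deterministic logits", {
  cfg <- densenet_config(reshape = c(4L, 4L, 4L), stem_channels = 4L,
                         block_layers = c(2L, 2L, 2L), growth = 6L,
                         se_reduction = 4L)
  model <- init_densenet(cfg, seed = 4L)
  fused <- rnorm(64)
  z <- classify_fused(fused, model)
  expect_length(z, 2)
  expect_identical(z, classify_fused(fused, model))
  expect_true(which.max(z) %in% 1:2)
})

test_that("SE gates forced to one reproduce the plain DenseNet exactly", {
  cfg_se <- densenet_config(reshape = c(4L, 4L, 4L), stem_channels = 4L,
                            block_layers = c(2L, 2L, 2L), growth = 6L,
                            se_reduction = 4L, use_se = TRUE)
  model <- init_densenet(cfg_se, seed = 5L)
  # bias hack: sigmoid(50) == 1 in double precision
  for (b in 1:3) {
    model$params[[paste0("se", b, "_w2")]][] <- 0
    model$params[[paste0("se", b, "_b2")]][] <- 50
  }
  plain <- model
  plain$cfg$use_se <- FALSE
  fused <- rnorm(64)
  expect_identical(classify_fused(fused, model), classify_fused(fused, plain))
})
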