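# Assembly of the full multimodal classifier: image encoder + audio
# encoder -> fusion -> DenseNet-SE head, trained end-to-end with Adam
# and a reduce-on-plateau learning-rate schedule.

#' Assemble a multimodal estrus classifier
#'
#' Builds the image encoder, audio encoder, fusion module and backbone
#' with consistent dimensions. The component initializations are drawn
#' from sub-seeds derived from `seed`, so two models built with the same
#' seed share identical initial weights in every common component
#' regardless of `fusion_mode` — the property the ablation harness
#' relies on to attribute metric deltas to architecture alone.
#'
#' @param grid a [patch_grid()] for the image branch.
#' @param encoder_cfg an [encoder_config()].
#' @param audio_cfg an [audio_cnn_config()].
#' @param fusion_cfg a [fusion_config()]; its `image_dim`/`audio_dim`
#'   must match the encoder output dims.
#' @param backbone_cfg a [densenet_config()]; `prod(reshape)` must equal
#'   the fused dimension implied by `fusion_mode`.
#' @param fusion_mode `"adaptive"`, `"concat"`, or a numeric image
#'   weight in \[0, 1\] for fixed fusion (1 = image only, 0 = audio only).
#' @param seed integer master seed for initialization.
#' @return list of class `sow_model`.
#' @export
multimodal_model <- function(grid, encoder_cfg, audio_cfg, fusion_cfg,
                             backbone_cfg, fusion_mode = "adaptive",
                             seed = 1L) {
  stopifnot(grid$embed_dim == fusion_cfg$image_dim,
            audio_cfg$out_dim == fusion_cfg$audio_dim)
  fused_dim <- if (identical(fusion_mode, "concat")) {
    fusion_cfg$image_dim + fusion_cfg$audio_dim
  } else {
    fusion_cfg$common_dim
  }
  if (prod(backbone_cfg$reshape) != fused_dim) {
    rlang::abort(sprintf(
      "backbone reshape (%d) does not match the fused dimension (%d)",
      prod(backbone_cfg$reshape), fused_dim))
  }
  seed <- as.integer(seed)
  structure(list(
    image_enc = init_image_encoder(grid, encoder_cfg, seed),
    audio_enc = init_audio_cnn(audio_cfg, seed + 1L),
    fusion = init_fusion(fusion_cfg, seed + 2L),
    backbone = init_densenet(backbone_cfg, seed + 3L),
    fusion_mode = fusion_mode,
    seed = seed
  ), class = "sow_model")
}

# flatten / unflatten parameters with component prefixes
model_flat_params <- function(model) {
  c(stats::setNames(model$image_enc$params,
                    paste0("vit.", names(model$image_enc$params))),
    stats::setNames(model$audio_enc$params,
                    paste0("aud.", names(model$audio_enc$params))),
    stats::setNames(model$fusion$params,
                    paste0("fus.", names(model$fusion$params))),
    stats::setNames(model$backbone$params,
                    paste0("bb.", names(model$backbone$params))))
}

model_set_flat_params <- function(model, flat) {
  strip <- function(prefix) {
    sel <- startsWith(names(flat), prefix)
    stats::setNames(flat[sel], substring(names(flat)[sel], nchar(prefix) + 1L))
  }
  model$image_enc$params <- strip("vit.")
  model$audio_enc$params <- strip("aud.")
  model$fusion$params <- strip("fus.")
  model$backbone$params <- strip("bb.")
  model
}

subset_nodes <- function(nodes, prefix) {
  sel <- startsWith(names(nodes), prefix)
  stats::setNames(nodes[sel], substring(names(nodes)[sel], nchar(prefix) + 1L))
}

# Forward pass for one prepared sample on the tape.  Unimodal fixed
# weights (0 or 1) skip the unused branch: with a weight of exactly 0
# the skipped term is an all-zero matrix, so the shortcut is
# bit-identical to the full computation.
ad_model_forward <- function(sample, nodes, model) {
  mode <- model$fusion_mode
  p_fus <- subset_nodes(nodes, "fus.")
  need_img <- !(is.numeric(mode) && mode == 0)
  need_aud <- !(is.numeric(mode) && mode == 1)
  x <- NULL; y <- NULL
  if (need_img) {
    x <- ad_vit_forward(sample$patches, subset_nodes(nodes, "vit."),
                        model$image_enc$cfg)
  }
  if (need_aud) {
    y <- ad_audio_forward(sample$audio, subset_nodes(nodes, "aud."),
                          model$audio_enc$cfg)
  }
  cfgf <- model$fusion$cfg
  if (is.numeric(mode) && mode == 1) {
    fused <- ad_add_bias(ad_matmul(x, p_fus$proj_img_w), p_fus$proj_img_b)
    att <- 1
  } else if (is.numeric(mode) && mode == 0) {
    fused <- ad_add_bias(ad_matmul(y, p_fus$proj_aud_w), p_fus$proj_aud_b)
    att <- 0
  } else {
    res <- ad_fuse(x, y, p_fus, cfgf, mode)
    fused <- res$fused
    att <- if (is.null(res$a)) NA_real_ else mean(ad_value(res$a))
  }
  logits <- ad_densenet_forward(fused, subset_nodes(nodes, "bb."),
                                model$backbone$cfg)
  list(logits = logits, attention = att)
}

#' Prepare a raw pair for the model
#'
#' Runs the preprocessing front end and caches the model-ready tensors:
#' the thermal image is normalized, standardized, wavelet-denoised,
#' resized to the encoder's grid and split into patches; the audio clip
#' is band-pass denoised, decimated to the encoder's rate and
#' center-cropped/padded to the configured length.
#'
#' @param img numeric matrix (raw grayscale thermal image in \[0,1\]).
#' @param clip an [audio_clip()].
#' @param model a [multimodal_model()].
#' @param label integer 0/1 (optional).
#' @param band passband for audio denoising; the upper edge is capped
#'   at 90% of the clip's Nyquist frequency for low-rate recordings.
#' @param audio_rate target sample rate for the audio branch; the clip
#'   rate must be an integer multiple.
#' @return list with `patches`, `audio` (column matrix), `label`.
#' @export
prepare_sample <- function(img, clip, model, label = NA_integer_,
                           band = c(100, 4000), audio_rate = 4000) {
  pre <- preprocess_image(img)
  pre <- resize_image(pre, model$image_enc$grid$image_size)
  patches <- extract_patches(pre, model$image_enc$grid)
  band[2] <- min(band[2], 0.45 * clip$sample_rate)
  clip <- denoise_audio(clip, cheby_spec(band = band))
  fac <- clip$sample_rate / audio_rate
  if (fac != round(fac)) rlang::abort("clip rate must be a multiple of audio_rate")
  if (fac > 1) clip <- decimate_audio(clip, as.integer(fac))
  x <- fit_to_length(clip$samples, model$audio_enc$cfg$input_len)
  list(patches = patches, audio = matrix(x, ncol = 1),
       label = as.integer(label))
}

#' Training hyperparameters
#'
#' Adam with a reduce-on-plateau schedule: when the validation loss
#' fails to improve for `patience` consecutive epochs, the learning
#' rate is multiplied by `factor`. A fixed step decay every `patience`
#' epochs is available with `schedule = "step"`.
#'
#' @param batch_size minibatch size (default 16).
#' @param epochs training epochs (default 100).
#' @param lr initial learning rate (default 0.001).
#' @param factor learning-rate drop factor in (0,1) (default 0.1).
#' @param patience epochs without validation improvement before a drop
#'   (default 5).
#' @param schedule `"plateau"` (default) or `"step"`.
#' @param seed integer seed for shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 100L, lr = 0.001,
                         factor = 0.1, patience = 5L,
                         schedule = c("plateau", "step"), seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0, factor > 0, factor < 1,
            patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, factor = factor,
                 patience = as.integer(patience),
                 schedule = match.arg(schedule), seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau schedule applied to a validation-loss sequence
#'
#' Pure function over a completed loss history, mirroring the in-training
#' scheduler: after each epoch, if the validation loss did not strictly
#' improve on the best seen so far, a counter increments; when it
#' reaches `patience` the learning rate is multiplied by `factor` and
#' the counter resets.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience,factor,lr0 schedule parameters.
#' @return tibble with `epoch`, `lr` (rate in force during the epoch)
#'   and `dropped` (whether a drop fired at the end of that epoch).
#' @export
plateau_schedule <- function(val_losses, patience = 5L, factor = 0.1,
                             lr0 = 0.001) {
  n <- length(val_losses)
  lr <- lr0; best <- Inf; wait <- 0L
  out_lr <- numeric(n); dropped <- logical(n)
  for (e in seq_len(n)) {
    out_lr[e] <- lr
    if (val_losses[e] < best) {
      best <- val_losses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor; wait <- 0L; dropped[e] <- TRUE
      }
    }
  }
  tibble::tibble(epoch = seq_len(n), lr = out_lr, dropped = dropped)
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# mean cross-entropy of plain logit rows against labels (0/1)
plain_ce <- function(logit_rows, labels) {
  mean(vapply(seq_along(labels), function(i) {
    p <- softmax2(logit_rows[[i]])
    -log(max(p[labels[i] + 1L], 1e-12))
  }, numeric(1)))
}

model_eval_logits <- function(model, samples) {
  flat <- model_flat_params(model)
  nodes <- lapply(flat, ad_const)
  lapply(samples, function(s) {
    as.vector(ad_value(ad_model_forward(s, nodes, model)$logits))
  })
}

#' Train the multimodal classifier
#'
#' Minibatch Adam on the 2-class cross-entropy, with per-epoch
#' validation loss, reduce-on-plateau learning-rate scheduling and
#' best-validation checkpointing. Fully deterministic given the model
#' seed and `tc$seed`. Aborts if the loss becomes non-finite.
#'
#' @param model a [multimodal_model()].
#' @param train,val lists of prepared samples (see [prepare_sample()])
#'   with labels.
#' @param tc a [train_config()].
#' @param verbose print one structured log line per epoch.
#' @return list of class `sow_fit`: the trained `model` (best-validation
#'   weights), `history` tibble (`epoch`, `lr`, `train_loss`,
#'   `val_loss`), `best_epoch`, `tc`.
#' @export
train_model <- function(model, train, val, tc = train_config(),
                        verbose = FALSE) {
  if (!length(train) || !length(val)) rlang::abort("empty train or val split")
  flat <- model_flat_params(model)
  m_state <- lapply(flat, function(x) x * 0)
  v_state <- lapply(flat, function(x) x * 0)
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- tc$lr; best <- Inf; wait <- 0L
  best_flat <- flat; best_epoch <- 0L
  labels_tr <- vapply(train, function(s) s$label, integer(1))
  labels_va <- vapply(val, function(s) s$label, integer(1))
  history <- vector("list", tc$epochs)

  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample(length(train))
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, length(ord), by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
        nodes <- lapply(flat, ad_param)
        logit_list <- lapply(idx, function(i) {
          ad_model_forward(train[[i]], nodes, model)$logits
        })
        logits <- logit_list[[1]]
        if (length(logit_list) > 1) {
          for (j in 2:length(logit_list)) {
            logits <- ad_concat_rows(logits, logit_list[[j]])
          }
        }
        loss <- ad_cross_entropy(logits, labels_tr[idx] + 1L)
        if (!is.finite(loss$val[1])) {
          rlang::abort(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ad_backward(loss)
        t_step <- t_step + 1L
        for (nm in names(flat)) {
          g <- nodes[[nm]]$grad
          if (is.null(g)) next
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
          mhat <- m_state[[nm]] / (1 - beta1^t_step)
          vhat <- v_state[[nm]] / (1 - beta2^t_step)
          flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + loss$val[1]
        n_batches <- n_batches + 1L
      }
      train_loss <- ep_loss / n_batches
      model_tmp <- model_set_flat_params(model, flat)
      val_logits <- model_eval_logits(model_tmp, val)
      val_loss <- plain_ce(val_logits, labels_va)
      history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                         train_loss = train_loss,
                                         val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch=%d lr=%g train_loss=%.4f val_loss=%.4f",
                        epoch, lr, train_loss, val_loss))
      }
      if (val_loss < best) {
        best <- val_loss; wait <- 0L
        best_flat <- flat; best_epoch <- epoch
      } else if (tc$schedule == "plateau") {
        wait <- wait + 1L
        if (wait >= tc$patience) {
          lr <- lr * tc$factor; wait <- 0L
        }
      }
      if (tc$schedule == "step" && epoch %% tc$patience == 0L) {
        lr <- lr * tc$factor
      }
    }
  })
  structure(list(model = model_set_flat_params(model, best_flat),
                 history = dplyr::bind_rows(history),
                 best_epoch = best_epoch, tc = tc),
            class = "sow_fit")
}

#' Predict labels for prepared samples
#'
#' @param object a `sow_fit` (from [train_model()]) or `sow_model`.
#' @param samples list of prepared samples.
#' @param ... unused.
#' @return tibble with `truth`, `estimate`, `prob_estrus`, `attention`
#'   (mean adaptive weight on the image modality; `NA` for
#'   non-adaptive fusion) per sample.
#' @export
predict_samples <- function(object, samples, ...) {
  model <- if (inherits(object, "sow_fit")) object$model else object
  flat <- model_flat_params(model)
  nodes <- lapply(flat, ad_const)
  rows <- lapply(samples, function(s) {
    fw <- ad_model_forward(s, nodes, model)
    z <- as.vector(ad_value(fw$logits))
    p <- softmax2(z)
    tibble::tibble(truth = s$label, estimate = which.max(z) - 1L,
                   prob_estrus = p[2], attention = fw$attention)
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a fitted model on a test set
#'
#' @param fit a `sow_fit` or `sow_model`.
#' @param samples list of prepared, labeled samples.
#' @return one-row tibble: confusion counts plus precision/recall/F1
#'   percentages (see [compute_metrics()]) and mean attention weight.
#' @export
evaluate_model <- function(fit, samples) {
  preds <- predict_samples(fit, samples)
  out <- compute_metrics(confusion_counts(preds$truth, preds$estimate))
  out$accuracy <- mean(preds$truth == preds$estimate) * 100
  out$mean_attention <- mean(preds$attention)
  out
}
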