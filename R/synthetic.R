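# Synthetic paired thermal/vocalization data with controllable class
# effect sizes.  Images emulate a hindquarters thermal frame: a smooth
# ambient background, a localized warm elliptical region whose intensity
# elevation differs by class (the vulvar warming cue), fine bright/dark
# "hair and stain" artifacts, and sensor noise.  Audio emulates farm
# recordings: a harmonic vocalization whose fundamental and harmonic
# count differ by class (estrus calls higher-pitched, amplitude-
# modulated), mains/fan hum at 50 Hz and harmonics, transient
# high-frequency chirps (birds/dripping), and broadband white noise at a
# configurable SNR.

#' Specification of the synthetic paired dataset
#'
#' Defaults generate a class-balanced set of 960 pairs. The class
#' separation knobs are the ellipse intensity elevation
#' (`delta_estrus` vs `delta_non`, on the \[0,1\] intensity scale) and
#' the call pitch bands; setting them equal yields an exactly
#' uninformative (null) dataset.
#'
#' @param n_pairs number of image/audio pairs (even; half per class).
#' @param image_size integer `c(H, W)`.
#' @param delta_estrus,delta_non warm-region elevation per class.
#' @param delta_jitter half-width of the uniform per-animal jitter on
#'   the elevation; with the defaults the class elevation ranges
#'   overlap slightly, so the thermal cue is strong but not perfect.
#' @param ellipse_axes ellipse semi-axes as fractions of image size.
#' @param hair_density fraction of pixels hit by hair/stain artifacts.
#' @param hair_amplitude artifact amplitude on the \[0,1\] scale.
#' @param image_noise_sd Gaussian sensor noise s.d.
#' @param sample_rate audio rate in Hz (16 kHz default; use 44100 for
#'   full-rate fidelity checks).
#' @param duration clip length in seconds.
#' @param estrus_f0,non_f0 fundamental-frequency ranges `c(lo, hi)` Hz.
#' @param estrus_harmonics,non_harmonics number of harmonics.
#' @param estrus_am_hz amplitude-modulation rate of estrus calls (Hz;
#'   0 disables).
#' @param hum_amp amplitude of the 50 Hz hum stack.
#' @param chirp_band chirp frequency band `c(lo, hi)` Hz.
#' @param chirp_amp chirp amplitude.
#' @param noise_snr_db white-noise SNR relative to the call, in dB.
#' @param call_overlap_frac fraction of samples whose call is drawn from
#'   the other class's call distribution (silent estrus / distress calls
#'   in non-estrus sows), capping how informative audio alone can be —
#'   the thermal cue stays the stronger modality, as on farm data.
#' @param image_occlusion_frac fraction of samples whose warm region is
#'   mostly hidden (tail position, dung, camera angle): the ellipse
#'   elevation is attenuated to 30% for those frames. Together with
#'   `call_overlap_frac` this gives the two modalities *complementary*
#'   failure modes, the situation input-dependent fusion exists for.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pairs = 960L, image_size = c(96L, 96L),
                           delta_estrus = 0.35, delta_non = 0.15,
                           delta_jitter = 0.10,
                           ellipse_axes = c(0.18, 0.12),
                           hair_density = 0.02, hair_amplitude = 0.2,
                           image_noise_sd = 0.06,
                           sample_rate = 16000L, duration = 1,
                           estrus_f0 = c(250, 350), estrus_harmonics = 5L,
                           estrus_am_hz = 8,
                           non_f0 = c(120, 180), non_harmonics = 3L,
                           hum_amp = 0.35, chirp_band = c(6000, 7500),
                           chirp_amp = 0.5, noise_snr_db = 3,
                           call_overlap_frac = 0.2,
                           image_occlusion_frac = 0.10, seed = 1L) {
  stopifnot(n_pairs %% 2 == 0, n_pairs >= 2,
            max(chirp_band) < sample_rate / 2,
            max(estrus_f0) * estrus_harmonics < sample_rate / 2)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Null version of a synthetic spec
#'
#' Equalizes every class-dependent parameter (elevation, pitch band,
#' harmonic count, amplitude modulation), so labels carry no signal and
#' any classifier's expected accuracy is 50%.
#'
#' @param spec a [synthetic_spec()].
#' @return the modified spec.
#' @export
null_synthetic_spec <- function(spec) {
  spec$delta_non <- spec$delta_estrus
  spec$non_f0 <- spec$estrus_f0
  spec$non_harmonics <- spec$estrus_harmonics
  # both classes amplitude-modulated identically
  spec$null_am <- TRUE
  spec
}

# Latent per-sample parameters, a pure function of the spec.
#' Latent ground-truth parameters of every sample
#'
#' Regenerates (deterministically from the spec seed) the latent
#' parameters each sample was built from: ellipse center/elevation,
#' call fundamental, per-sample noise seed. Enables oracle checks of
#' the preprocessing stages.
#'
#' @param spec a [synthetic_spec()].
#' @return tibble with one row per sample.
#' @export
synthetic_latents <- function(spec) {
  n <- spec$n_pairs
  h <- spec$image_size[1]; w <- spec$image_size[2]
  withr::with_seed(as.integer(spec$seed), {
    label <- rep(c(1L, 0L), n / 2)
    # silent estrus / distress calls: the call follows the other class
    flip <- stats::runif(n) < spec$call_overlap_frac
    call_class <- ifelse(flip, 1L - label, label)
    # occluded warm region: tail/dung/angle hides most of the elevation
    occluded <- stats::runif(n) < spec$image_occlusion_frac
    tibble::tibble(
      sample_id = sprintf("syn%04d", seq_len(n)),
      label = label,
      call_class = call_class,
      occluded = occluded,
      cx = stats::runif(n, 0.35 * w, 0.65 * w),
      cy = stats::runif(n, 0.35 * h, 0.65 * h),
      elevation = ifelse(label == 1L, spec$delta_estrus, spec$delta_non) +
        stats::runif(n, -spec$delta_jitter, spec$delta_jitter),
      f0 = ifelse(call_class == 1L,
                  stats::runif(n, spec$estrus_f0[1], spec$estrus_f0[2]),
                  stats::runif(n, spec$non_f0[1], spec$non_f0[2])),
      snr_db = spec$noise_snr_db + stats::runif(n, -1, 1),
      noise_seed = sample.int(2^30, n)
    )
  })
}

#' Ground truth for one generated sample
#'
#' @param spec a [synthetic_spec()].
#' @param sample_id sample identifier (e.g. `"syn0001"`).
#' @return one-row tibble of latent parameters.
#' @export
ground_truth <- function(spec, sample_id) {
  lat <- synthetic_latents(spec)
  row <- lat[lat$sample_id == sample_id, , drop = FALSE]
  if (!nrow(row)) rlang::abort(paste0("unknown sample_id: ", sample_id))
  row
}

# One synthetic thermal image from a latent row.  Values in [0, 1].
# clean = TRUE returns the noiseless, artifact-free image (background +
# warm ellipse only) — the ground truth for denoising checks.
synth_image <- function(lat, spec, clean = FALSE) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  ry <- matrix(seq_len(h), h, w)
  rx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # smooth ambient background with a mild gradient
  bg <- 0.35 + 0.08 * (rx / w) + 0.05 * (ry / h)
  ax <- spec$ellipse_axes[1] * w
  ay <- spec$ellipse_axes[2] * h
  d2 <- ((rx - lat$cx) / ax)^2 + ((ry - lat$cy) / ay)^2
  elev <- lat$elevation * if (isTRUE(lat$occluded)) 0.3 else 1
  base <- bg + elev * exp(-d2)             # soft-edged warm ellipse
  if (clean) return(pmin(pmax(base, 0), 1))
  withr::with_seed(lat$noise_seed, {
    img <- base
    # hair/stain artifacts: sparse bright/dark speckle plus short strokes
    n_spk <- stats::rpois(1, spec$hair_density * h * w)
    if (n_spk > 0) {
      pix <- sample.int(h * w, n_spk)
      img[pix] <- img[pix] + spec$hair_amplitude *
        sample(c(-1, 1), n_spk, replace = TRUE) * stats::runif(n_spk, 0.5, 1)
    }
    n_strokes <- stats::rpois(1, 6)
    for (s in seq_len(n_strokes)) {
      y0 <- sample.int(h, 1); x0 <- sample.int(w, 1)
      len <- sample(4:10, 1)
      dy <- sample(c(-1L, 0L, 1L), 1); dx <- sample(c(-1L, 0L, 1L), 1)
      if (dy == 0 && dx == 0) dx <- 1L
      amp <- spec$hair_amplitude * sample(c(-1, 1), 1)
      ys <- pmin(pmax(y0 + dy * (0:len), 1L), h)
      xs <- pmin(pmax(x0 + dx * (0:len), 1L), w)
      img[cbind(ys, xs)] <- img[cbind(ys, xs)] + amp
    }
    img <- img + matrix(stats::rnorm(h * w, sd = spec$image_noise_sd), h, w)
    pmin(pmax(img, 0), 1)
  })
}

# One synthetic vocalization clip from a latent row.
synth_audio <- function(lat, spec) {
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(lat$noise_seed + 1L, {
    n_h <- if (lat$call_class == 1L) spec$estrus_harmonics else spec$non_harmonics
    call <- numeric(n)
    for (k in seq_len(n_h)) {
      call <- call + (1 / k) * sin(2 * pi * k * lat$f0 * t +
                                     stats::runif(1, 0, 2 * pi))
    }
    am_on <- lat$call_class == 1L || isTRUE(spec$null_am)
    if (am_on && spec$estrus_am_hz > 0) {
      call <- call * (0.6 + 0.4 * sin(2 * pi * spec$estrus_am_hz * t))
    }
    call <- call / sqrt(mean(call^2))
    hum <- spec$hum_amp * (sin(2 * pi * 50 * t) +
                             0.5 * sin(2 * pi * 100 * t) +
                             0.25 * sin(2 * pi * 150 * t))
    chirps <- numeric(n)
    for (ch in seq_len(stats::rpois(1, 3))) {
      f_c <- stats::runif(1, spec$chirp_band[1], spec$chirp_band[2])
      start <- sample.int(n - round(0.05 * fs), 1)
      span <- start:(start + round(0.05 * fs) - 1)
      env <- sin(pi * seq_along(span) / length(span))^2
      chirps[span] <- chirps[span] +
        spec$chirp_amp * env * sin(2 * pi * f_c * t[span])
    }
    noise_sd <- 10^(-lat$snr_db / 20)
    x <- call + hum + chirps + stats::rnorm(n, sd = noise_sd)
    audio_clip(x / max(abs(x)), fs)
  })
}

#' Generate the synthetic dataset in memory
#'
#' @param spec a [synthetic_spec()].
#' @return list with `manifest` (tibble: `sample_id`, `label`),
#'   `images` (list of matrices), `clips` (list of [audio_clip()]s) and
#'   `latents`.
#' @export
generate_dataset <- function(spec) {
  lat <- synthetic_latents(spec)
  images <- vector("list", nrow(lat))
  clips <- vector("list", nrow(lat))
  for (i in seq_len(nrow(lat))) {
    images[[i]] <- synth_image(lat[i, ], spec)
    clips[[i]] <- synth_audio(lat[i, ], spec)
  }
  list(manifest = tibble::tibble(sample_id = lat$sample_id,
                                 label = lat$label),
       images = images, clips = clips, latents = lat)
}

#' Generate the synthetic dataset on disk
#'
#' Writes one PNG and one WAV per pair, a manifest CSV linking them,
#' and the spec as YAML. Byte-identical across runs with equal spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble (with file paths), invisibly.
#' @export
generate_pairs <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lat <- synthetic_latents(spec)
  man <- tibble::tibble(
    sample_id = lat$sample_id,
    image_path = file.path(dir, paste0(lat$sample_id, ".png")),
    audio_path = file.path(dir, paste0(lat$sample_id, ".wav")),
    label = lat$label
  )
  for (i in seq_len(nrow(lat))) {
    write_image(synth_image(lat[i, ], spec), man$image_path[i])
    write_wav(synth_audio(lat[i, ], spec), man$audio_path[i])
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  invisible(man)
}

#' Hand-crafted oracle features for a pair
#'
#' Two interpretable features used as a separability floor for the deep
#' pipeline: the mean intensity in the top decile of image pixels (a
#' proxy for warm-region elevation) and the fraction of audio power in
#' the estrus call band (200-1800 Hz) relative to the non-estrus band
#' (80-200 Hz).
#'
#' @param img image matrix.
#' @param clip an [audio_clip()].
#' @return one-row tibble with `warm_mean`, `band_ratio`.
#' @export
oracle_features <- function(img, clip) {
  warm <- mean(img[img >= stats::quantile(img, 0.9)])
  hi <- band_power_fraction(clip, c(200, 1800))
  lo <- band_power_fraction(clip, c(80, 200))
  tibble::tibble(warm_mean = warm, band_ratio = hi / (hi + lo))
}

#' Logistic-regression oracle accuracy on a synthetic dataset
#'
#' Fits a logistic model on the two [oracle_features()] over a train
#' fraction and reports held-out accuracy — the simple-classifier floor
#' the deep pipeline should comfortably clear (and the null-calibration
#' instrument when the spec is null).
#'
#' @param dataset from [generate_dataset()].
#' @param train_frac fraction used for fitting.
#' @param seed split seed.
#' @return held-out accuracy in \[0, 1\].
#' @export
oracle_accuracy <- function(dataset, train_frac = 0.6, seed = 1L) {
  feats <- dplyr::bind_rows(lapply(seq_along(dataset$images), function(i) {
    oracle_features(dataset$images[[i]], dataset$clips[[i]])
  }))
  feats$label <- dataset$manifest$label
  n <- nrow(feats)
  idx <- withr::with_seed(seed, sample(n, round(train_frac * n)))
  fit <- suppressWarnings(
    stats::glm(label ~ warm_mean + band_ratio, family = stats::binomial(),
               data = feats[idx, ]))
  pred <- as.integer(
    stats::predict(fit, feats[-idx, ], type = "response") > 0.5)
  mean(pred == feats$label[-idx])
}
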