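# Frequency-domain denoising of vocalization recordings: DFT, Chebyshev
# Type-I band-pass magnitude applied bin-wise (zero-phase), inverse DFT.
# Farm recordings mix the pig calls with mains/fan hum (narrowband, low
# frequency), bird chirps and dripping (high frequency) and broadband
# noise; a band-pass around the vocalization band removes the out-of-band
# components exactly and attenuates in-band noise not at all -- the
# trade-off is documented in the methods vignette.

#' Discrete Fourier transform of an audio clip
#'
#' `X(f) = sum_n x(n) exp(-i 2 pi f n / N)` via the FFT. Multi-channel
#' clips are mixed to mono first.
#'
#' @param clip an [audio_clip()].
#' @return list of class `audio_spectrum` with complex `bins` (length
#'   `N`), `sample_rate` and `n`.
#' @export
audio_fft <- function(clip) {
  clip <- as_mono(clip)
  x <- clip$samples
  if (!length(x)) rlang::abort("empty signal")
  structure(list(bins = stats::fft(x), sample_rate = clip$sample_rate,
                 n = length(x)),
            class = "audio_spectrum")
}

#' Inverse discrete Fourier transform back to a clip
#'
#' @param spec an `audio_spectrum`.
#' @return an [audio_clip()]; errors if the imaginary residue exceeds
#'   `1e-6` of the signal scale (non-Hermitian input).
#' @export
audio_ifft <- function(spec) {
  y <- stats::fft(spec$bins, inverse = TRUE) / spec$n
  scale <- max(Mod(spec$bins) / spec$n, 1)
  if (max(abs(Im(y))) > 1e-6 * scale) {
    rlang::warn("large imaginary residue after inverse FFT; taking real part")
  }
  audio_clip(Re(y), spec$sample_rate)
}

#' Chebyshev Type-I band-pass filter specification
#'
#' Analog-prototype transfer magnitude
#' `|H| = G / sqrt(1 + eps^2 T_N^2(w / w_p))` with ripple factor
#' `eps = sqrt(10^(ripple_db/10) - 1)`, evaluated through the standard
#' low-pass to band-pass frequency mapping.
#'
#' @param order filter order `N` (default 4).
#' @param ripple_db passband ripple in dB (default 0.5).
#' @param band numeric `c(f_lo, f_hi)` passband edges in Hz
#'   (default `c(100, 4000)`, covering grunt fundamentals and scream
#'   harmonics while excluding mains hum and high-frequency chirps).
#' @param gain passband gain `G` (default 1).
#' @return list of class `cheby_spec`.
#' @export
cheby_spec <- function(order = 4L, ripple_db = 0.5, band = c(100, 4000),
                       gain = 1) {
  stopifnot(order >= 1, ripple_db > 0, length(band) == 2,
            band[1] > 0, band[2] > band[1], gain > 0)
  structure(list(order = as.integer(order), ripple_db = ripple_db,
                 band = band, gain = gain,
                 eps = sqrt(10^(ripple_db / 10) - 1)),
            class = "cheby_spec")
}

# Chebyshev polynomial of the first kind, via the trigonometric /
# hyperbolic closed forms (|x| > 1 may overflow to Inf, which maps to a
# magnitude of exactly 0 downstream).
chebyshev_t <- function(n, x) {
  out <- numeric(length(x))
  inside <- abs(x) <= 1
  out[inside] <- cos(n * acos(x[inside]))
  xa <- abs(x[!inside])
  out[!inside] <- (sign(x[!inside])^n) * cosh(n * log(xa + sqrt(xa^2 - 1)))
  out
}

#' Band-pass magnitude response
#'
#' Evaluates the Chebyshev Type-I low-pass prototype magnitude under the
#' low-pass to band-pass mapping `w -> (w^2 - w0^2) / (B w)` with center
#' `w0^2 = w_lo * w_hi` and bandwidth `B = w_hi - w_lo`. Exactly
#' `G / sqrt(1 + eps^2)` at both passband edges; at most `G` anywhere.
#'
#' @param spec a [cheby_spec()].
#' @param f frequency or vector of frequencies in Hz (`f >= 0`).
#' @return magnitude response, same length as `f`.
#' @export
cheby1_magnitude <- function(spec, f) {
  stopifnot(inherits(spec, "cheby_spec"), all(f >= 0))
  flo <- spec$band[1]; fhi <- spec$band[2]
  x <- ifelse(f == 0, Inf, (f^2 - flo * fhi) / ((fhi - flo) * f))
  tn <- chebyshev_t(spec$order, x)
  spec$gain / sqrt(1 + spec$eps^2 * tn^2)
}

#' Apply the band-pass filter to a clip in the frequency domain
#'
#' FFT, bin-wise multiplication by the real magnitude response (a
#' zero-phase application: no group delay is introduced), inverse FFT.
#' Multi-channel input is averaged to mono before filtering. A
#' conventional time-domain IIR realization (bilinear-transform
#' `signal::cheby1` + forward-backward filtering) is available with
#' `method = "iir"`.
#'
#' @param clip an [audio_clip()].
#' @param spec a [cheby_spec()]; `band[2]` must lie below the Nyquist
#'   frequency.
#' @param method `"spectral"` (default) or `"iir"`.
#' @return filtered mono [audio_clip()], same length and rate.
#' @export
bandpass_filter <- function(clip, spec, method = c("spectral", "iir")) {
  method <- match.arg(method)
  clip <- as_mono(clip)
  if (spec$band[2] >= clip$sample_rate / 2) {
    rlang::abort("upper passband edge must be below the Nyquist frequency")
  }
  if (method == "iir") {
    if (!requireNamespace("signal", quietly = TRUE)) {
      rlang::abort("method = 'iir' requires the 'signal' package")
    }
    flt <- signal::cheby1(spec$order, spec$ripple_db,
                          W = spec$band / (clip$sample_rate / 2),
                          type = "pass")
    y <- signal::filtfilt(flt, clip$samples) * spec$gain
    return(audio_clip(y, clip$sample_rate))
  }
  sp <- audio_fft(clip)
  k <- seq_len(sp$n) - 1L
  fk <- pmin(k, sp$n - k) * sp$sample_rate / sp$n  # alias-aware bin frequency
  sp$bins <- sp$bins * cheby1_magnitude(spec, fk)
  audio_ifft(sp)
}

#' Denoise a vocalization recording
#'
#' The audio preprocessing stage: mix to mono and band-pass to the
#' vocalization band, removing narrowband hum, high-frequency chirps and
#' out-of-band broadband noise.
#'
#' @inheritParams bandpass_filter
#' @return denoised mono [audio_clip()].
#' @export
denoise_audio <- function(clip, spec = cheby_spec(), method = "spectral") {
  bandpass_filter(clip, spec, method)
}

#' Decimate a clip to a lower sample rate
#'
#' Spectral low-pass at the new Nyquist frequency (bin zeroing) followed
#' by point decimation. `factor` must divide the clip length.
#'
#' @param clip an [audio_clip()].
#' @param factor integer decimation factor.
#' @return decimated [audio_clip()] at `sample_rate / factor`.
#' @export
decimate_audio <- function(clip, factor) {
  clip <- as_mono(clip)
  n <- clip_length(clip)
  stopifnot(factor >= 1, n %% factor == 0L)
  if (factor == 1L) return(clip)
  sp <- audio_fft(clip)
  k <- seq_len(n) - 1L
  fk <- pmin(k, n - k) * clip$sample_rate / n
  cutoff <- clip$sample_rate / (2 * factor)
  sp$bins[fk >= cutoff] <- 0
  y <- audio_ifft(sp)
  audio_clip(y$samples[seq(1L, n, by = factor)], clip$sample_rate / factor)
}

#' Fraction of signal power inside a frequency band
#'
#' Spectral bookkeeping helper used to verify denoising: the share of
#' total power carried by DFT bins whose (alias-aware) frequency lies in
#' `band`.
#'
#' @param clip an [audio_clip()].
#' @param band numeric `c(f_lo, f_hi)` in Hz.
#' @return scalar in \[0, 1\].
#' @export
band_power_fraction <- function(clip, band) {
  sp <- audio_fft(clip)
  k <- seq_len(sp$n) - 1L
  fk <- pmin(k, sp$n - k) * sp$sample_rate / sp$n
  p <- Mod(sp$bins)^2
  sum(p[fk >= band[1] & fk <= band[2]]) / sum(p)
}
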