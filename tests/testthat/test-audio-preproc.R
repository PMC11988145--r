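test_that("DFT of impulse and constant signals matches closed forms", {
  imp <- audio_clip(c(1, 0, 0, 0), 8000)
  expect_equal(audio_fft(imp)$bins, complex(real = rep(1, 4)), tolerance = 1e-12)
  const <- audio_clip(rep(2.5, 16), 8000)
  sp <- audio_fft(const)
  expect_equal(Re(sp$bins[1]), 2.5 * 16)
  expect_lt(max(Mod(sp$bins[-1])), 1e-9)
  expect_error(audio_fft(audio_clip(numeric(0), 8000)))
})

test_that("Parseval holds and the inverse DFT round-trips", {
  set.seed(1)
  x <- rnorm(1024)
  clip <- audio_clip(x, 16000)
  sp <- audio_fft(clip)
  expect_lt(abs(sum(x^2) - sum(Mod(sp$bins)^2) / sp$n) / sum(x^2), 1e-6)
  back <- audio_ifft(sp)
  expect_lt(max(abs(back$samples - x)), 1e-9)
})

test_that("Chebyshev polynomial closed form matches the recurrence oracle", {
  cheb_rec <- function(n, x) {   # independent oracle: T_{n+1} = 2x T_n - T_{n-1}
    tm <- rep(1, length(x)); tc <- x
    if (n == 0) return(tm)
    for (k in seq_len(n - 1)) {
      tn <- 2 * x * tc - tm
      tm <- tc; tc <- tn
    }
    tc
  }
  set.seed(2)
  x <- runif(50, -3, 3)
  for (n in 1:8) {
    expect_equal(sowfuse:::chebyshev_t(n, x), cheb_rec(n, x),
                 tolerance = 1e-9)
  }
})

test_that("magnitude response hits G/sqrt(1+eps^2) at both passband edges", {
  spec <- cheby_spec(order = 4, ripple_db = 0.5, band = c(100, 4000), gain = 1)
  edge <- spec$gain / sqrt(1 + spec$eps^2)
  expect_lt(abs(cheby1_magnitude(spec, 100) - edge), 1e-9)
  expect_lt(abs(cheby1_magnitude(spec, 4000) - edge), 1e-9)
})

test_that("the passband response is equiripple-bounded and roll-off steep", {
  spec <- cheby_spec()
  f_in <- seq(100, 4000, length.out = 400)
  h <- cheby1_magnitude(spec, f_in)
  expect_true(all(h >= spec$gain / sqrt(1 + spec$eps^2) - 1e-12))
  expect_true(all(h <= spec$gain + 1e-12))
  # at 2 x f_hi the order-4 filter attenuates by at least 20 dB
  att_db <- -20 * log10(cheby1_magnitude(spec, 8000) / spec$gain)
  expect_gte(att_db, 20)
})

test_that("an in-band sinusoid passes with near-unit amplitude", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 1000 * t)
  y <- bandpass_filter(audio_clip(x, fs), cheby_spec())
  spec <- cheby_spec()
  amp <- max(abs(y$samples))
  expect_gte(amp, 1 / sqrt(1 + spec$eps^2) * 0.98)
  expect_lte(amp, 1.02)
})

test_that("an out-of-band sinusoid is strongly attenuated", {
  fs <- 44100
  t <- (0:(fs / 2 - 1)) / fs
  x <- sin(2 * pi * 8000 * t)
  y <- bandpass_filter(audio_clip(x, fs), cheby_spec())
  expect_lte(sqrt(mean(y$samples^2)), 0.1 * sqrt(mean(x^2)))
})

test_that("filtering is linear, zero-phase, and never adds energy at G=1", {
  set.seed(3)
  fs <- 8000
  spec <- cheby_spec(band = c(100, 3000))
  x <- rnorm(2048)
  y <- rnorm(2048)
  fx <- bandpass_filter(audio_clip(x, fs), spec)$samples
  fy <- bandpass_filter(audio_clip(y, fs), spec)$samples
  fxy <- bandpass_filter(audio_clip(2 * x - 3 * y, fs), spec)$samples
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
  # zero signal maps to zero
  z <- bandpass_filter(audio_clip(numeric(512) , fs), spec)$samples
  expect_equal(max(abs(z)), 0)
  # energy non-increasing
  expect_lte(sum(fx^2), sum(x^2))
  # zero phase: an in-band tone keeps its alignment (peak lag 0)
  t <- (0:2047) / fs
  tone <- sin(2 * pi * 500 * t)
  ft <- bandpass_filter(audio_clip(tone, fs), spec)$samples
  cc <- stats::ccf(ft, tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stereo input is averaged to mono before filtering", {
  set.seed(4)
  fs <- 8000
  left <- rnorm(1024)
  right <- rnorm(1024)
  st <- audio_clip(cbind(left, right), fs)
  spec <- cheby_spec(band = c(100, 3000))
  expect_equal(bandpass_filter(st, spec)$samples,
               bandpass_filter(audio_clip((left + right) / 2, fs), spec)$samples)
})

test_that("denoising a grunt-plus-noise mixture concentrates power in band", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  grunt <- rowSums(sapply(1:5, function(k) (1 / k) * sin(2 * pi * k * 300 * t)))
  hum <- 0.8 * sin(2 * pi * 50 * t)
  chirp <- 0.6 * sin(2 * pi * 7000 * t) * (t < 0.1)
  mix <- audio_clip(grunt + hum + chirp, fs)
  den <- denoise_audio(mix)
  expect_gte(band_power_fraction(den, c(100, 4000)), 0.95)
})

test_that("already band-limited input passes nearly unchanged", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 400 * t) + 0.5 * sin(2 * pi * 1200 * t)
  y <- denoise_audio(audio_clip(x, fs))$samples
  expect_gte(stats::cor(x, y), 0.99)
})

test_that("the IIR realization agrees with the spectral path in the passband", {
  skip_if_not_installed("signal")
  fs <- 16000
  t <- (0:(fs / 2 - 1)) / fs
  x <- sin(2 * pi * 800 * t)
  a <- bandpass_filter(audio_clip(x, fs), cheby_spec(), method = "spectral")
  b <- bandpass_filter(audio_clip(x, fs), cheby_spec(), method = "iir")
  mid <- 2000:6000  # away from edge transients
  expect_gte(stats::cor(a$samples[mid], b$samples[mid]), 0.99)
})

test_that("upper band edge must stay below Nyquist", {
  expect_error(bandpass_filter(audio_clip(rnorm(100), 4000), cheby_spec()),
               "Nyquist")
})

test_that("decimation keeps the in-band spectral peak", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 300 * t)
  d <- decimate_audio(audio_clip(x, fs), 8L)
  expect_equal(d$sample_rate, 2000)
  sp <- Mod(stats::fft(d$samples))^2
  freqs <- (seq_along(sp) - 1) * 2000 / length(sp)
  half <- freqs <= 1000
  expect_equal(freqs[half][which.max(sp[half])], 300, tolerance = 1.1)
})

test_that("WAV files round-trip in PCM16 and float32, mono and stereo", {
  set.seed(5)
  x <- runif(400, -0.9, 0.9)
  tmp <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_clip(x, 4000), tmp, bits = 16L)
  back <- read_wav(tmp)
  expect_equal(back$sample_rate, 4000)
  expect_lt(max(abs(back$samples - x)), 1 / 32768)

  tmp2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_clip(x, 4000), tmp2, bits = 32L)
  expect_equal(read_wav(tmp2)$samples, x, tolerance = 1e-7)

  st <- cbind(x, rev(x))
  tmp3 <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_clip(st, 8000), tmp3)
  back3 <- read_wav(tmp3)
  expect_true(is.matrix(back3$samples))
  expect_lt(max(abs(back3$samples - st)), 1 / 32768)
})
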