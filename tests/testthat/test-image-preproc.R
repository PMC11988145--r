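test_that("min-max normalization maps the range to [0,1] affinely", {
  img <- matrix(c(0, 10, 5, 5), 2, 2)
  expect_equal(normalize_image(img), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  set.seed(1)
  r <- normalize_image(matrix(rnorm(64), 8, 8))
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)
  expect_warning(z <- normalize_image(matrix(7, 2, 2)), "constant")
  expect_equal(z, matrix(0, 2, 2))
})

test_that("standardization gives mean 0, population sd 1, and is idempotent", {
  expect_equal(standardize_image(matrix(c(1, 3), 1, 2)),
               matrix(c(-1, 1), 1, 2))
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  s <- standardize_image(img)
  expect_lt(abs(mean(s)), 1e-9)
  expect_lt(abs(sqrt(mean((s - mean(s))^2)) - 1), 1e-9)
  expect_lt(max(abs(standardize_image(s) - s)), 1e-9)
  expect_error(standardize_image(matrix(5, 3, 3)), "constant")
})

test_that("Haar transform of a constant 2x2 image is a pure approximation", {
  d <- dwt2(matrix(3, 2, 2), "haar", 1L)
  expect_equal(d$approx, matrix(6, 1, 1))  # 2 * c for c = 3
  expect_equal(d$details[[1]]$lh, matrix(0, 1, 1))
  expect_equal(d$details[[1]]$hl, matrix(0, 1, 1))
  expect_equal(d$details[[1]]$hh, matrix(0, 1, 1))
})

test_that("DWT is orthonormal: Parseval and perfect reconstruction", {
  set.seed(3)
  for (wv in c("haar", "db2", "db4")) {
    for (dims in list(c(32, 32), c(64, 48))) {
      img <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      d <- dwt2(img, wv, 2L)
      expect_lt(abs(decomposition_energy(d) - sum(img^2)) / sum(img^2), 1e-6)
      expect_lt(max(abs(idwt2(d) - img)), 1e-8)
    }
  }
})

test_that("DWT rejects unknown wavelets and undersized images", {
  img <- matrix(rnorm(16), 4, 4)
  expect_error(dwt2(img, "sym5", 1L), "unknown wavelet")
  expect_error(dwt2(img, "db4", 1L), "too small")   # needs >= 8 rows
  expect_error(dwt2(matrix(rnorm(6), 2, 3), "haar", 1L), "even")
})

test_that("hard thresholding zeroes small details and keeps the rest", {
  set.seed(4)
  img <- matrix(rnorm(64), 8, 8)
  d <- dwt2(img, "haar", 1L)
  d$details[[1]]$hh[1, 1:4] <- c(3.2, -0.5, 1.1, -4.0)
  th <- hard_threshold(d, 1.0)
  expect_equal(th$details[[1]]$hh[1, 1:4], c(3.2, 0, 1.1, -4.0))
  # surviving coefficients are unchanged, not shrunk
  keep <- abs(d$details[[1]]$lh) >= 1.0
  expect_equal(th$details[[1]]$lh[keep], d$details[[1]]$lh[keep])
  # lambda = 0 is the identity
  expect_identical(hard_threshold(d, 0)$details, d$details)
  # idempotence
  expect_identical(hard_threshold(th, 1.0)$details, th$details)
  # approximation band is never thresholded
  expect_identical(hard_threshold(d, 1e9)$approx, d$approx)
  # energy never increases
  expect_lte(decomposition_energy(hard_threshold(d, 0.7)),
             decomposition_energy(d))
  expect_error(hard_threshold(d, -1), "nonnegative")
})

test_that("soft mode shrinks survivors toward zero", {
  d <- dwt2(matrix(rnorm(64), 8, 8), "haar", 1L)
  s <- hard_threshold(d, 0.5, mode = "soft")
  i <- which(abs(d$details[[1]]$hh) >= 0.5)
  expect_equal(abs(s$details[[1]]$hh[i]), abs(d$details[[1]]$hh[i]) - 0.5)
})

test_that("reconstruction bookkeeping: removed detail energy reappears as residual", {
  set.seed(5)
  img <- matrix(rnorm(32 * 32), 32, 32)
  d <- dwt2(img, "db2", 2L)
  lam <- max(abs(unlist(d$details))) + 1
  approx_only <- idwt2(hard_threshold(d, lam))
  removed <- decomposition_energy(d) - sum(d$approx^2)
  resid <- sum((img - approx_only)^2)
  expect_lt(abs(resid - removed) / removed, 1e-6)
  # all-zero coefficients reconstruct the zero image
  z <- d
  z$approx <- z$approx * 0
  z$details <- lapply(z$details, function(l) lapply(l, function(m) m * 0))
  expect_equal(max(abs(idwt2(z))), 0)
})

test_that("fixed-mode denoising with lambda 0 is the identity", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- denoise_image(img, threshold = "fixed", lambda = 0)
  expect_lt(max(abs(out - img)), 1e-8)
})

test_that("universal-threshold denoising reduces MSE on speckled images", {
  clean <- smooth_image(32, 32)
  wins <- 0
  for (sd in 1:20) {
    noisy <- withr::with_seed(sd, {
      n_spk <- 40
      x <- clean + matrix(rnorm(length(clean), sd = 0.02),
                          nrow(clean), ncol(clean))
      pix <- sample(length(x), n_spk)
      x[pix] <- x[pix] + sample(c(-1, 1), n_spk, TRUE) * runif(n_spk, 0.3, 0.5)
      x
    })
    den <- denoise_image(noisy)
    if (mean((den - clean)^2) < mean((noisy - clean)^2)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("denoising preserves the warm-region maximum location", {
  # localize the warm region as the argmax of a 7x7 box-smoothed image
  # (the ellipse top is flat, so a raw per-pixel argmax wanders under
  # residual coarse-scale noise); the denoised localization must agree
  # with the clean ground-truth image to within 3 px
  boxk <- function(m, r = 3L) {
    k <- matrix(0, nrow(m), ncol(m))
    n <- nrow(m); w <- ncol(m)
    for (dr in -r:r) for (dc in -r:r) {
      rs <- pmin(pmax(seq_len(n) + dr, 1), n)
      cs <- pmin(pmax(seq_len(w) + dc, 1), w)
      k <- k + m[rs, cs]
    }
    k / (2 * r + 1)^2
  }
  spec <- synthetic_spec(n_pairs = 10L, seed = 9L)
  lat <- synthetic_latents(spec)
  ok <- 0
  for (i in which(lat$label == 1L)) {
    clean <- sowfuse:::synth_image(lat[i, ], spec, clean = TRUE)
    ref <- arrayInd(which.max(boxk(clean)), dim(clean))
    den <- denoise_image(sowfuse:::synth_image(lat[i, ], spec))
    peak <- arrayInd(which.max(boxk(den)), dim(den))
    if (sqrt(sum((peak - ref)^2)) <= 3) ok <- ok + 1
  }
  expect_gte(ok, 4)  # 5 estrus samples in a 10-pair balanced set
})

test_that("the preprocessing pipeline is deterministic", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(preprocess_image(img), preprocess_image(img))
})

test_that("resize averages exactly for integer factors and interpolates otherwise", {
  img <- matrix(1:16, 4, 4)
  half <- resize_image(img, c(2, 2))
  expect_equal(half[1, 1], mean(img[1:2, 1:2]))
  expect_equal(half[2, 2], mean(img[3:4, 3:4]))
  odd <- resize_image(matrix(runif(35), 5, 7), c(3, 4))
  expect_equal(dim(odd), c(3L, 4L))
  expect_true(all(is.finite(odd)))
})

test_that("PNG write/read round-trips a grayscale matrix", {
  tmp <- withr::local_tempfile(fileext = ".png")
  img <- matrix(runif(64), 8, 8)
  write_image(img, tmp)
  back <- read_image(tmp)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
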