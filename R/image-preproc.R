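# Thermal-image preprocessing: intensity normalization, per-image
# standardization, and multi-level wavelet hard-threshold denoising to
# suppress fine-scale hair/stain texture while keeping the warm-region
# structure that carries the estrus cue.

# Orthonormal Daubechies scaling filters (analysis low-pass).  Periodized
# convolution keeps the transform exactly orthonormal for any even signal
# length >= filter length, which gives exact Parseval energy balance and
# perfect reconstruction.
.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690)
)

wavelet_filter_pair <- function(wavelet) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h)) {
    rlang::abort(paste0("unknown wavelet '", wavelet, "'; available: ",
                        paste(names(.wavelet_filters), collapse = ", ")))
  }
  l <- length(h)
  g <- rev(h) * (-1)^(seq_len(l) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

#' Min-max normalize an image to \[0, 1\]
#'
#' Order-preserving affine map sending the image minimum to 0 and the
#' maximum to 1, removing brightness/contrast differences between
#' acquisitions. A constant image has no contrast to preserve; it maps
#' to all zeros with a warning.
#'
#' @param img numeric matrix of pixel intensities.
#' @return numeric matrix with range \[0, 1\].
#' @export
normalize_image <- function(img) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  rng <- range(img)
  if (rng[1] == rng[2]) {
    rlang::warn("constant image: normalizing to all zeros")
    return(img * 0)
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Standardize an image to zero mean and unit variance
#'
#' Per-image z-scoring (population standard deviation), balancing
#' brightness across image regions. Errors on zero-variance input.
#'
#' @param img numeric matrix.
#' @return numeric matrix with mean 0 and population standard deviation 1.
#' @export
standardize_image <- function(img) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  mu <- mean(img)
  sd_pop <- sqrt(mean((img - mu)^2))
  if (sd_pop == 0) rlang::abort("cannot standardize a constant image")
  (img - mu) / sd_pop
}

# One periodized analysis step along the rows of a matrix (treating each
# column as a signal): returns list(a, d), each (n/2) x ncol.
.dwt_step <- function(x, h, g) {
  n <- nrow(x)
  l <- length(h)
  if (n %% 2L != 0L) rlang::abort("signal length must be even for a DWT level")
  if (n < l) rlang::abort("image too small for the requested wavelet/level")
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(l)) {
    rows <- (base + (k - 1L)) %% n + 1L
    xk <- x[rows, , drop = FALSE]
    a <- a + h[k] * xk
    d <- d + g[k] * xk
  }
  list(a = a, d = d)
}

# Inverse of .dwt_step (transpose of the orthonormal analysis operator).
.idwt_step <- function(a, d, h, g) {
  half <- nrow(a)
  n <- 2L * half
  l <- length(h)
  x <- matrix(0, n, ncol(a))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_len(l)) {
    rows <- (base + (k - 1L)) %% n + 1L
    add <- h[k] * a + g[k] * d
    # rows can repeat across k only via different i, and for fixed k the
    # row indices are distinct, so plain indexed addition is safe here.
    x[rows, ] <- x[rows, , drop = FALSE] + add
  }
  x
}

#' Two-dimensional discrete wavelet transform
#'
#' Multi-level separable 2-D DWT with an orthonormal Daubechies filter
#' bank and periodic boundary extension, so that total coefficient
#' energy equals image energy (Parseval) and reconstruction via
#' [idwt2()] is exact to floating-point accuracy. Each level halves both
#' dimensions; both must be even (and at least the filter length) at
#' every level.
#'
#' @param img numeric matrix (grayscale intensities).
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`.
#' @param level number of decomposition levels `J >= 1`.
#' @return An object of class `wavelet_decomposition`: list with
#'   `wavelet`, `level`, `approx` (coarsest LL band) and `details`, a
#'   list of `level` lists each holding matrices `lh`, `hl`, `hh`
#'   (level 1 = finest scale).
#' @export
dwt2 <- function(img, wavelet = "db4", level = 2L) {
  stopifnot(is.matrix(img), level >= 1L)
  fl <- wavelet_filter_pair(wavelet)
  details <- vector("list", level)
  ll <- img
  for (j in seq_len(level)) {
    cols <- .dwt_step(ll, fl$h, fl$g)               # along rows (vertical)
    la <- .dwt_step(t(cols$a), fl$h, fl$g)          # along columns
    ld <- .dwt_step(t(cols$d), fl$h, fl$g)
    ll <- t(la$a)
    details[[j]] <- list(lh = t(la$d), hl = t(ld$a), hh = t(ld$d))
  }
  structure(list(wavelet = wavelet, level = level,
                 approx = ll, details = details),
            class = "wavelet_decomposition")
}

#' Inverse two-dimensional discrete wavelet transform
#'
#' Reconstructs the image from a [dwt2()] decomposition. Exact inverse
#' when the coefficients are untouched.
#'
#' @param dec a `wavelet_decomposition`.
#' @return numeric matrix of the original size.
#' @export
idwt2 <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  fl <- wavelet_filter_pair(dec$wavelet)
  ll <- dec$approx
  for (j in rev(seq_len(dec$level))) {
    dj <- dec$details[[j]]
    if (!all(dim(dj$hh) == dim(ll))) {
      rlang::abort("inconsistent band shapes in decomposition")
    }
    a_col <- t(.idwt_step(t(ll), t(dj$lh), fl$h, fl$g))
    d_col <- t(.idwt_step(t(dj$hl), t(dj$hh), fl$h, fl$g))
    ll <- .idwt_step(a_col, d_col, fl$h, fl$g)
  }
  ll
}

#' Hard-threshold the detail coefficients of a wavelet decomposition
#'
#' Detail coefficients with magnitude below `lambda` are zeroed; all
#' others pass unchanged. The coarsest approximation band is never
#' thresholded, so large-scale structure is preserved.
#'
#' @param dec a `wavelet_decomposition`.
#' @param lambda nonnegative threshold.
#' @param mode `"hard"` (default) keeps surviving coefficients
#'   unchanged; `"soft"` additionally shrinks them toward zero by
#'   `lambda`.
#' @return the thresholded `wavelet_decomposition`.
#' @export
hard_threshold <- function(dec, lambda, mode = c("hard", "soft")) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  mode <- match.arg(mode)
  if (lambda < 0) rlang::abort("lambda must be nonnegative")
  thr <- function(w) {
    if (mode == "hard") w * (abs(w) >= lambda)
    else sign(w) * pmax(abs(w) - lambda, 0)
  }
  dec$details <- lapply(dec$details, function(lvl) lapply(lvl, thr))
  dec
}

#' Donoho universal threshold from the finest diagonal band
#'
#' `lambda = sigma_hat * sqrt(2 log n)` with the noise scale estimated
#' robustly as `median(|HH1|) / 0.6745` and `n` the pixel count.
#'
#' @param dec a `wavelet_decomposition`.
#' @param n_pixels pixel count of the source image.
#' @return nonnegative scalar threshold.
#' @export
universal_threshold <- function(dec, n_pixels) {
  hh1 <- dec$details[[1]]$hh
  sigma <- stats::median(abs(hh1)) / 0.6745
  sigma * sqrt(2 * log(n_pixels))
}

#' Wavelet hard-threshold denoising of a thermal image
#'
#' Composition [dwt2()] -> [hard_threshold()] -> [idwt2()]. With
#' `threshold = "universal"` (default) the threshold is the Donoho
#' universal threshold with a robust MAD noise estimate; with
#' `threshold = "fixed"` the supplied `lambda` is used as-is.
#'
#' @param img numeric matrix.
#' @param wavelet wavelet name (default `"db4"`).
#' @param level decomposition depth (default 2).
#' @param threshold `"universal"` or `"fixed"`.
#' @param lambda threshold value when `threshold = "fixed"`.
#' @param mode `"hard"` or `"soft"` shrinkage.
#' @return denoised numeric matrix, same size as `img`.
#' @export
denoise_image <- function(img, wavelet = "db4", level = 2L,
                          threshold = c("universal", "fixed"), lambda = 0,
                          mode = c("hard", "soft")) {
  threshold <- match.arg(threshold)
  mode <- match.arg(mode)
  dec <- dwt2(img, wavelet, level)
  lam <- if (threshold == "universal") universal_threshold(dec, length(img)) else lambda
  idwt2(hard_threshold(dec, lam, mode))
}

#' Preprocess a thermal image for the model path
#'
#' The fixed preprocessing order: min-max normalize, per-image
#' standardize, wavelet hard-threshold denoise.
#'
#' @inheritParams denoise_image
#' @return preprocessed numeric matrix.
#' @export
preprocess_image <- function(img, wavelet = "db4", level = 2L,
                             threshold = "universal", lambda = 0) {
  denoise_image(standardize_image(normalize_image(img)),
                wavelet = wavelet, level = level,
                threshold = threshold, lambda = lambda)
}

#' Total squared-coefficient energy of a decomposition
#' @param dec a `wavelet_decomposition`.
#' @return scalar energy (sum of squared coefficients over all bands).
#' @export
decomposition_energy <- function(dec) {
  sum(dec$approx^2) +
    sum(vapply(dec$details,
               function(lvl) sum(lvl$lh^2) + sum(lvl$hl^2) + sum(lvl$hh^2),
               numeric(1)))
}

#' Resize an image by bilinear interpolation
#'
#' Used to bring thermal frames of arbitrary resolution to the
#' patch-divisible input size of the image encoder. Integer
#' downscaling factors use exact block averaging.
#'
#' @param img numeric matrix.
#' @param size integer vector `c(height, width)` of the output.
#' @return numeric matrix of dimension `size`.
#' @export
resize_image <- function(img, size) {
  stopifnot(is.matrix(img), length(size) == 2)
  h <- nrow(img); w <- ncol(img)
  ho <- size[1]; wo <- size[2]
  if (h == ho && w == wo) return(img)
  if (h %% ho == 0 && w %% wo == 0) {
    fh <- h %/% ho; fw <- w %/% wo
    grp_r <- rep(seq_len(ho), each = fh)
    grp_c <- rep(seq_len(wo), each = fw)
    return(t(rowsum(t(rowsum(img, grp_r)), grp_c)) / (fh * fw))
  }
  # bilinear, pixel centers aligned
  sy <- (seq_len(ho) - 0.5) * h / ho + 0.5
  sx <- (seq_len(wo) - 0.5) * w / wo + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(sy - y0, 0), 1)
  wx <- pmin(pmax(sx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx)) +
    img[y1, x0, drop = FALSE] * (wy %o% (1 - wx)) +
    img[y0, x1, drop = FALSE] * ((1 - wy) %o% wx) +
    img[y1, x1, drop = FALSE] * (wy %o% wx)
  a
}

#' Read an image file as a grayscale intensity matrix
#'
#' PNG is read natively; JPEG requires the `jpeg` package. Color images
#' are converted to a single luminance channel (Rec. 601 weights),
#' since the preprocessing operates on a scalar intensity field.
#'
#' @param path image file path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      rlang::abort("reading JPEG requires the 'jpeg' package")
    }
    jpeg::readJPEG(path)
  } else {
    rlang::abort(paste0("unsupported image format: ", ext))
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  arr
}

#' Write a grayscale matrix as a PNG image
#'
#' Values are clipped to \[0, 1\].
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
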