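#' @include AllClasses.R
NULL

frame_pixels <- function(x) if (is(x, "ImageFrame")) x@pixels else as.matrix(x)

#' Peak signal-to-noise ratio
#'
#' \eqn{\mathrm{MSE} = \frac{1}{MN}\sum (I - I')^2},
#' \eqn{\mathrm{PSNR} = 10 \log_{10}\left(\frac{(2^n-1)^2}{\mathrm{MSE}}\right)}
#' in dB. Identical images return `Inf`.
#'
#' @param image,reference [ImageFrame-class] objects (or matrices, with
#'   `bitDepth` supplied) of identical shape and bit depth
#' @param bitDepth bit depth when matrices are passed
#' @return PSNR in dB
#' @examples
#' a <- ImageFrame(matrix(0, 8, 8)); b <- ImageFrame(matrix(1, 8, 8))
#' psnr(a, b)  # 10*log10(255^2) ~ 48.13 dB
#' @export
psnr <- function(image, reference, bitDepth = NULL) {
  n <- metric_bit_depth(image, reference, bitDepth)
  a <- frame_pixels(image); b <- frame_pixels(reference)
  if (!all(dim(a) == dim(b))) stop("images must share the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10((2^n - 1)^2 / mse)
}

metric_bit_depth <- function(image, reference, bitDepth) {
  if (!is.null(bitDepth)) return(as.integer(bitDepth))
  if (is(image, "ImageFrame") && is(reference, "ImageFrame")) {
    if (image@bitDepth != reference@bitDepth)
      stop("bit depths differ between image and reference")
    return(image@bitDepth)
  }
  if (is(image, "ImageFrame")) return(image@bitDepth)
  if (is(reference, "ImageFrame")) return(reference@bitDepth)
  stop("supply 'bitDepth' when passing plain matrices")
}

#' Structural similarity index
#'
#' Single global SSIM from whole-image first and second moments:
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_I\mu_{I'} + c_1)(2\sigma_{II'} + c_2)}
#' {(\mu_I^2 + \mu_{I'}^2 + c_1)(\sigma_I^2 + \sigma_{I'}^2 + c_2)}}
#' with \eqn{c_1 = (k_1 (2^n - 1))^2}, \eqn{c_2 = (k_2 (2^n - 1))^2},
#' \eqn{k_1 = 0.01}, \eqn{k_2 = 0.03} by default, and population
#' variances/covariance. The global form is the default; `window` switches to
#' the conventional sliding-window mean-SSIM (uniform window, stride 1,
#' interior positions only) as a clearly separate extension.
#'
#' @param image,reference frames of identical shape and bit depth
#' @param k1,k2 stabilization constants (defaults 0.01 and 0.03)
#' @param bitDepth bit depth when matrices are passed
#' @param window `NULL` for the global statistic (default) or an odd window
#'   side for the windowed variant
#' @return SSIM in \eqn{[-1, 1]}; exactly 1 for identical images
#' @export
ssim <- function(image, reference, k1 = 0.01, k2 = 0.03, bitDepth = NULL,
                 window = NULL) {
  n <- metric_bit_depth(image, reference, bitDepth)
  a <- frame_pixels(image); b <- frame_pixels(reference)
  if (!all(dim(a) == dim(b))) stop("images must share the same shape")
  L <- 2^n - 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (is.null(window)) return(ssim_stat(a, b, c1, c2))
  w <- as.integer(window)
  if (w < 2L || w > min(dim(a))) stop("invalid ssim window")
  nr <- nrow(a) - w + 1L; nc <- ncol(a) - w + 1L
  # box-filtered local moments via cumulative sums
  boxsum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sum
    cs <- t(cs)
    padded <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    padded[-1, -1] <- cs
    padded[(w + 1):(nrow(m) + 1), (w + 1):(ncol(m) + 1)] -
      padded[1:nr, (w + 1):(ncol(m) + 1)] -
      padded[(w + 1):(nrow(m) + 1), 1:nc] + padded[1:nr, 1:nc]
  }
  np <- w * w
  sa <- boxsum(a) / np; sb <- boxsum(b) / np
  saa <- boxsum(a * a) / np; sbb <- boxsum(b * b) / np
  sab <- boxsum(a * b) / np
  va <- saa - sa^2; vb <- sbb - sb^2; cab <- sab - sa * sb
  mean(((2 * sa * sb + c1) * (2 * cab + c2)) /
         ((sa^2 + sb^2 + c1) * (va + vb + c2)))
}

ssim_stat <- function(a, b, c1, c2) {
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' Reference-free local signal-to-noise ratio
#'
#' Tiles the frame into non-overlapping `patchSize` x `patchSize` tiles
#' (partial border tiles are dropped), computes per-tile
#' \eqn{\mathrm{SNR} = \mu / \sigma} with the population standard deviation,
#' excludes tiles with \eqn{\sigma = 0}, and averages the rest. The 16 x 16
#' default matches the clinical evaluation protocol.
#'
#' @param frame an [ImageFrame-class] or matrix
#' @param patchSize tile side (>= 2; default 16)
#' @return a [LocalSNRResult-class]; `meanSnr` is `NaN` when every tile was
#'   excluded (e.g. a constant frame)
#' @examples
#' f <- generatePhantom(defaultPhantomSpec(size = c(64L, 64L)))
#' localSNR(f)
#' @export
localSNR <- function(frame, patchSize = 16L) {
  m <- frame_pixels(frame)
  patchSize <- as.integer(patchSize)
  if (patchSize < 2L) stop("'patchSize' must be at least 2")
  nr <- nrow(m) %/% patchSize
  nc <- ncol(m) %/% patchSize
  if (nr < 1L || nc < 1L) stop("frame smaller than a single tile")
  rows <- integer(0); cols <- integer(0)
  mus <- numeric(0); sds <- numeric(0)
  n_excl <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      tile <- m[((i - 1L) * patchSize + 1L):(i * patchSize),
                ((j - 1L) * patchSize + 1L):(j * patchSize)]
      mu <- mean(tile)
      sd_pop <- sqrt(mean((tile - mu)^2))
      if (sd_pop == 0) {
        n_excl <- n_excl + 1L
      } else {
        rows <- c(rows, i); cols <- c(cols, j)
        mus <- c(mus, mu); sds <- c(sds, sd_pop)
      }
    }
  }
  per <- data.frame(row = rows, col = cols, mu = mus, sigma = sds,
                    snr = if (length(mus)) mus / sds else numeric(0))
  new("LocalSNRResult", perPatch = per,
      meanSnr = if (nrow(per)) mean(per$snr) else NaN,
      nExcluded = n_excl, patchSize = patchSize)
}

#' Relative dose from two SNRs
#'
#' Under the quantum-noise assumption that SNR is proportional to the square
#' root of dose, the dose ratio implied by two SNR measurements is
#' \eqn{(\mathrm{SNR}_1 / \mathrm{SNR}_2)^2}.
#'
#' @param snrNum,snrDen the two (positive) SNRs
#' @return the implied dose ratio
#' @examples
#' relativeDose(24.5, 11.3)  # ~4.7: denoised frames look ~4.7x the dose
#' @export
relativeDose <- function(snrNum, snrDen) {
  if (snrNum <= 0 || snrDen <= 0) stop("SNRs must be positive")
  (snrNum / snrDen)^2
}
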