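#' @include AllClasses.R
NULL

# centered integer frequency indices for an axis of length n: 0, 1, ...,
# floor(n/2), -(ceiling(n/2)-1), ..., -1 reordered to match fft output
centered_freq_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

#' Nyquist frequency at the patient entrance plane
#'
#' The detector element spacing is demagnified to the entrance plane with the
#' standard geometric correction `detectorSpacingMm * sedMm / sidMm`; the
#' Nyquist frequency is `1 / (2 * effective spacing)` in cycles/mm. Clinical
#' fluoroscopy geometries give values near 1 cycle/mm.
#'
#' @param geometry a [GeometrySpec-class]
#' @return Nyquist frequency (cycles/mm)
#' @examples
#' nyquistCyclesPerMm(GeometrySpec(0.4, 1000, 800))  # 1.5625
#' @export
nyquistCyclesPerMm <- function(geometry) {
  stopifnot(is(geometry, "GeometrySpec"))
  validObject(geometry)
  eff <- geometry@detectorSpacingMm * geometry@sedMm / geometry@sidMm
  1 / (2 * eff)
}

effective_spacing <- function(frame, geometry) {
  if (!is.null(geometry)) {
    stopifnot(is(geometry, "GeometrySpec"))
    return(geometry@detectorSpacingMm * geometry@sedMm / geometry@sidMm)
  }
  if (is(frame, "ImageFrame")) {
    g <- frame@geometry
    if (!is.null(g)) return(g@detectorSpacingMm * g@sedMm / g@sidMm)
    if (length(frame@pixelSpacingMm)) return(frame@pixelSpacingMm)
  }
  NULL
}

#' Radially averaged spectral magnitude
#'
#' Computes the 2D DFT of the frame, centers it (DC at the origin), and
#' averages the magnitude |F(u,v)| over integer annuli
#' \eqn{r \le \sqrt{u^2 + v^2} < r + 1}: `sOfR[r]` is the mean magnitude and
#' `nOfR[r]` the number of frequency bins in annulus r, so
#' `sum(nOfR * sOfR) == sum(|F|)` over all covered bins. For non-square
#' frames the vertical index is rescaled by M/N so both axes reach Nyquist at
#' the same annulus. When an effective pixel spacing is known (explicit
#' `geometry`, the frame's attached geometry, or its plain pixel spacing at
#' magnification 1) the annuli are also expressed in cycles/mm.
#'
#' @param frame an [ImageFrame-class] or matrix, at least 8x8
#' @param geometry optional [GeometrySpec-class] overriding the frame's
#' @param power average |F|^2 instead of |F| (extension; the default follows
#'   the magnitude-averaging definition)
#' @param window "none" (default, the plain DFT) or "hann" for a separable
#'   Hann apodization when spectral leakage matters
#' @return a [SpectrumProfile-class]
#' @export
radialProfile <- function(frame, geometry = NULL, power = FALSE,
                          window = c("none", "hann")) {
  window <- match.arg(window)
  m <- frame_pixels(frame)
  if (nrow(m) < 8L || ncol(m) < 8L) stop("frame must be at least 8x8")
  N <- nrow(m)  # height (v axis)
  M <- ncol(m)  # width (u axis)
  if (window == "hann") {
    hr <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (0:(M - 1)) / (M - 1)))
    m <- m * outer(hr, hc)
  }
  mag <- Mod(stats::fft(m))
  if (power) mag <- mag^2
  iv <- centered_freq_index(N)
  iu <- centered_freq_index(M)
  # radial distance in width-referenced index units (both axes hit Nyquist
  # at the same physical frequency)
  d <- sqrt(outer((iv * M / N)^2, iu^2, `+`))
  r <- as.integer(floor(d))
  tot <- tapply(as.numeric(mag), r, sum)
  cnt <- tapply(rep(1L, length(r)), r, sum)
  radii <- as.integer(names(tot))
  o <- order(radii)
  radii <- radii[o]
  s <- as.numeric(tot[o] / cnt[o])
  n_of_r <- as.integer(cnt[o])
  eff <- effective_spacing(frame, geometry)
  if (is.null(eff)) {
    new("SpectrumProfile", radii = radii, sOfR = s, nOfR = n_of_r)
  } else {
    new("SpectrumProfile", radii = radii, sOfR = s, nOfR = n_of_r,
        cyclesPerMm = radii / (M * eff), nyquistCpmm = 1 / (2 * eff))
  }
}

#' Frequency transfer ratio between two spectra
#'
#' Per-annulus ratio `S_num(r) / S_den(r)` characterizing how a processing
#' step transfers each spatial frequency. Annuli where the denominator is
#' zero are marked `NA`. Use [averageTransferRatios()] to average per-image
#' ratio curves over an image set with a per-bin standard deviation.
#'
#' @param numerator,denominator [SpectrumProfile-class] objects on matching
#'   annulus grids (same frame size and geometry)
#' @return data.frame with columns `radius`, `cyclesPerMm` (NA-filled when
#'   unknown) and `ratio`
#' @export
transferRatio <- function(numerator, denominator) {
  stopifnot(is(numerator, "SpectrumProfile"), is(denominator, "SpectrumProfile"))
  if (length(numerator@radii) != length(denominator@radii) ||
      any(numerator@radii != denominator@radii))
    stop("spectra are on different annulus grids")
  if (length(numerator@nyquistCpmm) && length(denominator@nyquistCpmm) &&
      abs(numerator@nyquistCpmm - denominator@nyquistCpmm) > 1e-9)
    stop("spectra have different geometries")
  ratio <- ifelse(denominator@sOfR == 0, NA_real_,
                  numerator@sOfR / denominator@sOfR)
  data.frame(
    radius = numerator@radii,
    cyclesPerMm = if (length(numerator@cyclesPerMm)) numerator@cyclesPerMm
                  else NA_real_,
    ratio = ratio)
}

#' @rdname transferRatio
#' @param ratios list of data.frames from `transferRatio()` on identical
#'   grids (one per image pair)
#' @return `averageTransferRatios`: data.frame with per-bin `mean` and `sd`
#'   of the ratio across images
#' @export
averageTransferRatios <- function(ratios) {
  stopifnot(length(ratios) >= 1L)
  mat <- vapply(ratios, function(r) r$ratio, numeric(nrow(ratios[[1L]])))
  mat <- matrix(mat, nrow = nrow(ratios[[1L]]))
  data.frame(
    radius = ratios[[1L]]$radius,
    cyclesPerMm = ratios[[1L]]$cyclesPerMm,
    mean = rowMeans(mat, na.rm = TRUE),
    sd = apply(mat, 1, stats::sd, na.rm = TRUE))
}

#' Hard annular bandpass filter
#'
#' Zeroes every DFT coefficient whose radial frequency (cycles/mm at the
#' entrance plane) lies outside `[fLo, fHi]` (a brick-wall annular mask, as
#' used to probe which frequency band carries clinically useful content),
#' inverse-transforms and returns the real part. DC is retained only when
#' `fLo = 0`. The filter is idempotent.
#'
#' @param frame an [ImageFrame-class] or matrix
#' @param band a [Band-class] within `[0, Nyquist]`
#' @param geometry a [GeometrySpec-class] (or `NULL` to use the frame's own
#'   geometry/pixel spacing)
#' @return an [ImageFrame-class] (intensities left unclipped)
#' @export
bandpassFilter <- function(frame, band, geometry = NULL) {
  stopifnot(is(band, "Band"))
  m <- frame_pixels(frame)
  eff <- effective_spacing(frame, geometry)
  if (is.null(eff))
    stop("no geometry or pixel spacing available: cannot express the band in cycles/mm")
  nyq <- 1 / (2 * eff)
  if (band@fLo < 0 || band@fHi > nyq + 1e-12 || band@fLo >= band@fHi)
    stop("band must satisfy 0 <= fLo < fHi <= Nyquist (", signif(nyq, 4),
         " cycles/mm)")
  N <- nrow(m); M <- ncol(m)
  fv <- centered_freq_index(N) / (N * eff)
  fu <- centered_freq_index(M) / (M * eff)
  f <- sqrt(outer(fv^2, fu^2, `+`))
  # an upper limit at Nyquist means "no upper cut": the corner bins beyond
  # the axial Nyquist stay, so the full band [0, Nyquist] is an identity
  upper_open <- band@fHi >= nyq * (1 - 1e-12)
  keep <- f >= band@fLo & (upper_open | f <= band@fHi)
  if (band@fLo == 0) keep[1, 1] <- TRUE else keep[1, 1] <- FALSE
  Fm <- stats::fft(m)
  Fm[!keep] <- 0
  out <- Re(stats::fft(Fm, inverse = TRUE)) / length(m)
  bd <- if (is(frame, "ImageFrame")) frame@bitDepth else 8L
  ImageFrame(out, bitDepth = bd,
             pixelSpacingMm = if (is(frame, "ImageFrame"))
               frame@pixelSpacingMm else numeric(0),
             geometry = if (is(frame, "ImageFrame")) frame@geometry else NULL)
}

#' Overall and consensus bands from observer selections
#'
#' Given per-observer/image bandpass selections, the overall band spans the
#' minimum lower to the maximum upper frequency of the whole set; the
#' consensus band is the intersection (maximum lower to minimum upper), and
#' may be empty when selections are disjoint.
#'
#' @param selections list of `c(fLo, fHi)` pairs (or [Band-class] objects)
#' @return list with elements `overall` and `consensus` ([Band-class];
#'   check `isEmptyBand()` on the consensus)
#' @examples
#' bandConsensus(list(c(0.02, 0.39), c(0.10, 0.23)))
#' @export
bandConsensus <- function(selections) {
  if (length(selections) == 0L) stop("no selections supplied")
  los <- vapply(selections, function(s)
    if (is(s, "Band")) s@fLo else as.numeric(s[1]), numeric(1))
  his <- vapply(selections, function(s)
    if (is(s, "Band")) s@fHi else as.numeric(s[2]), numeric(1))
  if (any(los >= his)) stop("each selection must have fLo < fHi")
  list(overall = Band(min(los), max(his)),
       consensus = Band(max(los), min(his)))
}
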