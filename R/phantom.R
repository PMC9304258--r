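#' @include AllClasses.R
NULL

#' Render a synthetic fluoroscopy phantom
#'
#' Deterministically renders the content described by a [PhantomSpec-class]:
#' a smooth low-spatial-frequency background (constant base level, linear
#' gradient, broad Gaussian blobs), dark curvilinear device tracks
#' (catheter/wire-like: an interpolating spline through the control points,
#' splatted with a Gaussian cross-profile whose centerline dip equals the
#' configured contrast), and sharp step-edge bands. The same spec always
#' yields the same frame; randomness only enters via [generateDataset()].
#'
#' @param spec a [PhantomSpec-class]
#' @return an [ImageFrame-class] with intensities clipped to the spec's bit
#'   depth range
#' @examples
#' f <- generatePhantom(defaultPhantomSpec(size = c(128L, 128L)))
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  M <- spec@size[1]; N <- spec@size[2]   # width, height
  col <- matrix(rep(seq_len(M) - 1, each = N), N, M)
  row <- matrix(rep(seq_len(N) - 1, times = M), N, M)
  img <- spec@baseLevel + spec@gradient[1] * col + spec@gradient[2] * row

  for (b in spec@background) {
    img <- img + b$amplitude *
      exp(-((row - b$center[1])^2 + (col - b$center[2])^2) / (2 * b$radius^2))
  }
  for (d in spec@devices) {
    if (!is.matrix(d$points) || nrow(d$points) < 2L)
      stop("device curves need at least 2 control points")
    img <- img - render_device_dip(d, N, M)
  }
  for (e in spec@edges) {
    side <- (col - e$position[2]) * cos(e$orientation) +
      (row - e$position[1]) * sin(e$orientation)
    img <- img + e$height * (side > 0)
  }
  maxv <- 2^spec@bitDepth - 1
  img <- pmin(pmax(img, 0), maxv)
  ImageFrame(img, bitDepth = spec@bitDepth,
             pixelSpacingMm = spec@pixelSpacingMm)
}

# Gaussian cross-profile dip around a spline through the control points;
# dip at the centerline equals the contrast, and `width` is the FWHM of the
# cross-profile so the track reads as a catheter of that apparent width
render_device_dip <- function(d, N, M) {
  pts <- d$points
  width <- if (is.null(d$width)) 3 else d$width
  contrast <- if (is.null(d$contrast)) 40 else d$contrast
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (tt[length(tt)] == 0) stop("degenerate device curve (zero length)")
  nsamp <- max(16L, ceiling(2 * tt[length(tt)]))
  ts <- seq(0, tt[length(tt)], length.out = nsamp)
  ry <- stats::spline(tt, pts[, 1], xout = ts)$y
  rx <- stats::spline(tt, pts[, 2], xout = ts)$y
  sigma <- width / (2 * sqrt(2 * log(2)))
  reach <- 3.5 * sigma
  D <- nn_min_dist(N, M, cbind(ry, rx), reach)
  dip <- matrix(0, N, M)
  near <- is.finite(D)
  dip[near] <- contrast * exp(-D[near]^2 / (2 * sigma^2))
  dip
}

#' A representative phantom specification
#'
#' The stock content used throughout the package's tests and examples: three
#' broad anatomical blobs, two catheter-like curvilinear devices and two
#' step edges on a 512 x 512, 8-bit, 0.5 mm/pixel canvas (matching typical
#' clinical fluoroscopy frames).
#'
#' @param size `c(M, N)` in pixels
#' @param seed stored in the spec for downstream dataset randomization
#' @return a [PhantomSpec-class]
#' @export
defaultPhantomSpec <- function(size = c(512L, 512L), seed = 1L) {
  M <- size[1]; N <- size[2]
  s <- function(v) v / 512 * c(N, M)   # scale stock coordinates to the canvas
  PhantomSpec(
    size = as.integer(size), bitDepth = 8L, pixelSpacingMm = 0.5,
    baseLevel = 140, gradient = c(0.02, 0.01),
    background = list(
      list(center = s(c(180, 200)), radius = 0.18 * min(M, N), amplitude = -35),
      list(center = s(c(340, 320)), radius = 0.22 * min(M, N), amplitude = 25),
      list(center = s(c(120, 400)), radius = 0.12 * min(M, N), amplitude = -18)
    ),
    devices = list(
      list(points = cbind(c(60, 160, 280, 420, 480) / 512 * N,
                          c(40, 180, 240, 300, 460) / 512 * M),
           width = 3, contrast = 45),
      list(points = cbind(c(450, 360, 250, 120) / 512 * N,
                          c(80, 200, 380, 470) / 512 * M),
           width = 2, contrast = 30)
    ),
    edges = list(
      list(position = s(c(256, 120)), orientation = 0.3, height = 20),
      list(position = s(c(400, 380)), orientation = 2.0, height = -15)
    ),
    seed = as.integer(seed)
  )
}

#' Generate a randomized phantom dataset
#'
#' Draws `count` frames whose blob/device/edge placements are independently
#' randomized around the template's content (centers uniform over the canvas,
#' sizes and amplitudes jittered around the template values, device curves
#' re-drawn as smooth random tracks), reproducibly from `seed`.
#'
#' @param template a [PhantomSpec-class] whose content defines the ranges
#' @param count number of frames (>= 1)
#' @param seed integer seed
#' @return list of [ImageFrame-class] of length `count`
#' @export
generateDataset <- function(template, count, seed = template@seed) {
  stopifnot(is(template, "PhantomSpec"), count >= 1)
  specs <- randomPhantomSpecs(template, count, seed)
  lapply(specs, generatePhantom)
}

#' @rdname generateDataset
#' @details `randomPhantomSpecs()` returns the randomized specs themselves,
#'   for ground-truth-aware tests and manifests.
#' @export
randomPhantomSpecs <- function(template, count, seed = template@seed) {
  M <- template@size[1]; N <- template@size[2]
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  lapply(seq_len(count), function(i) {
    bg <- lapply(template@background, function(b) {
      list(center = c(stats::runif(1, 0, N - 1), stats::runif(1, 0, M - 1)),
           radius = b$radius * stats::runif(1, 0.7, 1.3),
           amplitude = b$amplitude * stats::runif(1, 0.7, 1.3))
    })
    dev <- lapply(template@devices, function(d) {
      list(points = random_track(N, M), width = d$width,
           contrast = d$contrast * stats::runif(1, 0.8, 1.2))
    })
    edg <- lapply(template@edges, function(e) {
      list(position = c(stats::runif(1, 0.2, 0.8) * N,
                        stats::runif(1, 0.2, 0.8) * M),
           orientation = stats::runif(1, 0, pi),
           height = e$height * stats::runif(1, 0.7, 1.3))
    })
    PhantomSpec(size = template@size, bitDepth = template@bitDepth,
                pixelSpacingMm = template@pixelSpacingMm,
                baseLevel = template@baseLevel, gradient = template@gradient,
                background = bg, devices = dev, edges = edg,
                seed = template@seed + i)
  })
}

# smooth random catheter-like track: a jittered walk across the canvas
random_track <- function(N, M) {
  k <- sample(4:6, 1)
  start <- c(stats::runif(1, 0.05, 0.95) * N, stats::runif(1, 0.02, 0.15) * M)
  heading <- stats::runif(1, -0.5, 0.5)
  pts <- matrix(NA_real_, k, 2)
  pts[1, ] <- start
  step <- (M * 0.85) / (k - 1)
  for (j in 2:k) {
    heading <- heading + stats::runif(1, -0.5, 0.5)
    pts[j, 1] <- min(max(pts[j - 1, 1] + step * sin(heading), 2), N - 3)
    pts[j, 2] <- min(max(pts[j - 1, 2] + step * cos(abs(heading) * 0.3), 2),
                     M - 3)
  }
  pts
}

# seed the RNG locally, preserving the caller's state
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
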