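test_that("PNG and TIFF round trips are lossless at the declared bit depth", {
  dir <- withr::local_tempdir()
  cases <- list(
    list(f = rand_frame(1, 32, 24, 8L), ext = "png"),
    list(f = rand_frame(2, 32, 24, 8L), ext = "tiff"),
    list(f = rand_frame(3, 17, 19, 16L), ext = "tiff"),
    # boundary values: one pixel at 2^n - 1 and one at 0
    list(f = ImageFrame(matrix(c(255, 0, 7, 128), 2, 2), bitDepth = 8L),
         ext = "png"),
    list(f = ImageFrame(matrix(c(65535, 0, 1, 40000), 2, 2), bitDepth = 16L),
         ext = "tiff"),
    # constant 16-bit frame
    list(f = ImageFrame(matrix(12345, 8, 8), bitDepth = 16L), ext = "tiff"))
  for (cs in cases) {
    p <- file.path(dir, paste0("f_", cs$ext, nrow(pixels(cs$f)), ".", cs$ext))
    writeFrame(cs$f, p)
    g <- readFrame(p)
    expect_identical(dim(g), dim(cs$f))
    expect_equal(bitDepth(g), bitDepth(cs$f))
    expect_equal(pixels(g), pixels(cs$f), ignore_attr = TRUE)
  }
})

test_that("out-of-range intensities are a write-time contract violation", {
  f <- ImageFrame(matrix(c(-1, 10, 20, 30), 2, 2), bitDepth = 8L)
  expect_error(writeFrame(f, tempfile(fileext = ".png")), "clip")
  g <- ImageFrame(matrix(300, 2, 2), bitDepth = 8L)
  expect_error(writeFrame(g, tempfile(fileext = ".png")), "clip")
  expect_equal(max(pixels(clipFrame(g))), 255)
  expect_equal(min(pixels(clipFrame(f))), 0)
})

test_that("unreadable files and unknown formats raise format errors", {
  p <- tempfile(fileext = ".png")
  writeLines("not a png", p)
  expect_error(readFrame(p), "unreadable")
  expect_error(readFrame(tempfile(fileext = ".png")), "not found")
  p2 <- tempfile(fileext = ".xyz")
  file.create(p2)
  expect_error(readFrame(p2), "extension")
})

test_that("synthetic DICOM round-trips pixels and geometry tags", {
  dir <- withr::local_tempdir()
  set.seed(42)
  m <- matrix(sample(0:4095, 24 * 20, replace = TRUE), 24, 20)
  p <- file.path(dir, "a.dcm")
  write_test_dicom(p, m, bits_stored = 12L, spacing = c(0.4, 0.4),
                   sid = 1000, sed = 800)
  f <- readFrame(p)
  expect_equal(pixels(f), m, ignore_attr = TRUE)
  expect_equal(bitDepth(f), 12L)
  g <- geometry(f)
  expect_s4_class(g, "GeometrySpec")
  expect_equal(g@detectorSpacingMm, 0.4)
  expect_equal(g@sidMm, 1000)
  expect_equal(g@sedMm, 800)
  # geometry extraction is a pure function of the header
  f2 <- readFrame(p)
  expect_equal(geometry(f2), g)
})

test_that("DICOM rescale slope/intercept are applied to pixel values", {
  p <- tempfile(fileext = ".dcm")
  m <- matrix(0:15, 4, 4)
  write_test_dicom(p, m, bits_stored = 16L, slope = 2, intercept = -10)
  f <- readFrame(p)
  expect_equal(pixels(f), m * 2 - 10, ignore_attr = TRUE)
})

test_that("DICOM without geometry tags warns and returns a frame without geometry", {
  p <- tempfile(fileext = ".dcm")
  m <- matrix(1:12, 3, 4)
  expect_warning(
    f <- readFrame(write_test_dicom(p, m, with_geometry = FALSE)),
    "geometry")
  expect_null(geometry(f))
  expect_equal(pixels(f), m, ignore_attr = TRUE)
})

test_that("multi-frame DICOM is read frame by frame", {
  p <- tempfile(fileext = ".dcm")
  m1 <- matrix(1:6, 2, 3); m2 <- matrix(7:12, 2, 3)
  write_test_dicom(p, list(m1, m2))
  expect_equal(pixels(readFrame(p, frame = 1L)), m1, ignore_attr = TRUE)
  expect_equal(pixels(readFrame(p, frame = 2L)), m2, ignore_attr = TRUE)
  expect_error(readFrame(p, frame = 3L), "out of range")
})

test_that("ImageFrame and GeometrySpec enforce their invariants", {
  expect_error(ImageFrame(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
  expect_error(GeometrySpec(0.4, 1000, 1200), "exceed")
  expect_error(GeometrySpec(-0.1, 1000, 800), "positive")
  f <- ImageFrame(matrix(0, 3, 4))
  expect_equal(dim(f), c(3L, 4L))
})
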