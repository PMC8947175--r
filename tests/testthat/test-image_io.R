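test_that("channel_stack enforces its invariants", {
  m <- matrix(1, 4, 4)
  expect_s3_class(channel_stack(m, m, m, 0.31), "channel_stack")
  expect_error(channel_stack(m, m, matrix(1, 4, 5), 0.31), "identical")
  expect_error(channel_stack(m, m, m, 0), "positive")
  expect_error(channel_stack(m, m, m, c(1, 2)), "positive")
  expect_error(channel_stack(-m, m, m, 0.31), "negative")
  bad <- m; bad[1] <- NA
  expect_error(channel_stack(bad, m, m, 0.31), "non-finite")
})

test_that("integer stacks survive write/read round trips bit-exactly", {
  set.seed(42)
  v <- matrix(as.numeric(sample(0:65535, 48 * 48, TRUE)), 48)
  s <- channel_stack(v, v[48:1, ], t(v), pixel_size_um = 0.25,
                     image_id = "rt16", dtype = "uint16")
  f <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(s, f)
  r <- read_stack(f)
  expect_identical(r$dsdna, s$dsdna)
  expect_identical(r$h2b, s$h2b)
  expect_identical(r$hsp60, s$hsp60)
  expect_equal(r$pixel_size_um, 0.25)
  expect_identical(r$image_id, "rt16")

  z <- channel_stack(matrix(0, 8, 8), matrix(0, 8, 8), matrix(0, 8, 8),
                     pixel_size_um = 0.5)
  fz <- withr::local_tempfile(fileext = ".tif")
  write_stack(z, fz)
  expect_equal(read_stack(fz)$dsdna, z$dsdna)
})

test_that("float stacks round trip to single precision", {
  set.seed(7)
  mk <- function() matrix(runif(16 * 16, 0, 300), 16)
  s <- channel_stack(mk(), mk(), mk(), pixel_size_um = 0.31)
  f <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(s, f)
  r <- read_stack(f)
  expect_lt(max(abs(r$dsdna - s$dsdna)) / max(s$dsdna), 1e-6)
})

test_that("pixel size is written as OME metadata and read back", {
  s <- channel_stack(matrix(1, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6),
                     pixel_size_um = 0.31)
  f <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(s, f)
  # independent route: pull PhysicalSizeX straight out of the
  # ImageDescription tag with a regex, no package parsing involved
  desc <- attr(tiff::readTIFF(f, all = TRUE, info = TRUE)[[1]],
               "description")
  got <- regmatches(desc, regexpr('PhysicalSizeX="[0-9.]+"', desc))
  expect_identical(got, 'PhysicalSizeX="0.31"')
  expect_equal(read_stack(f)$pixel_size_um, 0.31)
})

test_that("pixel size precedence is override > OME > resolution tags", {
  s <- channel_stack(matrix(1, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6),
                     pixel_size_um = 0.31)
  f <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(s, f)
  expect_equal(read_stack(f, channel_map(pixel_size_um = 0.5))$pixel_size_um,
               0.5)
  # resolution tags only (no OME description)
  m <- matrix(runif(36), 6)
  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(m, m, m), f2, bits.per.sample = 32,
                  compression = "none")
  ectopuncta:::tiff_patch_meta(f2, px_per_cm = 1e4 / 0.4)
  expect_equal(read_stack(f2)$pixel_size_um, 0.4, tolerance = 1e-6)
  # nothing at all is an error, never a silent default
  f3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(m, m, m), f3, bits.per.sample = 32)
  expect_error(read_stack(f3), "pixel size")
})

test_that("missing files and insufficient channels are errors", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "not found")
  m <- matrix(runif(36), 6)
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(m, m), f, bits.per.sample = 32)
  expect_error(read_stack(f, channel_map(pixel_size_um = 1)),
               "insufficient channels")
})

test_that("channel-role mapping is a pure permutation of the straight read", {
  set.seed(3)
  mk <- function() matrix(as.numeric(sample(0:255, 64, TRUE)), 8)
  s <- channel_stack(mk(), mk(), mk(), pixel_size_um = 0.31,
                     dtype = "uint8")
  f <- withr::local_tempfile(fileext = ".ome.tif")
  write_stack(s, f)
  straight <- read_stack(f)
  perm <- read_stack(f, channel_map(dsdna = 3, h2b = 1, hsp60 = 2))
  expect_identical(perm$dsdna, straight$hsp60)
  expect_identical(perm$h2b, straight$dsdna)
  expect_identical(perm$hsp60, straight$h2b)
  expect_error(channel_map(dsdna = 1, h2b = 1, hsp60 = 2), "distinct")
})

test_that("max projection collapses a z-stack pixelwise", {
  a <- matrix(1:9, 3); b <- matrix(9:1, 3)
  expect_equal(max_project(list(a, b)), pmax(a, b))
  expect_error(max_project(list()), "non-empty")
})

test_that("channel configuration is read from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("channels:", "  dsdna: 2", "  h2b: 3", "  hsp60: 1",
               "pixel_size_um: 0.42"), f)
  cm <- read_channel_config(f)
  expect_equal(cm$dsdna, 2L)
  expect_equal(cm$hsp60, 1L)
  expect_equal(cm$pixel_size_um, 0.42)
})
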