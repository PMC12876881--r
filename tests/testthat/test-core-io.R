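# core_io: containers, TIFF round trips, tables, calibration JSON, config.

test_that("Volume3D validity catches malformed inputs", {
  a <- array(runif(24), c(2, 3, 4))
  v <- Volume3D(a, c(2.52, 2.52, 2.52), "OCM", 3L)
  expect_s4_class(v, "Volume3D")
  expect_identical(dim(v), c(2L, 3L, 4L))
  expect_identical(voxels(v), a)
  expect_equal(voxelSpacing(v), c(2.52, 2.52, 2.52))
  expect_identical(modality(v), "OCM")
  expect_identical(acqDay(v), 3L)
  expect_error(Volume3D(matrix(1, 2, 2), c(1, 1, 1)), "3D array")
  expect_error(Volume3D(a, c(1, -1, 1)), "spacing")
  expect_error(Volume3D(a, c(1, 1, 1), modality = "XRAY"), "modality")
  b <- a
  b[1] <- NA
  expect_error(Volume3D(b, c(1, 1, 1)), "finite")
})

test_that("LabelMask validity and accessors", {
  lab <- array(0L, c(3, 3, 3))
  lab[1:2, 1:2, 1:2] <- 1L
  lab[3, 3, 3] <- 2L
  m <- LabelMask(lab, c(1, 1, 1), 5L)
  expect_identical(nLabels(m), 2L)
  expect_identical(labelData(m), lab)
  expect_identical(acqDay(m), 5L)
  expect_error(LabelMask(array(-1L, c(2, 2, 2)), c(1, 1, 1)),
               "non-negative")
})

test_that("show methods print without error", {
  v <- Volume3D(array(runif(8), c(2, 2, 2)), c(1, 1, 1))
  m <- LabelMask(array(1L, c(2, 2, 2)), c(1, 1, 1))
  cal <- FusionCalibration(c(1, 2, 3), c(1, 1.1, 1.1), 0.5)
  expect_output(show(v), "Volume3D")
  expect_output(show(m), "LabelMask")
  expect_output(show(cal), "FusionCalibration")
})

test_that("16-bit integer TIFF volumes round-trip exactly", {
  set.seed(4)
  a <- array(sample(0:65535, 2 * 5 * 6, replace = TRUE), c(2, 5, 6))
  v <- Volume3D(a + 0, c(0.84, 0.84, 0.84), "PAM", 2L)
  path <- tempfile(fileext = ".tif")
  writeVolume(v, path)
  back <- readVolume(path, c(0.84, 0.84, 0.84), "PAM", 2L)
  expect_identical(voxels(back), voxels(v))
  expect_identical(modality(back), "PAM")
  unlink(path)
})

test_that("32-bit TIFF volumes round-trip within the quantization step", {
  set.seed(5)
  a <- array(runif(60), c(3, 4, 5))
  v <- Volume3D(a, c(1, 1, 1))
  path <- tempfile(fileext = ".tif")
  writeVolume(v, path)
  back <- readVolume(path, c(1, 1, 1))
  # 32-bit storage quantizes [0, 1] intensities at 1/(2^32 - 1)
  expect_lt(max(abs(voxels(back) - voxels(v))), 2^-31)
  # out-of-range data must be rescaled by the caller
  expect_error(writeVolume(Volume3D(array(1.5, c(1, 2, 2)), c(1, 1, 1)),
                           path, bits = 32L),
               "rescale")
  unlink(path)
})

test_that("LabelMask round-trips through integer TIFF", {
  lab <- array(0L, c(2, 4, 4))
  lab[1, 1:2, 1:2] <- 1L
  lab[2, 3:4, 3:4] <- 7L
  m <- LabelMask(lab, c(1, 1, 1), 3L)
  path <- tempfile(fileext = ".tif")
  writeVolume(m, path)
  back <- readVolume(path, c(1, 1, 1))
  expect_identical(array(as.integer(voxels(back)), dim(lab)), lab)
  unlink(path)
})

test_that("readVolume / writeVolume reject malformed inputs", {
  expect_error(readVolume(tempfile(), c(1, 1, 1)), "not found")
  expect_error(Volume3D(array(c(1, NA, rep(1, 6)), c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(Volume3D(array(NaN, c(1, 1, 1)), c(1, 1, 1)), "finite")
  big <- Volume3D(array(70000, c(1, 2, 2)), c(1, 1, 1))
  expect_error(writeVolume(big, tempfile(fileext = ".tif"), bits = 16L),
               "16-bit range")
})

test_that("writeTable writes data.frames and uniform record lists", {
  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  path <- tempfile(fileext = ".csv")
  writeTable(df, path)
  back <- read.csv(path)
  expect_equal(back$a, df$a)
  expect_equal(back$b, df$b)
  recs <- list(list(a = 1, b = "x"), list(a = 2, b = "y"))
  writeTable(recs, path)
  expect_equal(nrow(read.csv(path)), 2L)
  bad <- list(list(a = 1), list(b = 2))
  expect_error(writeTable(bad, path), "heterogeneous")
  expect_error(writeTable(list(), path), "empty record list")
  unlink(path)
})

test_that("calibration JSON round-trips", {
  cal <- FusionCalibration(c(2.986, 5.884, -4.088), c(1, 1.041, 1.041),
                           0.274)
  path <- tempfile(fileext = ".json")
  writeCalibration(cal, path)
  back <- readCalibration(path)
  expect_equal(back@offset, cal@offset)
  expect_equal(back@scale, cal@scale)
  expect_equal(back@residual, cal@residual)
  unlink(path)
})

test_that("config defaults validate and YAML overrides merge", {
  cfg <- defaultConfig()
  expect_silent(validateConfig(cfg))
  path <- tempfile(fileext = ".yaml")
  writeConfig(list(tracking = list(tau = 0.6),
                   growth = list(f_regrow = 20)), path)
  merged <- readConfig(path)
  expect_equal(merged$tracking$tau, 0.6)
  expect_equal(merged$growth$f_regrow, 20)
  # untouched values fall back to the defaults
  expect_equal(merged$tracking$sigma_d_um, cfg$tracking$sigma_d_um)
  expect_equal(merged$classify$k, cfg$classify$k)
  unlink(path)
})

test_that("validateConfig rejects out-of-range parameters", {
  bad <- defaultConfig()
  bad$tracking$weights <- c(spatial = 0.5, volume = 0.3, bbox = 0.3)
  expect_error(validateConfig(bad), "sum to 1")
  bad <- defaultConfig()
  bad$fusion$threshold_fraction <- 1.2
  expect_error(validateConfig(bad), "threshold_fraction")
  bad <- defaultConfig()
  bad$growth$f_plateau <- 0.9
  expect_error(validateConfig(bad), "f_plateau")
})
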