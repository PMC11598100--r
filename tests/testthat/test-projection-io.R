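test_that("float32 projection stacks round-trip bit-exactly", {
  dir <- withr::local_tempdir()
  fr <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  # quantize to float32 once: that is the on-disk precision
  fr <- array(readBin(writeBin(as.vector(fr), raw(), size = 4),
                      "numeric", length(fr), size = 4), dim(fr))
  st <- ProjectionStack(fr, pixelPitch = 0.05, domain = "line_integral")
  path <- file.path(dir, "stack.tif")
  writeProjectionStack(st, path)
  geom <- ScanGeometry(6, 5, "parallel")
  back <- readProjectionStack(path, geom, pixelPitch = 0.05,
                              domain = "line_integral")
  expect_identical(frames(back), fr)
})

test_that("16-bit raw counts are read without rescaling", {
  dir <- withr::local_tempdir()
  fr <- array(c(0, 500, 30000, 65535, 123, 42), c(1, 2, 3))
  st <- ProjectionStack(fr, pixelPitch = 1, domain = "raw_counts")
  path <- file.path(dir, "counts.tif")
  writeProjectionStack(st, path)
  back <- readProjectionStack(path, ScanGeometry(2, 3, "parallel"))
  expect_equal(max(frames(back)), 65535)
  expect_equal(sort(as.vector(frames(back))), sort(as.vector(fr)))
})

test_that("directories of per-angle TIFFs load in lexicographic order with uniform angles", {
  dir <- withr::local_tempdir()
  for (i in 1:4) {
    m <- matrix(i / 10, 8, 8)
    tiff::writeTIFF(m, file.path(dir, sprintf("proj_%03d.tif", i - 1)),
                    bits.per.sample = 16L, compression = "none")
  }
  geom <- ScanGeometry(8, 8, "parallel", rotationRange = 180)
  st <- readProjectionStack(dir, geom)
  expect_equal(angles(st), c(0, 45, 90, 135))
  # frame order follows file names, not creation order
  expect_true(all(diff(frames(st)[, 1, 1]) > 0))
})

test_that("inconsistent frame shapes fail naming the offending file", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.1, 4, 4), file.path(dir, "a.tif"))
  tiff::writeTIFF(matrix(0.1, 5, 4), file.path(dir, "b.tif"))
  expect_error(readProjectionStack(dir, ScanGeometry(4, 4, "parallel")),
               "b\\.tif")
})

test_that("missing angle information is a hard error", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.1, 4, 4), file.path(dir, "a.tif"))
  expect_error(readProjectionStack(dir), "angle")
})

test_that("angle sidecar overrides the uniform grid", {
  dir <- withr::local_tempdir()
  for (i in 1:3)
    tiff::writeTIFF(matrix(0.1, 4, 4), file.path(dir, sprintf("p%d.tif", i)))
  writeLines(c("0", "10", "25"), file.path(dir, "angles.txt"))
  st <- readProjectionStack(dir, ScanGeometry(4, 4, "parallel"))
  expect_equal(angles(st), c(0, 10, 25))
})

test_that("volumes round-trip with their voxel-size sidecar", {
  dir <- withr::local_tempdir()
  v <- array(as.numeric(1:64), c(4, 4, 4))  # ramp volume
  vol <- CTVolume(v, voxelSize = 0.05)
  path <- file.path(dir, "vol.tif")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_identical(voxels(back), v)
  expect_equal(voxelSize(back), 0.05)
})

test_that("non-finite voxels cannot be written", {
  v <- array(1, c(2, 2, 2))
  v[1] <- NaN
  expect_error(writeVolume(CTVolume(v), tempfile(fileext = ".tif")),
               "non-finite")
})

test_that("scan geometry configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  g <- ScanGeometry(64, 64, "cone", sourceObjectDist = 50,
                    sourceDetectorDist = 100, rotationRange = 360)
  writeScanGeometry(g, path)
  back <- readScanGeometry(path)
  expect_equal(back@sourceObjectDist, 50)
  expect_equal(back@beamType, "cone")
})

test_that("cone geometry validity enforces distance ordering", {
  expect_error(ScanGeometry(4, 4, "cone", sourceObjectDist = 100,
                            sourceDetectorDist = 50),
               "sourceDetectorDist")
})

test_that("reader plug-ins extend readProjectionStack", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "stack.csv")
  write.csv(matrix(1:4, 2, 2), path, row.names = FALSE)
  registerStackReader("csv-test",
    predicate = function(p) grepl("\\.csv$", p),
    reader = function(p) list(as.matrix(read.csv(p))))
  st <- readProjectionStack(path, ScanGeometry(2, 2, "parallel"))
  expect_equal(dim(frames(st)), c(1L, 2L, 2L))
  rm("csv-test", envir = bstdmar:::.readers)
})
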