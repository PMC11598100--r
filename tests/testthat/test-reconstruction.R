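test_that("the windowed ramp filter kills DC and is linear", {
  const <- matrix(3.7, 4, 64)
  out <- filterRows(const, "hamming")
  expect_lt(max(abs(out)), 1e-10 * 3.7)

  set.seed(12)
  a <- matrix(rnorm(3 * 32), 3, 32)
  b <- matrix(rnorm(3 * 32), 3, 32)
  expect_equal(filterRows(a + b, "ram-lak"),
               filterRows(a, "ram-lak") + filterRows(b, "ram-lak"),
               tolerance = 1e-12)
})

test_that("the impulse response matches the inverse transform of the windowed ramp", {
  n <- 32
  np <- 256
  imp <- matrix(0, 1, n)
  imp[1, 10] <- 1
  for (kind in c("ram-lak", "hamming")) {
    got <- filterRows(imp, kind, padding = np)
    # direct evaluation: q[j] = (1/np) sum_k |nu_k| W(nu_k) e^{2 pi i k (j-10)/np}
    k <- 0:(np - 1)
    nu <- ifelse(k <= np / 2, k, k - np) / np
    W <- if (kind == "ram-lak") 1 else 0.54 + 0.46 * cos(pi * abs(nu) / 0.5)
    resp <- abs(nu) * W
    oracle <- vapply(seq_len(n), function(j) {
      Re(sum(resp * exp(2i * pi * k * (j - 10) / np))) / np
    }, numeric(1))
    expect_equal(got[1, ], oracle, tolerance = 1e-12)
  }
})

test_that("FBP recovers a uniform disk from its analytic sinogram", {
  n <- 256; pitch <- 0.1; radius <- 8; mu <- 0.05
  sino <- diskSinogram(360, n, pitch, radius, mu)
  slice <- fbp2d(sino, angles = uniformAngles(360), pitch = pitch,
                 kind = "hamming")
  xy <- (seq_len(n) - (n + 1) / 2) * pitch
  inner <- outer(xy^2, xy^2, "+") <= (radius - 0.5)^2
  expect_lt(abs(mean(slice[inner]) - mu) / mu, 0.03)
  expect_lt(sqrt(mean((slice[inner] - mu)^2)) / mu, 0.05)
  expect_identical(fbp2d(matrix(0, 360, n), angles = uniformAngles(360),
                         pitch = pitch),
                   matrix(0, n, n))
})

test_that("shifting the object shifts the reconstruction identically", {
  n <- 128; pitch <- 0.1; mu <- 0.04
  ang <- uniformAngles(240)
  img <- matrix(0, n, n)
  xy <- (seq_len(n) - (n + 1) / 2) * pitch
  r2c <- outer(xy^2, xy^2, "+")
  img[r2c <= 3^2] <- mu
  shift <- 10  # pixels, along +x (columns)
  img2 <- matrix(0, n, n)
  img2[, (1 + shift):n] <- img[, 1:(n - shift)]
  rec1 <- fbp2d(forwardProjectImage(img, ang, pitch), angles = ang,
                pitch = pitch)
  rec2 <- fbp2d(forwardProjectImage(img2, ang, pitch), angles = ang,
                pitch = pitch)
  interior <- 20:(n - 20)
  err <- rec2[interior, interior + shift] - rec1[interior, interior]
  expect_lt(mean(abs(err)) / mu, 0.02)
  expect_lt(max(abs(err)) / mu, 0.06)
})

test_that("angle span and count preconditions are enforced", {
  expect_error(fbp2d(matrix(1, 1, 8), angles = 0), "2 angles")
  expect_error(fbp2d(matrix(1, 8, 8), angles = seq(0, 80, length.out = 8)),
               "180")
})

test_that("FDK at quasi-parallel geometry matches 2D FBP of the central row", {
  n <- 64; px <- 0.1
  ph <- makePhantom(n, withMetal = FALSE, seed = 3, pixelSize = px)
  geom <- ScanGeometry(n, n, "cone", sourceObjectDist = 5000,
                       sourceDetectorDist = 10000)
  st <- polychromaticProject(ph, geom, monoSpectrum(40), i0 = 30000,
                             noise = "none", nAngles = 90)
  tst <- ProjectionStack(pmin(frames(st) / 30000, 1), angles = angles(st),
                         pixelPitch = pixelPitch(st),
                         domain = "transmittance")
  vol <- fdk(tst, geom, kind = "hamming")
  ctr <- (n + 1) %/% 2
  sino <- -log(pmax(frames(st)[, ctr, ] / 30000, 1e-6))
  ref <- fbp2d(sino, angles = angles(st), pitch = px, kind = "hamming")
  rmse <- sqrt(mean((voxels(vol)[, , ctr] - ref)^2)) / max(abs(ref))
  expect_lt(rmse, 0.01)
})

test_that("FDK of a zero stack is a zero volume and symmetry is preserved", {
  n <- 32
  geom <- ScanGeometry(n, n, "cone", sourceObjectDist = 60,
                       sourceDetectorDist = 120)
  zst <- ProjectionStack(array(0, c(45, n, n)),
                         angles = uniformAngles(45), pixelPitch = 0.2,
                         domain = "line_integral")
  expect_true(all(voxels(fdk(zst, geom)) == 0))

  # centred annular phantom: the reconstruction is invariant (within
  # interpolation tolerance) under 90-degree in-plane rotation
  lab <- matrix(0L, 64, 64)
  lab <- bstdmar:::.drawDisk(lab, 32.5, 32.5, 27, 1L)
  lab <- bstdmar:::.drawDisk(lab, 32.5, 32.5, 23, 0L)
  ann <- new("MaterialPhantom", labels = lab,
             materials = defaultMaterials(), pixelSize = 0.1)
  geom2 <- ScanGeometry(64, 64, "cone", sourceObjectDist = 200,
                        sourceDetectorDist = 400)
  # 80 angles: the 4.5-degree grid is invariant under 90-degree rotation,
  # so the symmetry check probes the reconstructor, not the angle sampling
  st <- polychromaticProject(ann, geom2, monoSpectrum(40), i0 = 30000,
                             noise = "none", nAngles = 80)
  tst <- ProjectionStack(pmin(frames(st) / 30000, 1), angles = angles(st),
                         pixelPitch = pixelPitch(st),
                         domain = "transmittance")
  v <- voxels(fdk(tst, geom2))
  ctr <- v[, , 32]
  rot <- t(ctr)[, ncol(ctr):1]  # 90-degree rotation
  expect_lt(max(abs(ctr - rot)) / max(abs(ctr)), 0.05)
})

test_that("forward projection matches analytic chords of a uniform disk", {
  n <- 128; pitch <- 0.1; radius <- 4; mu <- 0.03
  img <- matrix(0, n, n)
  xy <- (seq_len(n) - (n + 1) / 2) * pitch
  img[outer(xy^2, xy^2, "+") <= radius^2] <- mu
  fp <- forwardProjectImage(img, c(0, 45, 90), pitch)
  s <- (seq_len(n) - (n + 1) / 2) * pitch
  chord <- 2 * sqrt(pmax(radius^2 - s^2, 0)) * mu
  for (i in 1:3)
    expect_lt(max(abs(fp[i, ] - chord)) / max(chord), 0.02)
})
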