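test_that("paired phantoms differ only at metal-labelled pixels", {
  a <- makePhantom(128, withMetal = TRUE, seed = 4)
  b <- makePhantom(128, withMetal = FALSE, seed = 4)
  metal <- a@labels == 3L
  expect_gt(sum(metal), 0)
  expect_identical(a@labels[!metal], b@labels[!metal])
  expect_false(any(b@labels == 3L))
  # different seeds give different interior layouts
  c <- makePhantom(128, withMetal = TRUE, seed = 5)
  expect_false(identical(a@labels, c@labels))
})

test_that("Beer-Lambert null and slab closed forms are exact", {
  # all-air phantom: every detector pixel reads exactly i0
  air <- new("MaterialPhantom", labels = matrix(0L, 64, 64),
             materials = defaultMaterials(), pixelSize = 0.1)
  geom <- ScanGeometry(2, 64, "parallel")
  st <- polychromaticProject(air, geom, noise = "none", nAngles = 8,
                             i0 = 12345)
  expect_equal(unique(as.vector(frames(st))), 12345)

  # monochromatic uniform slab: I = i0 * exp(-mu * L) to 1e-9
  lab <- matrix(0L, 64, 64)
  lab[21:40, ] <- 1L  # 20-pixel slab crossing the field, axis-aligned
  slab <- new("MaterialPhantom", labels = lab,
              materials = defaultMaterials(), pixelSize = 0.1)
  E <- 40
  mu <- defaultMaterials()$a[1] * E^-3 + defaultMaterials()$b[1]
  stm <- polychromaticProject(slab, ScanGeometry(1, 64, "parallel"),
                              monoSpectrum(E), i0 = 30000, noise = "none",
                              nAngles = 4)
  # vertical rays (angle 0) cross the full 2 mm slab thickness
  expect_equal(frames(stm)[1, 1, 32], 30000 * exp(-mu * 2),
               tolerance = 1e-9)
})

test_that("polychromatic beams harden: effective attenuation falls with thickness", {
  spec <- xraySpectrum(c(25, 55), c(0.5, 0.5))
  mats <- defaultMaterials()
  thick <- seq(2, 20, by = 2)  # mm of plastic
  mu25 <- mats$a[1] * 25^-3 + mats$b[1]
  mu55 <- mats$a[1] * 55^-3 + mats$b[1]
  I <- 0.5 * exp(-mu25 * thick) + 0.5 * exp(-mu55 * thick)
  effMu <- -log(I) / thick
  expect_true(all(diff(effMu) < 0))

  # and the simulator agrees with the two-exponential mixture
  lab <- matrix(0L, 64, 64)
  lab[1:30, ] <- 1L
  slab <- new("MaterialPhantom", labels = lab, materials = mats,
              pixelSize = 0.1)
  st <- polychromaticProject(slab, ScanGeometry(1, 64, "parallel"), spec,
                             i0 = 1e5, noise = "none", nAngles = 1)
  want <- 1e5 * (0.5 * exp(-mu25 * 3) + 0.5 * exp(-mu55 * 3))
  expect_equal(frames(st)[1, 1, 32], want, tolerance = 1e-9)
})

test_that("Poisson noise is seeded and deterministic", {
  ph <- makePhantom(64, TRUE, seed = 2)
  geom <- ScanGeometry(2, 64, "parallel")
  a <- polychromaticProject(ph, geom, noise = "poisson", seed = 9,
                            nAngles = 12)
  b <- polychromaticProject(ph, geom, noise = "poisson", seed = 9,
                            nAngles = 12)
  c <- polychromaticProject(ph, geom, noise = "poisson", seed = 10,
                            nAngles = 12)
  expect_identical(frames(a), frames(b))
  expect_false(identical(frames(a), frames(c)))
})

test_that("paired stacks agree off-metal and metal only absorbs", {
  cfg <- modifyList(smallPairedConfig(), list(noise = "none"))
  ds <- pairedDataset(cfg, seed = 7)
  fw <- frames(ds$withMetal)
  fo <- frames(ds$withoutMetal)
  shadow <- metalShadow(ds$phantom, angles(ds$withMetal),
                        ndet = dim(fw)[3], minPath = 0)
  off <- !shadow
  for (r in seq_len(dim(fw)[2]))
    expect_equal(fw[, r, ][off], fo[, r, ][off])
  expect_true(all(fw <= fo + 1e-9))
})

test_that("metal shadow marks exactly the rays crossing the rod", {
  ph <- makePhantom(128, TRUE, seed = 1)
  ang <- uniformAngles(16)
  sh <- metalShadow(ph, ang, minPath = 0)
  # every angle sees the rod: shadow width is at least the rod diameter
  widths <- rowSums(sh)
  expect_true(all(widths >= 2 * 1.2 / ph@pixelSize - 2))
  shNone <- metalShadow(makePhantom(128, TRUE, seed = 1), ang,
                        minPath = 1e6)
  expect_equal(sum(shNone), 0)
})
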