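test_that("boundary extraction yields the exterior 8-connected ring", {
  f <- matrix(seq_len(25) / 25, 5, 5)
  m <- matrix(FALSE, 5, 5)
  m[3, 3] <- TRUE
  b <- extractBoundary(f, m)
  expect_equal(sum(b$chi), 8)
  expect_equal(b$rhat[b$boundary], f[b$boundary])
  expect_true(all(b$rhat[b$chi == 0] == 0))

  # 3x3 block in 7x7: enumerate 8-neighbours by brute force
  m2 <- matrix(FALSE, 7, 7)
  m2[3:5, 3:5] <- TRUE
  expected <- matrix(FALSE, 7, 7)
  for (i in 1:7) for (j in 1:7) {
    if (m2[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 7 && jj >= 1 && jj <= 7 && m2[ii, jj])
        expected[i, j] <- TRUE
    }
  }
  b2 <- extractBoundary(matrix(1, 7, 7), m2)
  expect_equal(sum(expected), 16)
  expect_identical(b2$boundary, expected)
})

test_that("degenerate masks are rejected", {
  f <- matrix(1, 5, 5)
  expect_error(extractBoundary(f, matrix(FALSE, 5, 5)), "empty")
  expect_error(extractBoundary(f, matrix(TRUE, 5, 5)), "whole image")
})

test_that("Shepard fill reproduces constant and symmetric cases exactly", {
  n <- 9
  m <- matrix(FALSE, n, n)
  m[4:6, 4:6] <- TRUE
  f <- matrix(7.5, n, n)
  expect_equal(shepardDirect(f, m), f)  # constant boundary -> constant fill

  # boundary values 0/10 on diametrically opposite ring pixels: the centre
  # pixel is equidistant from every such pair, so the weights cancel and
  # the fill is exactly 5
  f2 <- matrix(0, 5, 5)
  m2 <- matrix(FALSE, 5, 5)
  m2[3, 3] <- TRUE
  ring <- extractBoundary(f2, m2)$boundary
  idx <- which(ring, arr.ind = TRUE)
  f2[ring] <- ifelse(idx[, "col"] > 3 |
                       (idx[, "col"] == 3 & idx[, "row"] > 3), 10, 0)
  expect_equal(shepardDirect(f2, m2)[3, 3], 5)
})

test_that("Shepard fill matches an independent double-loop oracle", {
  set.seed(11)
  n <- 16
  f <- matrix(runif(n * n), n, n)
  m <- matrix(FALSE, n, n)
  m[6:11, 5:12] <- TRUE
  got <- shepardDirect(f, m)
  # brute-force reimplementation over all boundary/interior pairs
  b <- extractBoundary(f, m)
  bidx <- which(b$boundary, arr.ind = TRUE)
  oracle <- f
  for (idx in which(m)) {
    i <- (idx - 1) %% n + 1
    j <- (idx - 1) %/% n + 1
    num <- 0; den <- 0
    for (k in seq_len(nrow(bidx))) {
      d <- sqrt((bidx[k, 1] - i)^2 + (bidx[k, 2] - j)^2)
      w <- d^-3
      num <- num + w * f[bidx[k, 1], bidx[k, 2]]
      den <- den + w
    }
    oracle[i, j] <- num / den
  }
  expect_lt(max(abs(got - oracle)), 1e-12)
  # convex-combination bound
  rng <- range(f[b$boundary])
  expect_true(all(got[m] >= rng[1] & got[m] <= rng[2]))
})

test_that("Shepard fill is translation-equivariant", {
  set.seed(3)
  n <- 20
  f <- matrix(runif(n * n), n, n)
  m <- matrix(FALSE, n, n)
  m[5:9, 6:10] <- TRUE
  base <- shepardDirect(f, m)
  sh <- 4
  f2 <- matrix(0, n, n)
  f2[(1 + sh):n, (1 + sh):n] <- f[1:(n - sh), 1:(n - sh)]
  m2 <- matrix(FALSE, n, n)
  m2[(5 + sh):(9 + sh), (6 + sh):(10 + sh)] <- TRUE
  shifted <- shepardDirect(f2, m2)
  expect_equal(shifted[(5 + sh):(9 + sh), (6 + sh):(10 + sh)],
               base[5:9, 6:10], tolerance = 1e-12)
})

test_that("pyramid convolution is linear and null on zero input", {
  filt <- defaultPyramidFilters()
  expect_equal(convpyrConvolve(matrix(0, 32, 32), filt),
               matrix(0, 32, 32))
  set.seed(4)
  x <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(convpyrConvolve(5.25 * x, filt),
               5.25 * convpyrConvolve(x, filt), tolerance = 1e-12)
  y <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(convpyrConvolve(x + y, filt),
               convpyrConvolve(x, filt) + convpyrConvolve(y, filt),
               tolerance = 1e-10)
})

test_that("pyramid impulse response approximates the exact d^-3 kernel", {
  filt <- defaultPyramidFilters()
  x <- matrix(0, 64, 64)
  x[33, 33] <- 1
  out <- convpyrConvolve(x, filt)
  exact <- bstdmar:::radialKernelImage(64, 64, 33, 33, 3)
  z <- x == 0
  relL2 <- sqrt(sum((out[z] - exact[z])^2) / sum(exact[z]^2))
  expect_lt(relL2, 0.05)
})

test_that("membrane ratio tracks the Shepard oracle on random blob masks", {
  filt <- defaultPyramidFilters()
  set.seed(21)
  devs <- replicate(5, {
    f <- randomField(64)
    m <- randomBlobMask(64)
    direct <- shepardDirect(f, m)
    pyr <- membraneInterpolate(f, m, filt)
    b <- extractBoundary(f, m)
    mean(abs(pyr[m] - direct[m])) / diff(range(f[b$boundary]))
  })
  expect_lt(mean(devs), 0.02)
})

test_that("membrane fill is exact outside the mask and near-constant inside for constant boundaries", {
  filt <- defaultPyramidFilters()
  set.seed(9)
  f <- randomField(48)
  m <- randomBlobMask(48, nBlobs = 1)
  fc <- f
  b <- extractBoundary(f, m)
  fc[b$boundary] <- 0.4
  out <- membraneInterpolate(fc, m, filt)
  expect_identical(out[!m], fc[!m])           # outside-mask bit-exactness
  expect_lt(max(abs(out[m] - 0.4)) / 0.4, 1e-6)  # constant ratio cancels
})

test_that("disconnected mask blobs are filled from the global boundary within tolerance", {
  filt <- defaultPyramidFilters()
  set.seed(33)
  f <- randomField(64)
  m <- matrix(FALSE, 64, 64)
  m[10:18, 12:20] <- TRUE
  m[40:50, 38:50] <- TRUE
  direct <- shepardDirect(f, m)
  pyr <- membraneInterpolate(f, m, filt)
  b <- extractBoundary(f, m)
  dev <- mean(abs(pyr[m] - direct[m])) / diff(range(f[b$boundary]))
  expect_lt(dev, 0.02)
})

test_that("edge-touching masks are handled by padding", {
  filt <- defaultPyramidFilters()
  f <- matrix(runif(24 * 24), 24, 24)
  m <- matrix(FALSE, 24, 24)
  m[1:4, 10:14] <- TRUE  # touches the top edge
  out <- membraneInterpolate(f, m, filt)
  expect_true(all(is.finite(out)))
  expect_identical(out[!m], f[!m])
})

test_that("filter refitting is deterministic and sensitive to the seed", {
  a <- fitFilters(trainingSize = 32, nTrain = 2, sparsity = 12, seed = 5,
                  maxit = 8, tolerance = 1)
  b <- fitFilters(trainingSize = 32, nTrain = 2, sparsity = 12, seed = 5,
                  maxit = 8, tolerance = 1)
  expect_identical(a@h1, b@h1)
  expect_identical(a@h2, b@h2)
  expect_identical(a@g, b@g)
})
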