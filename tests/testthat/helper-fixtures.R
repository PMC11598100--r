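# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

# union of `nBlobs` random discs, kept away from the image edge
randomBlobMask <- function(n, nBlobs = 2, rmin = 4, rmax = 9) {
  m <- matrix(FALSE, n, n)
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  for (b in seq_len(nBlobs)) {
    r <- runif(1, rmin, rmax)
    ci <- runif(1, r + 3, n - r - 3)
    cj <- runif(1, r + 3, n - r - 3)
    m <- m | ((ii - ci)^2 + (jj - cj)^2 <= r^2)
  }
  m
}

# smooth-ish random image in [0, 1]
randomField <- function(n) {
  x <- matrix(runif(n * n), n, n)
  k <- c(1, 4, 6, 4, 1)
  sm <- bstdmar:::cpp_sepconv(x, k / sum(k))
  (sm - min(sm)) / (max(sm) - min(sm))
}

# analytic parallel-beam sinogram of a centred uniform disk
diskSinogram <- function(nAngles, nDet, pitch, radiusMM, mu) {
  s <- (seq_len(nDet) - (nDet + 1) / 2) * pitch
  chord <- 2 * sqrt(pmax(radiusMM^2 - s^2, 0))
  matrix(rep(chord * mu, each = nAngles), nAngles, nDet)
}

# small paired dataset shared by the end-to-end tests (computed once per
# test run)
smallPairedConfig <- function() {
  list(size = 128, nAngles = 180, detectorRows = 8, pixelSize = 0.2)
}
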