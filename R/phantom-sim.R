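# Polychromatic forward simulator: a structured phantom (plastic sleeve,
# brick-like inserts, a wooden strip) with an optional metal rod at a fixed
# position, projected with Beer-Lambert attenuation per spectral bin so
# that dense objects produce genuine beam-hardening streaks.

#' Material phantom on a pixel grid
#'
#' Integer material labels (0 = air) on a 2D slice grid plus the material
#' table.  Each material attenuates as
#' \eqn{\mu(E) = a E^{-3} + b} (mm^-1, E in keV): an inverse-cube
#' photoelectric term plus a flat Compton term, the minimal model that
#' reproduces beam hardening.
#'
#' @slot labels integer matrix of material ids (0 = air).
#' @slot materials data.frame with columns `id`, `name`, `a`, `b`.
#' @slot pixelSize pixel edge length in mm.
#' @exportClass MaterialPhantom
setClass("MaterialPhantom",
  representation(labels = "matrix", materials = "data.frame",
                 pixelSize = "numeric"))

setMethod("show", "MaterialPhantom", function(object) {
  cat("MaterialPhantom:", nrow(object@labels), "x", ncol(object@labels),
      "pixels of", object@pixelSize, "mm | materials:",
      paste(object@materials$name, collapse = ", "), "\n")
})

#' Default material table
#'
#' Attenuation models \eqn{\mu(E) = a E^{-3} + b} chosen so that
#' metal >> plastic > wood > air at micro-CT energies (20-60 keV):
#' plastic tracks water-like attenuation (~0.027 mm^-1 at 40 keV), wood is
#' about half as dense, and the metal is a titanium-alloy-like rod
#' (~4 mm^-1 at 20 keV, ~0.9 mm^-1 at 40 keV).  With the default
#' millimetre-scale rod this leaves its core nearly opaque at the soft end
#' of the spectrum while the partial-path fringe spans intermediate count
#' levels, the regime in which the mask threshold genuinely matters.
#'
#' @return data.frame with columns `id`, `name`, `a`, `b`.
#' @export
defaultMaterials <- function() {
  data.frame(id = 1:3,
             name = c("plastic", "wood", "metal"),
             a = c(490, 250, 2.9e4),
             b = c(0.019, 0.009, 0.42))
}

#' Polychromatic X-ray spectrum
#'
#' A discrete spectrum: keV bin centres and photon fractions summing to 1.
#' `defaultSpectrum()` is a 5-bin 20-60 keV tube-like spectrum peaked at
#' 40 keV; `monoSpectrum(E)` is a single bin (no beam hardening), used for
#' ground-truth reference simulations.
#'
#' @param energies keV bin centres.
#' @param weights photon fractions (non-negative; normalized to sum 1).
#' @return list with components `energies` and `weights`.
#' @export
xraySpectrum <- function(energies, weights) {
  stopifnot(length(energies) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  list(energies = as.numeric(energies),
       weights = as.numeric(weights) / sum(weights))
}

#' @rdname xraySpectrum
#' @export
defaultSpectrum <- function() {
  xraySpectrum(c(20, 30, 40, 50, 60), c(0.15, 0.25, 0.30, 0.20, 0.10))
}

#' @rdname xraySpectrum
#' @param E single energy in keV.
#' @export
monoSpectrum <- function(E = 40) xraySpectrum(E, 1)

# mu matrix: one row per material id, one column per energy bin
.muTable <- function(materials, energies) {
  outer(seq_len(nrow(materials)), seq_along(energies),
        function(i, j) materials$a[i] * energies[j]^-3 + materials$b[i])
}

.drawDisk <- function(labels, ci, cj, r, id) {
  n <- nrow(labels)
  ii <- matrix(seq_len(n), n, ncol(labels))
  jj <- matrix(seq_len(ncol(labels)), n, ncol(labels), byrow = TRUE)
  labels[(ii - ci)^2 + (jj - cj)^2 <= r^2] <- id
  labels
}

#' Build the structured test phantom
#'
#' A 2D slice phantom emulating a fixed-geometry paired acquisition: an
#' outer plastic sleeve (annulus), brick-like rectangular plastic inserts
#' whose layout depends on `seed`, a wooden strip, and - iff `withMetal` -
#' a metal rod (radius 1.2 mm) at a *fixed* position.  For a given seed
#' the with/without-metal pair differs only at metal-labelled pixels, so
#' the two simulated scans share the exact object geometry.
#'
#' @param size slice side length in pixels (>= 64).
#' @param withMetal include the metal rod?
#' @param seed layout seed (deterministic; R's default Mersenne-Twister
#'   stream, isolated from the caller's RNG state).
#' @param pixelSize pixel edge length in mm (default 0.1).
#' @return A [MaterialPhantom-class].
#' @export
makePhantom <- function(size = 256, withMetal = TRUE, seed = 1,
                        pixelSize = 0.1) {
  stopifnot(size >= 64)
  labels <- matrix(0L, size, size)
  c0 <- (size + 1) / 2
  rOut <- 0.43 * size
  rIn <- rOut - max(4, round(0.04 * size))
  labels <- .drawDisk(labels, c0, c0, rOut, 1L)
  labels <- .drawDisk(labels, c0, c0, rIn, 0L)
  withSeed(seed, {
    nBricks <- sample(4:6, 1)
    for (k in seq_len(nBricks)) {
      w <- sample(round(0.06 * size):round(0.14 * size), 1)
      h <- sample(round(0.06 * size):round(0.14 * size), 1)
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55 * rIn)
      ci <- round(c0 + rad * sin(ang))
      cj <- round(c0 + rad * cos(ang))
      ii <- max(1, ci - h):min(size, ci + h)
      jj <- max(1, cj - w):min(size, cj + w)
      labels[ii, jj] <- 1L
    }
    sr <- round(c0 + runif(1, -0.2, 0.2) * size)
    half <- max(2, round(0.015 * size))
    span <- round(0.27 * size)
    labels[(sr - half):(sr + half), (round(c0) - span):(round(c0) + span)] <- 2L
  })
  if (withMetal) {
    rodR <- 1.2 / pixelSize
    labels <- .drawDisk(labels, round(c0 + 0.05 * size),
                        round(c0 + 0.08 * size), rodR, 3L)
  }
  new("MaterialPhantom", labels = labels, materials = defaultMaterials(),
      pixelSize = pixelSize)
}

# per-material path lengths (mm) for a parallel-beam scan of a 2D phantom:
# array (n_angles, ndet, n_materials)
materialPathLengths <- function(phantom, angles, ndet = NULL) {
  if (is.null(ndet)) ndet <- ncol(phantom@labels)
  cpp_project_labels_par2d(phantom@labels, nrow(phantom@materials),
                           angles, as.integer(ndet), phantom@pixelSize,
                           phantom@pixelSize)
}

.spectralCounts <- function(lengths, materials, spec, i0) {
  mu <- .muTable(materials, spec$energies)
  dims <- dim(lengths)[1:2]
  acc <- matrix(0, dims[1L], dims[2L])
  nmat <- dim(lengths)[3L]
  for (e in seq_along(spec$energies)) {
    att <- matrix(0, dims[1L], dims[2L])
    for (m in seq_len(nmat)) att <- att + mu[m, e] * lengths[, , m]
    acc <- acc + spec$weights[e] * exp(-att)
  }
  i0 * acc
}

#' Polychromatic forward projection of a phantom
#'
#' Per detector bin, \eqn{I = I_0 \sum_E w(E) \exp(-\sum_m \mu_m(E)
#' \ell_m)}, with \eqn{\ell_m} the exact (Siddon-traced) intersection
#' length of the ray with material `m`.  A single-bin spectrum gives a
#' monochromatic (beam-hardening-free) scan.  With a parallel beam the 2D
#' slice phantom is treated as extruded along the rotation axis, so all
#' detector rows see the same slice; with a cone beam the phantom is
#' extruded into a 3D label volume occupying the central 75% of the axial
#' range and traced in 3D.
#'
#' @param phantom a [MaterialPhantom-class].
#' @param geometry a [ScanGeometry-class].
#' @param spec an [xraySpectrum()].
#' @param i0 unattenuated (flat-field) counts per detector pixel.
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed for the Poisson draw.
#' @param nAngles number of projections over the geometry's rotation range.
#' @return A raw-counts [ProjectionStack-class] (detector pitch: the
#'   phantom pixel size for parallel beam, magnified by SDD/SOD for cone
#'   beam).
#' @export
polychromaticProject <- function(phantom, geometry, spec = defaultSpectrum(),
                                 i0 = 30000, noise = c("none", "poisson"),
                                 seed = 1, nAngles = 360) {
  noise <- match.arg(noise)
  ang <- uniformAngles(nAngles, geometry@rotationRange)
  nv <- geometry@detectorRows
  nu <- geometry@detectorCols
  if (geometry@beamType == "parallel") {
    lengths <- materialPathLengths(phantom, ang, nu)
    I <- .spectralCounts(lengths, phantom@materials, spec, i0)
    fr <- array(0, c(nAngles, nv, nu))
    for (r in seq_len(nv)) fr[, r, ] <- I
    pitch <- phantom@pixelSize
  } else {
    nz <- nv
    lab3 <- extrudeLabels(phantom@labels, nz)
    pitch <- phantom@pixelSize * geometry@sourceDetectorDist /
      geometry@sourceObjectDist
    lengths <- cpp_project_labels_cone3d(
      as.integer(lab3), nrow(phantom@labels), ncol(phantom@labels), nz,
      nrow(phantom@materials), ang, as.integer(nu), as.integer(nv),
      phantom@pixelSize, geometry@sourceObjectDist,
      geometry@sourceDetectorDist, pitch)
    fr <- array(0, c(nAngles, nv, nu))
    for (i in seq_len(nAngles)) {
      li <- array(lengths[, , , i], dim(lengths)[1:3])
      fr[i, , ] <- .spectralCounts(li, phantom@materials, spec, i0)
    }
  }
  if (noise == "poisson") {
    fr <- withSeed(seed, array(rpois(length(fr), fr), dim(fr)))
  }
  ProjectionStack(fr, angles = ang, pixelPitch = pitch,
                  domain = "raw_counts", i0 = i0)
}

# extrude a 2D label slice into nz axial slices occupying the central
# `fill` fraction of the axial range (air above and below)
extrudeLabels <- function(labels, nz, fill = 0.75) {
  lab3 <- array(0L, c(dim(labels), nz))
  half <- floor(fill * nz / 2)
  mid <- (nz + 1) / 2
  zr <- max(1, ceiling(mid - half)):min(nz, floor(mid + half))
  for (z in zr) lab3[, , z] <- labels
  lab3
}

#' Detector-domain metal shadow of a phantom
#'
#' Logical `(n_angles x ndet)` matrix marking rays whose exact intersection
#' length with metal exceeds `minPath` (mm): the ground-truth footprint a
#' metal mask should cover.
#'
#' @param phantom a [MaterialPhantom-class] (with metal).
#' @param angles projection angles in degrees.
#' @param ndet number of detector bins.
#' @param minPath minimum metal path length in mm to count as shadow
#'   (default 0.3, three pixels: shorter grazing paths remove too little
#'   signal to be distinguishable from the soft-tissue background and are
#'   absorbed by the mask dilation instead).
#' @return logical matrix.
#' @export
metalShadow <- function(phantom, angles, ndet = NULL, minPath = 0.3) {
  metalId <- match("metal", phantom@materials$name)
  lengths <- materialPathLengths(phantom, angles, ndet)
  lengths[, , metalId] > minPath
}

#' Simulate a paired with/without-metal acquisition
#'
#' Emulates the fixed-geometry paired experiment: two polychromatic scans
#' of the same phantom layout, with and without the metal rod, sharing
#' geometry, angles, spectrum, flat-field level and noise seed; plus the
#' monochromatic (reference-energy) no-metal reconstruction of the central
#' slice as the artifact-free reference image.
#'
#' @param config list overriding any of the defaults: `size` (256),
#'   `nAngles` (360), `detectorRows` (32), `pixelSize` (0.1 mm), `i0`
#'   (30000), `noise` (`"poisson"`), `spec` ([defaultSpectrum()]),
#'   `referenceEnergy` (40 keV), `filter` (`"hamming"`).
#' @param seed seed controlling the phantom layout and the noise draw.
#' @return list with `withMetal` and `withoutMetal`
#'   ([ProjectionStack-class]s), `reference` (a [CTVolume-class] slice),
#'   `phantom` (the with-metal [MaterialPhantom-class]), `geometry` and
#'   the resolved `config`.
#' @export
pairedDataset <- function(config = list(), seed = 1) {
  cfg <- modifyList(list(size = 256, nAngles = 360, detectorRows = 32,
                         pixelSize = 0.1, i0 = 30000, noise = "poisson",
                         spec = defaultSpectrum(), referenceEnergy = 40,
                         filter = "hamming"), config)
  geom <- ScanGeometry(detectorRows = cfg$detectorRows,
                       detectorCols = cfg$size, beamType = "parallel")
  phWith <- makePhantom(cfg$size, withMetal = TRUE, seed = seed,
                        pixelSize = cfg$pixelSize)
  phWithout <- makePhantom(cfg$size, withMetal = FALSE, seed = seed,
                           pixelSize = cfg$pixelSize)
  stackWith <- polychromaticProject(phWith, geom, cfg$spec, cfg$i0,
                                    noise = cfg$noise, seed = seed,
                                    nAngles = cfg$nAngles)
  stackWithout <- polychromaticProject(phWithout, geom, cfg$spec, cfg$i0,
                                       noise = cfg$noise, seed = seed,
                                       nAngles = cfg$nAngles)
  # the reference emulates an artifact-free *acquired* scan, so it carries
  # the same noise model as the paired acquisitions
  refStack <- polychromaticProject(phWithout, geom,
                                   monoSpectrum(cfg$referenceEnergy),
                                   cfg$i0, noise = cfg$noise, seed = seed,
                                   nAngles = cfg$nAngles)
  refSino <- frames(refStack)[, 1L, ] / cfg$i0
  refSlice <- fbp2d(-log(pmax(refSino, 1e-6)), angles = angles(refStack),
                    pitch = cfg$pixelSize, kind = cfg$filter)
  list(withMetal = stackWith, withoutMetal = stackWithout,
       reference = CTVolume(refSlice, voxelSize = cfg$pixelSize),
       phantom = phWith, geometry = geom, config = cfg)
}
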