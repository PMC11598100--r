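#' @import methods
#' @importFrom stats approx fft median optim quantile rnorm rpois runif sd
#'   setNames coef lm
#' @importFrom utils packageVersion modifyList head tail
#' @useDynLib bstdmar, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.stack_domains <- c("raw_counts", "transmittance", "line_integral")

#' Ordered stack of 2D detector projections
#'
#' Holds the raw acquisition projections \eqn{f_i(x,y)}: one 2D detector
#' frame per rotation angle, plus the angular positions and the detector
#' pixel pitch.  Frames are stored as a 3D array indexed
#' `(angle, detector row, detector column)` with row 1 at the top of the
#' detector and column 1 at the left.  The `domain` flag records whether
#' values are raw detector counts, flat-field-normalized transmittance in
#' \[0, 1\], or attenuation line integrals (\eqn{-\log} transmittance).
#'
#' @slot frames 3D numeric array, `n_angles x detector_rows x detector_cols`.
#' @slot angles numeric vector of projection angles in degrees,
#'   counter-clockwise positive, strictly increasing, one per frame.
#' @slot pixelPitch detector pixel pitch in mm.
#' @slot domain one of `"raw_counts"`, `"transmittance"`, `"line_integral"`.
#' @slot i0 flat-field (unattenuated) count level, or `NA` when unknown.
#'
#' @seealso [ProjectionStack()], [readProjectionStack()]
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(frames = "array", angles = "numeric",
                 pixelPitch = "numeric", domain = "character",
                 i0 = "numeric"))

setValidity("ProjectionStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3D array (angles x rows x cols)")
  else if (d[1L] != length(object@angles))
    msg <- c(msg, "number of frames must equal number of angles")
  if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (!object@domain %in% .stack_domains)
    msg <- c(msg, paste("domain must be one of:",
                        paste(.stack_domains, collapse = ", ")))
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  v <- object@frames
  if (object@domain == "raw_counts" && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "raw_counts frames must be non-negative")
  if (object@domain == "transmittance" &&
      (any(v < -1e-6, na.rm = TRUE) || any(v > 1 + 1e-6, na.rm = TRUE)))
    msg <- c(msg, "transmittance frames must lie in [0, 1] (tol 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Construct a ProjectionStack
#'
#' @param frames 3D array `(n_angles, rows, cols)`, or a list of equally
#'   sized matrices (one per angle).
#' @param angles projection angles in degrees; defaults to uniform,
#'   endpoint-exclusive spacing over `rotationRange` (so `n` frames over
#'   360 degrees sit at `0, 360/n, ..., 360*(n-1)/n`).
#' @param pixelPitch detector pixel pitch in mm.
#' @param domain value domain of the frames (see class description).
#' @param i0 flat-field count level if known.
#' @param rotationRange total angular range in degrees used when `angles`
#'   is missing.
#' @return A [ProjectionStack-class] object.
#' @export
ProjectionStack <- function(frames, angles = NULL, pixelPitch = 1,
                            domain = c("raw_counts", "transmittance",
                                       "line_integral"),
                            i0 = NA_real_, rotationRange = 360) {
  domain <- match.arg(domain)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share one shape")
    arr <- array(0, c(length(frames), dims[[1L]][1L], dims[[1L]][2L]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (is.null(angles))
    angles <- uniformAngles(dim(frames)[1L], rotationRange)
  new("ProjectionStack", frames = frames, angles = as.numeric(angles),
      pixelPitch = pixelPitch, domain = domain, i0 = as.numeric(i0))
}

#' Uniform endpoint-exclusive angle grid
#'
#' `n` angles covering `range` degrees starting at 0:
#' `0, range/n, ..., range*(n-1)/n`.
#'
#' @param n number of projections.
#' @param range total angular range in degrees (360 for a full scan).
#' @return numeric vector of length `n`.
#' @export
uniformAngles <- function(n, range = 360) range * (seq_len(n) - 1) / n

#' Acquisition geometry of a tomographic scan
#'
#' @slot sourceObjectDist source-to-rotation-axis distance in mm
#'   (`NA` for parallel beam).
#' @slot sourceDetectorDist source-to-detector distance in mm
#'   (`NA` for parallel beam).
#' @slot detectorRows,detectorCols detector dimensions in pixels.
#' @slot beamType `"parallel"` or `"cone"`.
#' @slot rotationRange total scan range in degrees.
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(sourceObjectDist = "numeric", sourceDetectorDist = "numeric",
                 detectorRows = "integer", detectorCols = "integer",
                 beamType = "character", rotationRange = "numeric"))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (!object@beamType %in% c("parallel", "cone"))
    msg <- c(msg, "beamType must be 'parallel' or 'cone'")
  if (object@beamType == "cone") {
    if (!isTRUE(object@sourceDetectorDist > object@sourceObjectDist) ||
        !isTRUE(object@sourceObjectDist > 0))
      msg <- c(msg, "cone beam requires sourceDetectorDist > sourceObjectDist > 0")
  }
  if (object@detectorRows < 1L || object@detectorCols < 1L)
    msg <- c(msg, "detector dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanGeometry
#'
#' @param detectorRows,detectorCols detector dimensions in pixels.
#' @param beamType `"parallel"` or `"cone"`.
#' @param sourceObjectDist,sourceDetectorDist distances in mm (cone beam).
#' @param rotationRange total scan range in degrees.
#' @return A [ScanGeometry-class] object.
#' @export
ScanGeometry <- function(detectorRows, detectorCols,
                         beamType = c("parallel", "cone"),
                         sourceObjectDist = NA_real_,
                         sourceDetectorDist = NA_real_,
                         rotationRange = 360) {
  new("ScanGeometry", sourceObjectDist = sourceObjectDist,
      sourceDetectorDist = sourceDetectorDist,
      detectorRows = as.integer(detectorRows),
      detectorCols = as.integer(detectorCols),
      beamType = match.arg(beamType), rotationRange = rotationRange)
}

#' Reconstructed scalar volume
#'
#' A 3D voxel grid centred on the rotation axis; a single reconstructed
#' slice is stored with third dimension 1.
#'
#' @slot voxels 3D numeric array.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", voxelSize = "numeric"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array (use dim = c(n, n, 1) for a slice)")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D array, or a matrix (stored as a single slice).
#' @param voxelSize voxel edge length in mm.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, voxelSize = 1) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  new("CTVolume", voxels = voxels, voxelSize = voxelSize)
}

#' Fitted convolution-pyramid kernel triple
#'
#' Small separable kernels driving the multiscale analysis/synthesis scheme
#' that approximates convolution with the large-support inverse-distance
#' weight kernel \eqn{w(d) = d^{-p}} in linear time: `h1` filters before
#' each downsampling (analysis), `h2` after each upsampling (synthesis) and
#' `g` injects the stored analysis signal at every level.
#'
#' @slot h1 odd-length symmetric analysis kernel (applied separably).
#' @slot h2 odd-length symmetric synthesis kernel.
#' @slot g odd-length symmetric per-level kernel.
#' @slot weightExponent exponent `p` of the target weight kernel.
#' @seealso [fitFilters()], [defaultPyramidFilters()], [convpyrConvolve()]
#' @exportClass PyramidFilters
setClass("PyramidFilters",
  representation(h1 = "numeric", h2 = "numeric", g = "numeric",
                 weightExponent = "numeric"))

setValidity("PyramidFilters", function(object) {
  msg <- character()
  for (nm in c("h1", "h2", "g")) {
    k <- slot(object, nm)
    if (length(k) %% 2L == 0L || !all(is.finite(k)))
      msg <- c(msg, paste(nm, "must be finite and of odd length"))
    else if (max(abs(k - rev(k))) > 1e-12)
      msg <- c(msg, paste(nm, "must be symmetric about its centre"))
  }
  if (object@weightExponent <= 0)
    msg <- c(msg, "weightExponent must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-projection metal mask
#'
#' Binary detector-domain mask of high-density (low-count) pixels for one
#' projection, as produced by [computeMask()].
#'
#' @slot pixels logical matrix, same shape as the projection frame.
#' @slot threshold raw-count threshold used.
#' @slot dilationRadius dilation disc radius in pixels.
#' @exportClass MetalMask
setClass("MetalMask",
  representation(pixels = "matrix", threshold = "numeric",
                 dilationRadius = "numeric"))

setValidity("MetalMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  TRUE
})

#' Soft/hard decomposition of one projection
#'
#' Result of [decompose()]: soft-tissue transmittance image `S` (the
#' original frame outside the mask, the membrane fill inside) and the
#' hard-tissue image `U` linked to the frame by `f = U * (1 - S) + S`.
#' In the transmittance domain a dense object only removes signal, so `U`
#' is non-positive under the mask and exactly 0 outside it; the
#' bright-metal display/reconstruction image is the hard-tissue
#' transmittance [hardTransmittance()].
#'
#' @slot S soft-tissue transmittance image in \[0, 1\].
#' @slot U signed hard-tissue image, 0 outside the mask.
#' @slot mask the [MetalMask-class] used.
#' @slot epsClamp lower clamp applied to `(1 - S)` in the inversion.
#' @exportClass DecompositionPair
setClass("DecompositionPair",
  representation(S = "matrix", U = "matrix", mask = "MetalMask",
                 epsClamp = "numeric"))

setValidity("DecompositionPair", function(object) {
  msg <- character()
  if (!identical(dim(object@S), dim(object@U)))
    msg <- c(msg, "S and U must share one shape")
  if (!identical(dim(object@S), dim(object@mask@pixels)))
    msg <- c(msg, "mask must match the frame shape")
  if (any(object@U[!object@mask@pixels] != 0))
    msg <- c(msg, "U must be 0 outside the mask")
  if (length(msg)) msg else TRUE
})

#' Single-row sinogram with a metal trace
#'
#' The `(angle, detector column)` arrangement of one detector row across
#' all projections, together with the binary trace of metal-affected bins.
#' This is the working surface of the sinogram-inpainting baselines
#' [limar()] and [nmar()].
#'
#' @slot values numeric matrix `n_angles x n_cols`.
#' @slot trace logical matrix of metal-affected bins, same shape.
#' @slot angles projection angles in degrees.
#' @slot domain value domain (as for [ProjectionStack-class]).
#' @exportClass MetalSinogram
setClass("MetalSinogram",
  representation(values = "matrix", trace = "matrix", angles = "numeric",
                 domain = "character"))

setValidity("MetalSinogram", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@trace)))
    msg <- c(msg, "trace shape must equal values shape")
  if (!is.logical(object@trace))
    msg <- c(msg, "trace must be logical")
  if (nrow(object@values) != length(object@angles))
    msg <- c(msg, "one angle per sinogram row is required")
  if (!object@domain %in% .stack_domains)
    msg <- c(msg, "invalid domain")
  if (length(msg)) msg else TRUE
})

#' Construct a MetalSinogram
#'
#' @param values numeric matrix `n_angles x n_cols`.
#' @param trace logical matrix of metal-affected bins (default none).
#' @param angles projection angles in degrees.
#' @param domain value domain of `values`.
#' @return A [MetalSinogram-class] object.
#' @export
MetalSinogram <- function(values, trace = NULL, angles = NULL,
                          domain = c("line_integral", "transmittance",
                                     "raw_counts")) {
  if (is.null(trace))
    trace <- matrix(FALSE, nrow(values), ncol(values))
  if (is.null(angles)) angles <- uniformAngles(nrow(values))
  new("MetalSinogram", values = values, trace = trace,
      angles = as.numeric(angles), domain = match.arg(domain))
}
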