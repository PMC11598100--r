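# Accessor generics and show methods for the core classes.

#' Accessors for the core data classes
#'
#' `frames`, `angles`, `pixelPitch`, `stackDomain`, `flatField` read the
#' slots of a [ProjectionStack-class]; `voxels` and `voxelSize` those of a
#' [CTVolume-class]; `maskPixels` the binary mask of a [MetalMask-class];
#' `sinogramValues` and `sinogramTrace` those of a [MetalSinogram-class];
#' `softImage`, `hardImage` and `hardTransmittance` the components of a
#' [DecompositionPair-class].
#'
#' @param x the object.
#' @return The corresponding slot value (see Details of each class).
#' @name accessors
#' @aliases frames angles pixelPitch stackDomain flatField voxels voxelSize
#'   maskPixels sinogramValues sinogramTrace softImage hardImage
#'   hardTransmittance
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("stackDomain", function(x) standardGeneric("stackDomain"))
#' @rdname accessors
#' @export
setGeneric("flatField", function(x) standardGeneric("flatField"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setGeneric("sinogramTrace", function(x) standardGeneric("sinogramTrace"))
#' @rdname accessors
#' @export
setGeneric("softImage", function(x) standardGeneric("softImage"))
#' @rdname accessors
#' @export
setGeneric("hardImage", function(x) standardGeneric("hardImage"))
#' @rdname accessors
#' @export
setGeneric("hardTransmittance", function(x) standardGeneric("hardTransmittance"))

#' @rdname accessors
setMethod("frames", "ProjectionStack", function(x) x@frames)
#' @rdname accessors
setMethod("angles", "ProjectionStack", function(x) x@angles)
#' @rdname accessors
setMethod("angles", "MetalSinogram", function(x) x@angles)
#' @rdname accessors
setMethod("pixelPitch", "ProjectionStack", function(x) x@pixelPitch)
#' @rdname accessors
setMethod("stackDomain", "ProjectionStack", function(x) x@domain)
#' @rdname accessors
setMethod("stackDomain", "MetalSinogram", function(x) x@domain)
#' @rdname accessors
setMethod("flatField", "ProjectionStack", function(x) x@i0)
#' @rdname accessors
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelSize", "CTVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("maskPixels", "MetalMask", function(x) x@pixels)
#' @rdname accessors
setMethod("sinogramValues", "MetalSinogram", function(x) x@values)
#' @rdname accessors
setMethod("sinogramTrace", "MetalSinogram", function(x) x@trace)
#' @rdname accessors
setMethod("softImage", "DecompositionPair", function(x) x@S)
#' @rdname accessors
setMethod("hardImage", "DecompositionPair", function(x) x@U)

#' @rdname accessors
#' @details `hardTransmittance` returns the multiplicative hard-tissue
#'   transmittance `f / S` (clamped to \[0, 1\]), whose negative log is the
#'   dense object's own attenuation line integral: the input for hard-tissue
#'   ("bone image") reconstruction.
setMethod("hardTransmittance", "DecompositionPair", function(x) {
  S <- x@S
  f <- recompose(S, x@U)
  t <- f / pmax(S, x@epsClamp)
  t[!x@mask@pixels] <- 1
  pmin(pmax(t, 0), 1)
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat("ProjectionStack:", d[1L], "frames of", d[2L], "x", d[3L],
      "pixels |", object@domain, "\n")
  cat("  angles:", format(object@angles[1L], digits = 4), "..",
      format(object@angles[d[1L]], digits = 4), "deg | pitch",
      object@pixelPitch, "mm\n")
})

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry:", object@beamType, "beam,",
      object@detectorRows, "x", object@detectorCols, "detector,",
      object@rotationRange, "deg scan\n")
  if (object@beamType == "cone")
    cat("  SOD", object@sourceObjectDist, "mm | SDD",
        object@sourceDetectorDist, "mm\n")
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat("CTVolume:", d[1L], "x", d[2L], "x", d[3L], "voxels of",
      object@voxelSize, "mm\n")
})

setMethod("show", "PyramidFilters", function(object) {
  cat("PyramidFilters (weight exponent", object@weightExponent, "):\n")
  cat("  h1:", format(object@h1, digits = 4), "\n")
  cat("  h2:", format(object@h2, digits = 4), "\n")
  cat("  g :", format(object@g, digits = 4), "\n")
})

setMethod("show", "MetalMask", function(object) {
  cat("MetalMask:", sum(object@pixels), "of", length(object@pixels),
      "pixels | threshold", object@threshold, "| dilation",
      object@dilationRadius, "px\n")
})

setMethod("show", "DecompositionPair", function(object) {
  cat("DecompositionPair:", nrow(object@S), "x", ncol(object@S),
      "| masked pixels:", sum(object@mask@pixels), "\n")
})

setMethod("show", "MetalSinogram", function(object) {
  cat("MetalSinogram:", nrow(object@values), "angles x",
      ncol(object@values), "bins |", object@domain, "| traced bins:",
      sum(object@trace), "\n")
})
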