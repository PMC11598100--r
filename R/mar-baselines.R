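# Reference sinogram-inpainting MAR methods: linear-interpolation MAR
# (LI-MAR) and normalized MAR (NMAR).  Both replace the metal trace of a
# per-row sinogram by interpolated values; interpolation is always carried
# out in the attenuation line-integral (-log transmittance) domain, the
# domain MAR methods are defined on, and results are converted back to the
# input's domain.

#' Rearrange a projection stack into per-row sinograms
#'
#' For each detector row `r`, `sinogram[[r]][i, c] = frames[i, r, c]`; the
#' metal trace is taken from the mask stack the same way.
#' [sinogramsToStack()] inverts the rearrangement exactly.
#'
#' @param stack a [ProjectionStack-class].
#' @param masks logical array shaped like the frames (e.g. from
#'   [decomposeStack()]), or `NULL` for empty traces.
#' @return list of [MetalSinogram-class] objects, one per detector row.
#' @export
buildSinograms <- function(stack, masks = NULL) {
  fr <- frames(stack)
  d <- dim(fr)
  if (!is.null(masks) && !identical(dim(masks), d))
    stop("mask stack shape does not match the projection stack")
  lapply(seq_len(d[2L]), function(r) {
    tr <- if (is.null(masks)) matrix(FALSE, d[1L], d[3L]) else
      matrix(masks[, r, ], d[1L], d[3L])
    MetalSinogram(matrix(fr[, r, ], d[1L], d[3L]), trace = tr,
                  angles = angles(stack), domain = stackDomain(stack))
  })
}

#' @rdname buildSinograms
#' @param sinos list of [MetalSinogram-class] objects, one per detector
#'   row, as produced by [buildSinograms()].
#' @param template a [ProjectionStack-class] providing angles, pitch and
#'   domain for the rebuilt stack.
#' @export
sinogramsToStack <- function(sinos, template) {
  d <- c(length(angles(template)), length(sinos), ncol(sinos[[1L]]@values))
  fr <- array(0, d)
  for (r in seq_len(d[2L])) fr[, r, ] <- sinos[[r]]@values
  ProjectionStack(fr, angles = angles(template),
                  pixelPitch = pixelPitch(template),
                  domain = stackDomain(template), i0 = flatField(template))
}

# linear interpolation across the trace, one sinogram row (fixed angle) at
# a time, in line-integral domain; edge-touching runs use nearest-value
# extension; fully traced rows fall back to the mean of adjacent angles
.inpaintRows <- function(values, trace) {
  out <- values
  full <- which(rowSums(!trace) == 0L)
  for (i in seq_len(nrow(values))) {
    tr <- trace[i, ]
    if (!any(tr)) next
    keep <- which(!tr)
    if (!length(keep)) next  # handled below from adjacent angles
    out[i, tr] <- approx(keep, values[i, keep], xout = which(tr),
                         rule = 2)$y
  }
  if (length(full)) {
    warning("sinogram rows fully traced at ", length(full),
            " angle(s); filled with adjacent-angle row means")
    n <- nrow(values)
    for (i in full) {
      nb <- c(if (i > 1L) i - 1L, if (i < n) i + 1L)
      nb <- setdiff(nb, full)
      fill <- if (length(nb)) mean(out[nb, ]) else mean(values[!trace])
      out[i, ] <- fill
    }
  }
  out
}

.sinoToLin <- function(sino) .toLineIntegrals(sino@values, sino@domain)

.linToDomain <- function(lin, domain) {
  switch(domain,
    line_integral = lin,
    transmittance = exp(-lin),
    stop("unsupported sinogram domain: ", domain))
}

#' Linear-interpolation MAR (LI-MAR)
#'
#' In every angular row, each maximal run of metal-trace bins is replaced
#' by 1D linear interpolation (in the attenuation line-integral domain)
#' between the nearest untraced values on either side; runs touching the
#' row edge are filled by nearest-value extension.  Untraced bins are
#' unchanged, and the operation is idempotent.
#'
#' @param sino a [MetalSinogram-class] with its metal trace set.
#' @return A [MetalSinogram-class] with trace bins replaced (same domain).
#' @export
limar <- function(sino) {
  lin <- .inpaintRows(.sinoToLin(sino), sino@trace)
  out <- sino
  vals <- .linToDomain(lin, sino@domain)
  out@values[sino@trace] <- vals[sino@trace]
  out
}

#' Normalized MAR (NMAR)
#'
#' Divides the sinogram by a forward-projected prior sinogram (floored at
#' `1e-6 * max(prior)`), fills the flattened trace with the LI-MAR
#' interpolation, multiplies the prior back in, and restores untraced bins
#' from the input.  With a constant prior, NMAR reduces exactly to LI-MAR.
#'
#' @param sino a [MetalSinogram-class] with its metal trace set.
#' @param prior prior line-integral sinogram: a numeric matrix (shape of
#'   `sino`) or a [MetalSinogram-class], typically forward-projected from
#'   [makeNmarPrior()].
#' @return A [MetalSinogram-class] with trace bins replaced (same domain).
#' @export
nmar <- function(sino, prior) {
  if (is(prior, "MetalSinogram")) prior <- .toLineIntegrals(prior@values,
                                                            prior@domain)
  if (!identical(dim(prior), dim(sino@values)))
    stop("prior shape does not match the sinogram")
  if (max(prior) <= 0) stop("prior sinogram is all zero")
  lin <- .sinoToLin(sino)
  pfloor <- pmax(prior, 1e-6 * max(prior))
  norm <- lin / pfloor
  filled <- .inpaintRows(norm, sino@trace) * pfloor
  out <- sino
  vals <- .linToDomain(filled, sino@domain)
  out@values[sino@trace] <- vals[sino@trace]
  out
}

#' Build a tissue-class prior volume for NMAR
#'
#' Classifies an uncorrected reconstruction into air (below `airThreshold`,
#' set to 0) and soft tissue (set to the median soft-tissue value); voxels
#' above `softThreshold` (metal) are also set to the soft-tissue value.
#' Forward-projecting the result with the scan geometry yields the NMAR
#' prior sinogram.  A degenerate single-class histogram produces a
#' constant prior (NMAR then degrades to LI-MAR) with a warning.
#'
#' @param vol a [CTVolume-class] (or matrix slice) reconstructed without
#'   MAR.
#' @param airThreshold,softThreshold attenuation class boundaries.
#' @return object of the same kind as `vol` with classified voxel values.
#' @export
makeNmarPrior <- function(vol, airThreshold, softThreshold) {
  v <- if (is(vol, "CTVolume")) voxels(vol) else vol
  soft <- v >= airThreshold & v <= softThreshold
  if (!any(soft)) {
    warning("degenerate histogram: no soft-tissue class; prior is constant")
    softVal <- 0
  } else {
    softVal <- median(v[soft])
  }
  out <- array(0, dim(v) %||% length(v))
  out[v >= airThreshold] <- softVal
  out <- array(out, dim(v))
  if (is(vol, "CTVolume")) CTVolume(out, voxelSize(vol)) else out
}

#' Apply a sinogram-domain MAR baseline to one sinogram
#'
#' Convenience wrapper running `"limar"` or `"nmar"` (building the prior
#' from an uncorrected [fbp2d()] reconstruction) on a single sinogram.
#'
#' @param sino a [MetalSinogram-class] with trace set.
#' @param method `"limar"` or `"nmar"`.
#' @param pitch detector pitch in mm (for the prior reconstruction).
#' @param airThreshold,softThreshold NMAR tissue-class boundaries; by
#'   default both derive from the soft-tissue level of the uncorrected
#'   reconstruction (the median of voxels above half its 95th percentile,
#'   a statistic that skips the air/noise floor): air below 40% of that
#'   level, metal above 3x that level.
#' @param kind ramp window for the prior reconstruction.
#' @return A [MetalSinogram-class].
#' @export
applyBaselineMAR <- function(sino, method = c("limar", "nmar"), pitch = 1,
                             airThreshold = NULL, softThreshold = NULL,
                             kind = "hamming") {
  method <- match.arg(method)
  if (method == "limar") return(limar(sino))
  rec <- fbp2d(sino, pitch = pitch, kind = kind)
  q95 <- quantile(rec, 0.95, names = FALSE)
  obj <- rec[rec > 0.5 * q95]
  m <- if (length(obj)) median(obj) else 0
  if (is.null(airThreshold)) airThreshold <- 0.4 * m
  if (is.null(softThreshold)) softThreshold <- 3 * m
  prior <- makeNmarPrior(rec, airThreshold, softThreshold)
  priorSino <- forwardProjectImage(prior, angles(sino), pixelSize = pitch,
                                   ndet = ncol(sino@values), pitch = pitch)
  nmar(sino, priorSino)
}
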