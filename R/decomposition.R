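# Soft/hard decomposition of a projection under the image-formation model
#   f = U * (1 - S) + S
# with S the soft-tissue transmittance (membrane fill inside the metal
# mask, the raw frame outside) and U the hard-tissue image obtained by
# algebraic inversion.

#' Normalize raw detector counts to transmittance
#'
#' `t = clip(raw / i0, 0, 1)` with `i0` the flat-field (unattenuated)
#' count level.  When `i0` is not supplied it is estimated as the 99.9th
#' percentile of the frame (in an air-dominated background this is the
#' flat-field level to within noise).
#'
#' @param raw numeric matrix of detector counts.
#' @param i0 flat-field level in counts (> 0).
#' @return numeric matrix of transmittance values in \[0, 1\].
#' @export
normalizeTransmittance <- function(raw, i0 = NULL) {
  if (is.null(i0)) i0 <- quantile(raw, 0.999, names = FALSE)
  if (!isTRUE(i0 > 0)) stop("i0 must be positive")
  pmin(pmax(raw / i0, 0), 1)
}

#' Threshold a projection into a metal mask
#'
#' Metal absorbs strongly, so it appears *dark* on the detector: mask
#' pixels are those with raw counts strictly below the threshold, then
#' dilated by a disc to absorb partial-volume fringes at the object edge.
#' Raising the threshold grows the mask monotonically (before dilation,
#' `mask(th1)` is a subset of `mask(th2)` whenever `th1 <= th2`).
#'
#' @param raw numeric matrix of raw detector counts.
#' @param threshold count threshold; pixels with `raw < threshold` are
#'   masked.
#' @param dilationRadius dilation disc radius in pixels (default 1; radius
#'   1 is the full 8-neighbourhood).  An empty mask is legal.
#' @return A [MetalMask-class].
#' @export
computeMask <- function(raw, threshold, dilationRadius = 1) {
  stopifnot(is.matrix(raw))
  pixels <- raw < threshold
  if (any(pixels) && dilationRadius > 0)
    pixels <- binaryDilate(pixels, dilationRadius)
  new("MetalMask", pixels = pixels, threshold = threshold,
      dilationRadius = dilationRadius)
}

#' Decompose a projection into soft- and hard-tissue images
#'
#' Computes the soft-tissue transmittance `S` as the membrane fill of the
#' masked region (identical to `f` outside the mask, smooth inverse-
#' distance interpolation of the boundary values inside) and the
#' hard-tissue image `U` by inverting the image-formation model
#' `f = U * (1 - S) + S`:
#' \deqn{U = (f - S) / \max(1 - S, \epsilon).}
#' In the transmittance domain a dense object only removes signal
#' (`f <= S` under the mask when the fill estimates the unobstructed soft
#' tissue), so `U` is non-positive there and exactly 0 outside the mask.
#' The inversion is exact: [recompose()] restores `f` to numerical
#' precision wherever the clamp on `(1 - S)` is inactive.
#'
#' @param f numeric matrix of transmittance values in \[0, 1\]
#'   (tolerance 1e-6; normalize first).
#' @param mask a [MetalMask-class] or logical matrix.  An empty mask
#'   yields `S = f`, `U = 0`.
#' @param filters pyramid filters for the membrane fill.
#' @param epsClamp lower clamp on `(1 - S)` guarding the `S -> 1`
#'   degeneracy of the model (default 1e-3).
#' @param method `"convpyr"` (default) or `"shepard"` for the exact
#'   O(K n) reference fill.
#' @return A [DecompositionPair-class].
#' @export
decompose <- function(f, mask, filters = defaultPyramidFilters(),
                      epsClamp = 1e-3, method = c("convpyr", "shepard")) {
  method <- match.arg(method)
  if (min(f) < -1e-6 || max(f) > 1 + 1e-6)
    stop("f is not a transmittance image (values outside [0, 1]); ",
         "call normalizeTransmittance() first")
  if (is(mask, "MetalMask")) m <- mask else {
    m <- new("MetalMask", pixels = mask > 0, threshold = NA_real_,
             dilationRadius = 0)
    mask <- m
  }
  px <- m@pixels
  if (!any(px)) {
    return(new("DecompositionPair", S = f, U = matrix(0, nrow(f), ncol(f)),
               mask = m, epsClamp = epsClamp))
  }
  S <- switch(method,
    convpyr = membraneInterpolate(f, px, filters),
    shepard = shepardDirect(f, px))
  S[px] <- pmin(pmax(S[px], 0), 1)
  U <- matrix(0, nrow(f), ncol(f))
  U[px] <- (f[px] - S[px]) / pmax(1 - S[px], epsClamp)
  new("DecompositionPair", S = S, U = U, mask = m, epsClamp = epsClamp)
}

#' Recompose a projection from its soft and hard components
#'
#' The image-formation model: `f = U * (1 - S) + S` elementwise.  With
#' `U = 0` this returns `S`; with `S = 1` it returns 1 for any `U` (the
#' degeneracy motivating the `epsClamp` guard in [decompose()]).
#'
#' @param S soft-tissue transmittance matrix.
#' @param U hard-tissue image matrix of the same shape.
#' @return numeric matrix `U * (1 - S) + S`.
#' @export
recompose <- function(S, U) {
  if (!identical(dim(S), dim(U))) stop("S and U shapes differ")
  U * (1 - S) + S
}

#' Decompose every frame of a projection stack
#'
#' Applies [computeMask()] (on raw counts) and [decompose()] (on
#' transmittance) per projection and returns the soft-tissue transmittance
#' stack, the hard-tissue transmittance stack and the mask stack.
#'
#' @param stack a raw-counts [ProjectionStack-class].
#' @param threshold raw-count mask threshold.
#' @param i0 flat-field level (default: estimated per stack as the 99.9th
#'   percentile of all counts).
#' @param dilationRadius mask dilation radius in pixels.
#' @param filters pyramid filters for the membrane fill.
#' @param epsClamp clamp passed to [decompose()].
#' @return list with `soft` and `hard` (transmittance
#'   [ProjectionStack-class]s) and `masks` (logical array shaped like the
#'   frames).
#' @export
decomposeStack <- function(stack, threshold, i0 = NULL, dilationRadius = 1,
                           filters = defaultPyramidFilters(),
                           epsClamp = 1e-3) {
  stopifnot(stackDomain(stack) == "raw_counts")
  fr <- frames(stack)
  if (is.null(i0)) {
    i0 <- if (is.finite(flatField(stack))) flatField(stack) else
      quantile(fr, 0.999, names = FALSE)
  }
  na <- dim(fr)[1L]
  soft <- fr
  hard <- fr
  masks <- array(FALSE, dim(fr))
  for (i in seq_len(na)) {
    raw <- fr[i, , ]
    m <- computeMask(raw, threshold, dilationRadius)
    t <- normalizeTransmittance(raw, i0)
    pair <- decompose(t, m, filters = filters, epsClamp = epsClamp)
    soft[i, , ] <- softImage(pair)
    hard[i, , ] <- hardTransmittance(pair)
    masks[i, , ] <- maskPixels(m)
  }
  bstdLog("decompose_stack", sprintf("threshold=%g i0=%g frames=%d",
                                     threshold, i0, na))
  list(soft = ProjectionStack(soft, angles = angles(stack),
                              pixelPitch = pixelPitch(stack),
                              domain = "transmittance", i0 = 1),
       hard = ProjectionStack(hard, angles = angles(stack),
                              pixelPitch = pixelPitch(stack),
                              domain = "transmittance", i0 = 1),
       masks = masks)
}
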