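# Quantitative evaluation: SSIM, PSNR, background normalization,
# absolute-difference maps, intensity profiles and baseline removal.

.checkShapes <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
}

.ssimTerm <- function(mx, my, vx, vy, cxy, c1, c2) {
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Structural similarity index (SSIM)
#'
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'  {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} and population
#' moments (variances and covariance normalized by the pixel count).
#' The default `"global"` mode evaluates the formula once with image-wide
#' moments; `"windowed"` averages per-window evaluations of a sliding
#' square window with stride 1.
#'
#' @param a,b numeric matrices of the same shape.
#' @param L dynamic range; default the maximum of the reference image `b`.
#' @param k1,k2 stabilization factors (defaults 0.01 and 0.03).
#' @param mode `"global"` (default) or `"windowed"`.
#' @param window window side length for windowed mode (default 8).
#' @return scalar in \[-1, 1\]; `computeSSIM(a, a)` is exactly 1.
#' @export
computeSSIM <- function(a, b, L = NULL, k1 = 0.01, k2 = 0.03,
                        mode = c("global", "windowed"), window = 8) {
  mode <- match.arg(mode)
  .checkShapes(a, b)
  if (is.null(L)) L <- max(b)
  stopifnot(L > 0)
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (mode == "global") {
    n <- length(a)
    mx <- mean(a); my <- mean(b)
    vx <- sum((a - mx)^2) / n
    vy <- sum((b - my)^2) / n
    cxy <- sum((a - mx) * (b - my)) / n
    return(.ssimTerm(mx, my, vx, vy, cxy, c1, c2))
  }
  w <- as.integer(window)
  stopifnot(w >= 2, nrow(a) >= w, ncol(a) >= w)
  boxMean <- function(x) {
    # mean over every w x w window via a summed-area table
    cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    cs <- rbind(0, cbind(0, cs))
    nr <- nrow(x); nc <- ncol(x)
    i <- seq_len(nr - w + 1L); j <- seq_len(nc - w + 1L)
    (cs[i + w, j + w, drop = FALSE] - cs[i, j + w, drop = FALSE] -
       cs[i + w, j, drop = FALSE] + cs[i, j, drop = FALSE]) / w^2
  }
  mx <- boxMean(a); my <- boxMean(b)
  vx <- boxMean(a^2) - mx^2
  vy <- boxMean(b^2) - my^2
  cxy <- boxMean(a * b) - mx * my
  mean(.ssimTerm(mx, my, vx, vy, cxy, c1, c2))
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `20*log10(maxI) - 10*log10(MSE)` in dB, with `MSE` the mean squared
#' difference.  Identical images have zero MSE; the documented sentinel
#' `Inf` is returned in that case.
#'
#' @param a,b numeric matrices of the same shape.
#' @param maxI peak intensity; default the maximum of the reference `b`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
computePSNR <- function(a, b, maxI = NULL) {
  .checkShapes(a, b)
  if (is.null(maxI)) maxI <- max(b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  20 * log10(maxI) - 10 * log10(mse)
}

#' Equalize the background level of an image against a reference
#'
#' Applies the affine map that makes the mean and standard deviation of
#' `img` over the background region match those of `ref` there.  The
#' default region is an automatically detected air region: the lowest
#' decile of the reference values, detected on a 3x3 box-smoothed copy of
#' the reference so that the selection does not condition on the
#' reference's own per-pixel noise (which would bias its in-region
#' standard deviation low).  With zero background variance an offset-only
#' match is applied with a warning.
#'
#' @param img image to normalize.
#' @param ref reference image of the same shape.
#' @param region logical matrix selecting background pixels (non-empty).
#' @return normalized image matrix.
#' @export
normalizeBackground <- function(img, ref, region = NULL) {
  .checkShapes(img, ref)
  if (is.null(region)) {
    sm <- cpp_sepconv(ref, rep(1 / 3, 3))
    region <- sm <= quantile(sm, 0.1, names = FALSE)
  }
  if (!any(region)) stop("background region is empty")
  mi <- mean(img[region]); mr <- mean(ref[region])
  si <- sd(img[region]); sr <- sd(ref[region])
  if (!isTRUE(si > 0)) {
    warning("zero background variance: offset-only normalization")
    return(img - mi + mr)
  }
  (img - mi) * (sr / si) + mr
}

#' Absolute-difference map
#'
#' @param a,b numeric matrices of the same shape.
#' @return `|a - b|`, elementwise.
#' @export
absdiffMap <- function(a, b) {
  .checkShapes(a, b)
  abs(a - b)
}

#' Extract an intensity profile along a row or column
#'
#' @param img numeric matrix.
#' @param row,col 1-based index of the row *or* column to extract
#'   (exactly one of the two).
#' @return numeric vector of pixel intensities.
#' @export
intensityProfile <- function(img, row = NULL, col = NULL) {
  if (is.null(row) == is.null(col))
    stop("give exactly one of 'row' or 'col'")
  if (!is.null(row)) {
    if (row < 1 || row > nrow(img)) stop("row index out of range")
    return(img[row, ])
  }
  if (col < 1 || col > ncol(img)) stop("column index out of range")
  img[, col]
}

#' Remove a low-order baseline from a profile
#'
#' Subtracts a polynomial least-squares fit (default linear) from the
#' profile, so a purely affine profile becomes (numerically) zero.
#'
#' @param profile numeric vector.
#' @param degree polynomial degree of the baseline (default 1).
#' @return numeric vector of residuals.
#' @export
removeBaseline <- function(profile, degree = 1) {
  x <- seq_along(profile)
  fit <- lm(profile ~ stats::poly(x, degree, raw = TRUE))
  as.vector(profile - stats::fitted(fit))
}

#' Compare a reconstruction against a reference image
#'
#' Background-normalizes the reconstruction to the reference
#' ([normalizeBackground()]) and reports global SSIM, PSNR and the mean
#' absolute-difference map value.
#'
#' @param recon reconstructed slice (matrix or [CTVolume-class]).
#' @param reference reference slice of the same shape.
#' @param normalize background-normalize before scoring? (default TRUE)
#' @return list with `ssim`, `psnr`, `meanAbsDiff`.
#' @export
evaluateReconstruction <- function(recon, reference, normalize = TRUE) {
  r <- if (is(recon, "CTVolume")) voxels(recon)[, , 1L] else recon
  ref <- if (is(reference, "CTVolume")) voxels(reference)[, , 1L] else reference
  if (normalize) r <- normalizeBackground(r, ref)
  list(ssim = computeSSIM(r, ref),
       psnr = computePSNR(r, ref),
       meanAbsDiff = mean(absdiffMap(r, ref)))
}
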