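# Membrane interpolation: fill a masked region smoothly from its boundary
# values.  Two routes compute the same quantity:
#   * shepardDirect()      - exact inverse-distance (d^-3) weighted average,
#                            O(K * n); serves as the reference/oracle.
#   * membraneInterpolate() - ratio of two convolution-pyramid passes,
#                            O(n); the production path.

.discOffsets <- function(radius) {
  r <- max(0L, as.integer(round(radius)))
  dd <- expand.grid(di = -r:r, dj = -r:r)
  # (r + 0.5)-inflated Euclidean disc: radius 1 is the full 8-neighbourhood
  dd[dd$di^2 + dd$dj^2 <= (radius + 0.5)^2, , drop = FALSE]
}

# shift-OR dilation of a logical matrix by a disc of the given radius
binaryDilate <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  off <- .discOffsets(radius)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | mask[si, sj]
  }
  out
}

#' Extract the boundary ring of a masked region
#'
#' The boundary of a binary mask is the set of pixels *outside* the mask
#' that are 8-adjacent to a mask pixel (an exterior ring, so boundary
#' values are never contaminated by in-mask intensities).  Returns the
#' boundary extension used by the convolution-pyramid membrane: `rhat`
#' carries the image value on boundary pixels and 0 elsewhere, and the
#' characteristic image `chi` is 1 exactly on boundary pixels.
#'
#' @param f numeric image matrix.
#' @param mask logical matrix of the same shape; must be non-empty and must
#'   not cover the whole image.
#' @return list with components `rhat`, `chi` (numeric matrices) and
#'   `boundary` (logical matrix).
#' @export
extractBoundary <- function(f, mask) {
  stopifnot(is.matrix(f), identical(dim(f), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty: no region to interpolate")
  boundary <- binaryDilate(mask, 1) & !mask
  if (!any(boundary))
    stop("mask covers the whole image: no boundary exists")
  chi <- matrix(0, nrow(f), ncol(f))
  chi[boundary] <- 1
  rhat <- chi * f
  list(rhat = rhat, chi = chi, boundary = boundary)
}

# pad f (edge-replicated) and mask (FALSE border) when the mask touches the
# image edge, so an exterior boundary ring always exists
.padForMask <- function(f, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  touches <- any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) ||
    any(mask[, nc])
  if (!touches) return(list(f = f, mask = mask, pad = 0L))
  fp <- rbind(f[1, , drop = FALSE], f, f[nr, , drop = FALSE])
  fp <- cbind(fp[, 1, drop = FALSE], fp, fp[, nc, drop = FALSE])
  mp <- matrix(FALSE, nr + 2L, nc + 2L)
  mp[2:(nr + 1L), 2:(nc + 1L)] <- mask
  list(f = fp, mask = mp, pad = 1L)
}

#' Exact Shepard membrane fill (reference implementation)
#'
#' For every pixel `x` inside the mask computes the inverse-distance
#' weighted average of the boundary values,
#' \deqn{r(x) = \sum_k w_k(x) b(x_k) / \sum_k w_k(x), \quad
#'       w_k(x) = d(x_k, x)^{-p},}
#' with Euclidean pixel distance `d` and exponent `p = 3` by default.
#' Pixels outside the mask are returned unchanged, so the result matches
#' `f` bit-exactly on and beyond the boundary.  Complexity is
#' O(boundary size x mask size); this is the test oracle for
#' [membraneInterpolate()], not the production path.
#'
#' @param f numeric image matrix.
#' @param mask logical matrix (same shape): the region to fill.
#' @param weightExponent inverse-distance exponent `p` (default 3).
#' @return numeric matrix: `f` with the masked region replaced by the
#'   membrane fill.  Every filled value lies within the range of the
#'   boundary values (convex combination).
#' @export
shepardDirect <- function(f, mask, weightExponent = 3) {
  p <- .padForMask(f, mask > 0)
  bext <- extractBoundary(p$f, p$mask)
  bidx <- which(bext$boundary, arr.ind = TRUE)
  bval <- p$f[bext$boundary]
  iidx <- which(p$mask, arr.ind = TRUE)
  d2 <- outer(iidx[, 1], bidx[, 1], "-")^2 +
        outer(iidx[, 2], bidx[, 2], "-")^2
  stopifnot(all(d2 > 0))  # boundary and interior are disjoint by construction
  w <- d2^(-weightExponent / 2)
  r <- as.vector(w %*% bval) / rowSums(w)
  out <- p$f
  out[p$mask] <- r
  if (p$pad > 0L) out <- out[2:(nrow(out) - 1L), 2:(ncol(out) - 1L)]
  out
}

.down2 <- function(x) x[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]

.up2 <- function(x, targetDim) {
  z <- matrix(0, targetDim[1L], targetDim[2L])
  z[seq(1, targetDim[1L], 2), seq(1, targetDim[2L], 2)] <- x
  z
}

.defaultLevels <- function(d) max(1L, floor(log2(min(d))) - 1L)

#' Approximate large-kernel convolution with a convolution pyramid
#'
#' Multiscale approximation of `w * x` for the large-support
#' inverse-distance kernel \eqn{w(d) = d^{-p}}: the analysis pass filters
#' with `h1` and downsamples by 2 per level; the synthesis pass upsamples,
#' filters with `h2` and adds the `g`-filtered analysis signal of each
#' level.  All filters are small and separable, so the total cost is linear
#' in the pixel count.  The input is zero-padded to cover the coarsest
#' kernel support and cropped afterwards.
#'
#' @param x numeric matrix (finite values).
#' @param filters a [PyramidFilters-class], e.g. [defaultPyramidFilters()].
#' @param nLevels pyramid depth; default `floor(log2(min(dim(x)))) - 1`,
#'   automatically reduced (with a log line) when the image is too small
#'   for the coarsest-level kernel support.
#' @return numeric matrix of the same shape as `x`.
#' @export
convpyrConvolve <- function(x, filters, nLevels = NULL) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  L <- if (is.null(nLevels)) .defaultLevels(dim(x)) else as.integer(nLevels)
  # the coarsest level must still fit the 5-tap kernels
  maxL <- max(1L, floor(log2(min(dim(x)) / 4)))
  if (L > maxL) {
    bstdLog("convpyr", sprintf("reducing n_levels %d -> %d for %dx%d image",
                               L, maxL, nrow(x), ncol(x)))
    L <- maxL
  }
  pad <- 2L^L + 4L
  nr <- nrow(x) + 2L * pad
  nc <- ncol(x) + 2L * pad
  xp <- matrix(0, nr, nc)
  xp[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))] <- x
  a <- vector("list", L + 1L)
  a[[1L]] <- xp
  for (l in seq_len(L))
    a[[l + 1L]] <- .down2(cpp_sepconv(a[[l]], filters@h1))
  ah <- cpp_sepconv(a[[L + 1L]], filters@g)
  for (l in rev(seq_len(L)))
    ah <- cpp_sepconv(.up2(ah, dim(a[[l]])), filters@h2) +
      cpp_sepconv(a[[l]], filters@g)
  ah[pad + seq_len(nrow(x)), pad + seq_len(ncol(x)), drop = FALSE]
}

#' Fast membrane fill via convolution pyramids
#'
#' Computes the Shepard membrane as a ratio of two pyramid convolutions,
#' `(w * rhat) / (w * chi)`, where `rhat` carries the boundary values
#' and `chi` their characteristic image (see [extractBoundary()]).  Pixels
#' outside the mask are returned unchanged (bit-exact), enforcing equality
#' with `f` on the boundary ring.
#'
#' @inheritParams shepardDirect
#' @param filters a [PyramidFilters-class] fitted for the desired weight
#'   exponent; defaults to the shipped `d^-3` set.
#' @param nLevels pyramid depth override (see [convpyrConvolve()]).
#' @return numeric matrix: `f` with the masked region replaced by the
#'   membrane fill.
#' @export
membraneInterpolate <- function(f, mask, filters = defaultPyramidFilters(),
                                nLevels = NULL) {
  p <- .padForMask(f, mask > 0)
  bext <- extractBoundary(p$f, p$mask)
  num <- convpyrConvolve(bext$rhat, filters, nLevels)
  den <- convpyrConvolve(bext$chi, filters, nLevels)
  inside <- p$mask
  if (any(den[inside] < 1e-12))
    stop("membrane denominator underflow inside the mask: ",
         "broken pyramid filters or empty boundary")
  out <- p$f
  out[inside] <- num[inside] / den[inside]
  if (p$pad > 0L) out <- out[2:(nrow(out) - 1L), 2:(ncol(out) - 1L)]
  out
}

## --- filter fitting ---------------------------------------------------------

.filtersFromPar <- function(par, weightExponent) {
  h1 <- c(par[3], par[2], par[1], par[2], par[3])
  h2 <- c(par[6], par[5], par[4], par[5], par[6])
  g <- c(par[8], par[7], par[8])
  new("PyramidFilters", h1 = h1, h2 = h2, g = g,
      weightExponent = weightExponent)
}

# relative L2 error of the pyramid against the exact radial convolution,
# measured where the (sparse) input is zero -- the pixels the membrane
# ratio actually uses
.pyrLoss <- function(par, inputs, targets, L, weightExponent) {
  filt <- .filtersFromPar(par, weightExponent)
  num <- 0
  den <- 0
  for (i in seq_along(inputs)) {
    out <- convpyrConvolve(inputs[[i]], filt, nLevels = L)
    z <- inputs[[i]] == 0
    num <- num + sum((out[z] - targets[[i]][z])^2)
    den <- den + sum(targets[[i]][z]^2)
  }
  sqrt(num / den)
}

#' Fit the convolution-pyramid kernels against the exact weight kernel
#'
#' Numerically determines the `(h1, h2, g)` triple (5/5/3-tap, symmetric,
#' separable) that minimizes the relative L2 error between
#' [convpyrConvolve()] and the exact dense convolution with
#' \eqn{w(d) = d^{-p}} over a seeded set of random sparse training images.
#' The error is evaluated on the zero pixels of each training input, which
#' are the pixels the membrane ratio consumes.  The fit is deterministic
#' given `seed`.  Fitted filters for the default exponent are cached as
#' package data ([defaultPyramidFilters()]), so end users never refit.
#'
#' @param weightExponent target kernel exponent `p` (> 0; default 3).
#' @param trainingSize side length of the square training images.
#' @param nTrain number of training images.
#' @param sparsity number of non-zero pixels per training image.
#' @param seed RNG seed for the training set.
#' @param maxit maximum BFGS iterations.
#' @param tolerance maximum admissible relative L2 residual; the fit aborts
#'   with an error (reporting the residual) if it cannot be reached.
#' @param init optional 8-vector of starting parameters
#'   `(h1 centre, h1 +-1, h1 +-2, h2 centre, h2 +-1, h2 +-2, g centre, g +-1)`.
#' @return A [PyramidFilters-class] with a `"residual"` attribute.
#' @export
fitFilters <- function(weightExponent = 3, trainingSize = 64, nTrain = 8,
                       sparsity = 40, seed = 17, maxit = 300,
                       tolerance = 0.05, init = NULL) {
  stopifnot(weightExponent > 0)
  inputs <- withSeed(seed, lapply(seq_len(nTrain), function(i) {
    x <- matrix(0, trainingSize, trainingSize)
    idx <- sample.int(trainingSize^2, sparsity)
    x[idx] <- runif(sparsity, 0.2, 1)
    x
  }))
  targets <- lapply(inputs, cpp_radial_convolve, p = weightExponent)
  L <- .defaultLevels(c(trainingSize, trainingSize))
  if (is.null(init))
    init <- c(1.03, 0.68, 0.15, 1.03, 0.68, 0.15, 0.78, 0.03)
  fit <- optim(init, .pyrLoss, inputs = inputs, targets = targets, L = L,
               weightExponent = weightExponent,
               method = "BFGS", control = list(maxit = maxit, reltol = 1e-10))
  res <- fit$value
  if (!is.finite(res) || res > tolerance)
    stop(sprintf(paste0("pyramid filter fit did not converge: relative L2 ",
                        "residual %.4f exceeds tolerance %.4f"),
                 res, tolerance))
  filt <- .filtersFromPar(fit$par, weightExponent)
  attr(filt, "residual") <- res
  bstdLog("fit_filters", sprintf("p=%g residual=%.4f", weightExponent, res))
  filt
}

#' Load the shipped pyramid filter set
#'
#' Reads the fitted `(h1, h2, g)` kernels for the given weight exponent
#' from the package's plain-text filter data (see [fitFilters()]).  The
#' result is cached for the session.
#'
#' @param weightExponent target kernel exponent (a shipped set must exist;
#'   the package ships `p = 3`).
#' @return A [PyramidFilters-class].
#' @export
defaultPyramidFilters <- local({
  cache <- list()
  function(weightExponent = 3) {
    key <- as.character(weightExponent)
    if (!is.null(cache[[key]])) return(cache[[key]])
    path <- system.file("extdata",
                        sprintf("pyramid-filters-w%g.txt", weightExponent),
                        package = "bstdmar")
    if (!nzchar(path))
      stop("no shipped filter set for weight exponent ", weightExponent,
           "; run fitFilters()")
    vals <- yaml::read_yaml(path)
    filt <- new("PyramidFilters", h1 = as.numeric(vals$h1),
                h2 = as.numeric(vals$h2), g = as.numeric(vals$g),
                weightExponent = as.numeric(vals$weight_exponent))
    cache[[key]] <<- filt
    filt
  }
})

# exact image of the radial kernel w(d) = d^-p centred at (ci, cj):
# the direct-evaluation oracle for impulse-response tests
radialKernelImage <- function(nr, nc, ci, cj, p = 3) {
  d2 <- outer(seq_len(nr) - ci, seq_len(nc) - cj,
              function(a, b) a^2 + b^2)
  k <- d2^(-p / 2)
  k[d2 == 0] <- 0
  k
}
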