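# Signal conditioning between externally-preprocessed BOLD and FC computation.
# Fixed stage order (asserted by the pipeline driver):
# discard -> spatial smooth -> temporal low-pass -> z-score.

#' Discard initial timepoints
#'
#' Drops the first \code{nDiscard} volumes so the signal approaches steady
#' state; the remaining samples are unchanged.
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param nDiscard number of leading timepoints to drop (default 5).
#' @return a \linkS4class{BoldSeries} with t - nDiscard timepoints.
#' @export
discardInitial <- function(bold, nDiscard = 5L) {
  t <- nTimepoints(bold)
  if (nDiscard < 0L) stop("nDiscard must be >= 0")
  if (t <= nDiscard)
    stop(sprintf("cannot discard %d of %d timepoints", nDiscard, t))
  if (nDiscard == 0L) return(bold)
  boldSeries(bold@data[, , , (nDiscard + 1L):t, drop = FALSE], tr = bold@tr,
             affine = bold@affine, subjectId = bold@subjectId,
             ageGroup = bold@ageGroup)
}

.gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve the rows of a matrix with a symmetric kernel, mirror-reflecting at
# the boundaries (edge sample not repeated).
.convolveRowsReflect <- function(M, kern) {
  n <- nrow(M)
  r <- (length(kern) - 1L) %/% 2L
  if (r == 0L) return(M * kern)
  if (r >= n) stop("kernel wider than the volume axis")
  out <- matrix(0, n, ncol(M))
  base <- seq_len(n)
  for (j in seq_along(kern)) {
    idx <- base + (j - r - 1L)
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    out <- out + kern[j] * M[idx, , drop = FALSE]
  }
  out
}

.convolveAxis <- function(x, kern, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  M <- .convolveRowsReflect(matrix(xp, nrow = dp[1]), kern)
  aperm(array(M, dp), order(perm))
}

#' Spatial Gaussian smoothing of each timepoint
#'
#' Separable Gaussian convolution with per-axis sigma =
#' \code{fwhm / sqrt(8 log 2)} mm converted to voxel units from the grid
#' affine. Boundaries are mirror-reflected, so a spatially constant volume is
#' exactly preserved.
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param fwhmMm kernel full width at half maximum, in mm (default 3).
#' @return the smoothed \linkS4class{BoldSeries}.
#' @export
smoothSpatial <- function(bold, fwhmMm = 3) {
  if (fwhmMm < 0) stop("fwhm must be >= 0")
  if (fwhmMm == 0) return(bold)
  vox <- voxelSizes(bold)
  sigmaVox <- fwhmMm / sqrt(8 * log(2)) / vox
  x <- bold@data
  for (axis in 1:3) {
    kern <- .gaussKernel1d(sigmaVox[axis])
    if (length(kern) > 1L) x <- .convolveAxis(x, kern, axis)
  }
  boldSeries(x, tr = bold@tr, affine = bold@affine,
             subjectId = bold@subjectId, ageGroup = bold@ageGroup)
}

# Steady-state initial filter state for a unit step input (per unit of the
# first sample), so forward-backward passes start transient-free.
.lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[2:n]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# Single forward pass of an IIR filter along the rows of X (time x series),
# direct form II transposed, vectorized across columns. `zi` (if given) is
# the per-unit-input initial state, scaled by each column's first sample.
.iirFilterMatrix <- function(b, a, X, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- nrow(X); V <- ncol(X)
  Y <- matrix(0, n, V)
  Z <- if (is.null(zi)) matrix(0, nfilt - 1L, V)
       else zi %o% X[1L, ]
  for (i in seq_len(n)) {
    xi <- X[i, ]
    yi <- b[1] * xi + Z[1, ]
    if (nfilt > 2L)
      for (j in seq_len(nfilt - 2L))
        Z[j, ] <- b[j + 1L] * xi + Z[j + 1L, ] - a[j + 1L] * yi
    Z[nfilt - 1L, ] <- b[nfilt] * xi - a[nfilt] * yi
    Y[i, ] <- yi
  }
  Y
}

# Zero-phase (forward-backward) filtering along rows with odd-reflection
# padding at both ends to suppress edge transients.
.filtfiltMatrix <- function(b, a, X) {
  n <- nrow(X)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  head <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
    X[(pad + 1L):2L, , drop = FALSE]
  tail <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - pad), , drop = FALSE]
  Xp <- rbind(head, X, tail)
  zi <- .lfilterZi(b, a)
  Y <- .iirFilterMatrix(b, a, Xp, zi = zi)
  Y <- .iirFilterMatrix(b, a, Y[nrow(Y):1L, , drop = FALSE], zi = zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Temporal low-pass filtering
#'
#' 4th-order Butterworth low-pass (design via \code{signal::butter}) applied
#' forward-backward per voxel, so the filter is zero-phase and the series
#' length is preserved. The effective attenuation is the squared magnitude
#' response of the one-pass design.
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param cutoffHz low-pass cutoff in Hz (default 0.08); must be below the
#'   Nyquist frequency 1/(2 TR).
#' @param order filter order of the one-pass design (default 4).
#' @return the filtered \linkS4class{BoldSeries}.
#' @export
lowpassTemporal <- function(bold, cutoffHz = 0.08, order = 4L) {
  nyquist <- 1 / (2 * bold@tr)
  if (cutoffHz <= 0 || cutoffHz >= nyquist)
    stop(sprintf("cutoff %.4g Hz must lie in (0, Nyquist = %.4g Hz)",
                 cutoffHz, nyquist))
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  d <- dim(bold@data)
  X <- t(matrix(bold@data, nrow = prod(d[1:3])))  # time x voxels
  Y <- .filtfiltMatrix(bf$b, bf$a, X)
  boldSeries(array(t(Y), dim = d), tr = bold@tr, affine = bold@affine,
             subjectId = bold@subjectId, ageGroup = bold@ageGroup)
}

#' Voxel-wise z-scoring of the time series
#'
#' Centers and scales every voxel series to mean 0 and population SD 1
#' (denominator n; correlations are invariant to this choice). Constant
#' series inside the analysis mask are an error (their correlation is
#' undefined); constant series outside the mask are silently set to zero.
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param mask optional 3D logical array (or \linkS4class{LabelVolume},
#'   non-zero = in-mask) marking the voxels that take part in the analysis;
#'   by default all voxels are treated as in-mask.
#' @return the z-scored \linkS4class{BoldSeries}.
#' @export
zscoreTimeseries <- function(bold, mask = NULL) {
  d <- dim(bold@data)
  t <- d[4]
  X <- matrix(bold@data, nrow = prod(d[1:3]))  # voxels x time
  mu <- rowMeans(X)
  sd0 <- sqrt(rowMeans(X^2) - mu^2)
  inMask <- if (is.null(mask)) rep(TRUE, nrow(X)) else {
    m <- if (is(mask, "LabelVolume")) mask@data > 0L else mask
    as.vector(m)
  }
  const <- sd0 <= 1e-300
  nbad <- sum(const & inMask)
  if (nbad > 0L)
    stop(sprintf("%d constant in-mask voxel series cannot be z-scored", nbad))
  X <- (X - mu) / ifelse(const, 1, sd0)
  X[const, ] <- 0
  boldSeries(array(X, dim = d), tr = bold@tr, affine = bold@affine,
             subjectId = bold@subjectId, ageGroup = bold@ageGroup)
}

#' Full preprocessing chain in the fixed order
#'
#' discard -> spatial smooth -> temporal low-pass -> z-score. Any stage can
#' be disabled (nDiscard = 0, fwhmMm = 0, cutoffHz = NULL, zscore = FALSE).
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param nDiscard leading timepoints to drop.
#' @param fwhmMm Gaussian FWHM in mm.
#' @param cutoffHz low-pass cutoff in Hz, or NULL to skip.
#' @param zscore whether to z-score the series.
#' @param mask analysis mask forwarded to \code{\link{zscoreTimeseries}}.
#' @return the preprocessed \linkS4class{BoldSeries}.
#' @export
preprocessBold <- function(bold, nDiscard = 5L, fwhmMm = 3, cutoffHz = 0.08,
                           zscore = TRUE, mask = NULL) {
  out <- discardInitial(bold, nDiscard)
  out <- smoothSpatial(out, fwhmMm)
  if (!is.null(cutoffHz)) out <- lowpassTemporal(out, cutoffHz)
  if (zscore) out <- zscoreTimeseries(out, mask)
  out
}
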