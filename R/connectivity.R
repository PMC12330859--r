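# Per-voxel FC profiles to ROIs, partial-correlation lobe profiles for the
# WTA baseline, and Fisher-Z group merging.
#
# FC between a seed voxel and an ROI is the MEAN OF CORRELATIONS: Pearson r
# between the voxel and every ROI voxel, then averaged across the ROI. This
# differs from correlating with the ROI mean series; the latter is used only
# for ROI-ROI matrices (roiMeanSeries), where the definition is on averaged
# time series. Both orders are deliberately available.

# time x voxels matrix for the voxels selected by a logical/label 3D array
.seriesMatrix <- function(bold, which) {
  d <- dim(bold@data)
  idx <- if (is.logical(which)) which(which) else which
  X <- matrix(bold@data, nrow = prod(d[1:3]))
  t(X[idx, , drop = FALSE])
}

.maskIndices <- function(mask) {
  m <- if (is(mask, "LabelVolume")) mask@data > 0L else mask
  which(m)
}

#' Mean time series of an ROI
#'
#' Arithmetic mean across the ROI's voxels at each timepoint. This is the
#' "averaged time series" entering ROI-ROI connectivity; voxel-to-ROI FC uses
#' the mean-of-correlations order instead (see \code{\link{voxelRoiFC}}).
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param labels \linkS4class{LabelVolume} of ROI parcels.
#' @param roiId the ROI label.
#' @return numeric vector of length t.
#' @export
roiMeanSeries <- function(bold, labels, roiId) {
  assertSameGrid(bold, labels, "BOLD and label volumes")
  idx <- which(labels@data == roiId)
  if (!length(idx)) stop(sprintf("ROI %s is empty", roiId))
  rowMeans(.seriesMatrix(bold, idx))
}

#' Per-voxel FC profiles to every ROI
#'
#' For each seed voxel v and ROI r: the Pearson correlation between v's
#' series and every voxel series in r, averaged across the ROI (mean of
#' correlations). Any prior z-scoring leaves the result unchanged.
#'
#' @param bold a preprocessed \linkS4class{BoldSeries}.
#' @param seedMask \linkS4class{LabelVolume} (or logical array); non-zero =
#'   seed-structure voxel.
#' @param labels \linkS4class{LabelVolume} of ROI parcels.
#' @param roiset \linkS4class{RoiSet} fixing the profile axis order.
#' @return a \linkS4class{ProfileMap} on the pearson_r scale.
#' @export
voxelRoiFC <- function(bold, seedMask, labels, roiset) {
  assertSameGrid(bold, labels, "BOLD and label volumes")
  if (is(seedMask, "LabelVolume"))
    assertSameGrid(bold, seedMask, "BOLD and seed mask")
  seedIdx <- .maskIndices(seedMask)
  if (!length(seedIdx)) stop("seed mask is empty")
  seedMat <- .seriesMatrix(bold, seedIdx)
  roiIdx <- which(labels@data %in% roiset@ids)
  if (!length(roiIdx)) stop("no ROI voxels found for the given RoiSet")
  roiMat <- .seriesMatrix(bold, roiIdx)
  roiOf <- labels@data[roiIdx]
  vals <- .fcCore(seedMat, roiMat, roiOf, roiset@ids)
  new("ProfileMap", voxels = as.integer(seedIdx),
      values = pmin(pmax(vals, -1), 1), scale = "pearson_r",
      roiIds = roiset@ids, dims = dim(bold@data)[1:3])
}

# Mean-of-correlations FC: Pearson r between every seed column and every ROI
# column, then column-averaged per ROI id. seedMat/roiMat are time x voxels.
.fcCore <- function(seedMat, roiMat, roiOf, roiIds) {
  sdS <- apply(seedMat, 2L, stats::sd)
  sdR <- apply(roiMat, 2L, stats::sd)
  if (any(sdS == 0) || any(sdR == 0))
    stop(sprintf("%d in-mask voxel series have zero variance",
                 sum(sdS == 0) + sum(sdR == 0)))
  r <- stats::cor(seedMat, roiMat)
  vals <- vapply(roiIds, function(id) {
    cols <- roiOf == id
    if (!any(cols)) stop(sprintf("ROI %d is empty", id))
    rowMeans(r[, cols, drop = FALSE])
  }, numeric(nrow(r)))
  matrix(vals, nrow = nrow(r))
}

#' Fisher-Z transform of a correlation profile map
#'
#' z = atanh(r) = 0.5 log((1+r)/(1-r)), elementwise; |r| is clipped to
#' 1 - 1e-7 first so degenerate (|r| = 1) inputs stay finite. Clipping is
#' reported via a message.
#'
#' @param profiles a \linkS4class{ProfileMap} on the pearson_r scale.
#' @return a \linkS4class{ProfileMap} on the fisher_z scale.
#' @export
fisherZ <- function(profiles) {
  if (profiles@scale != "pearson_r")
    stop("fisherZ expects a pearson_r ProfileMap")
  r <- profiles@values
  lim <- 1 - 1e-7
  nclip <- sum(abs(r) > lim)
  if (nclip > 0L)
    message(sprintf("fisherZ: clipped %d correlation(s) at |r| = 1 - 1e-7",
                    nclip))
  z <- atanh(pmin(pmax(r, -lim), lim))
  methods::initialize(profiles, values = z, scale = "fisher_z")
}

#' Group-average Fisher-Z profile maps
#'
#' Voxel- and ROI-wise (optionally weighted) arithmetic mean of several
#' subjects' Fisher-Z profile maps sharing one voxel list and ROI axis.
#'
#' @param profileList list of \linkS4class{ProfileMap}s on the fisher_z
#'   scale.
#' @param weights optional per-subject weights (default equal).
#' @return the averaged \linkS4class{ProfileMap}.
#' @export
groupAverageProfiles <- function(profileList, weights = NULL) {
  stopifnot(length(profileList) >= 1L)
  ref <- profileList[[1]]
  for (p in profileList) {
    if (p@scale != "fisher_z")
      stop("group averaging expects fisher_z profiles")
    if (!identical(p@voxels, ref@voxels) || !identical(p@roiIds, ref@roiIds))
      stop("profile maps do not share voxel list and ROI axis")
  }
  if (is.null(weights)) weights <- rep(1, length(profileList))
  if (length(weights) != length(profileList))
    stop("one weight per profile map required")
  w <- weights / sum(weights)
  acc <- ref@values * w[1]
  for (i in seq_along(profileList)[-1])
    acc <- acc + profileList[[i]]@values * w[i]
  methods::initialize(ref, values = acc)
}

#' Partial-correlation profiles to the five merged lobes
#'
#' For each seed voxel and each lobe (temporal, parietal, frontal, occipital,
#' limbic): the correlation between the voxel series and the lobe's mean
#' series after both are residualized on the other four lobes' mean series
#' (with intercept). Input to the winner-takes-all baseline.
#'
#' @param bold a preprocessed \linkS4class{BoldSeries}.
#' @param seedMask seed-structure mask.
#' @param labels \linkS4class{LabelVolume} of ROI parcels.
#' @param roiset \linkS4class{RoiSet} whose lobe groups define the merging.
#' @return a \linkS4class{LobeProfileMap}.
#' @export
partialCorrLobes <- function(bold, seedMask, labels, roiset) {
  assertSameGrid(bold, labels, "BOLD and label volumes")
  lobes <- lobeGroups(roiset)
  lobes <- lobes[vapply(lobes, length, 1L) > 0L]
  if (length(lobes) < 2L)
    stop("need ROIs in at least 2 lobe groups for partial correlation")
  L <- vapply(lobes, function(idset) {
    idx <- which(labels@data %in% idset)
    if (!length(idx)) stop("empty lobe voxel set")
    rowMeans(.seriesMatrix(bold, idx))
  }, numeric(dim(bold@data)[4]))
  if (qr(cbind(1, L))$rank < ncol(L) + 1L)
    stop("lobe mean series are rank-deficient; partial correlation undefined")
  seedIdx <- .maskIndices(seedMask)
  seedMat <- .seriesMatrix(bold, seedIdx)
  vals <- matrix(NA_real_, length(seedIdx), ncol(L))
  for (l in seq_len(ncol(L))) {
    D <- cbind(1, L[, -l, drop = FALSE])
    qrD <- qr(D)
    rl <- qr.resid(qrD, L[, l])
    rv <- qr.resid(qrD, seedMat)
    vals[, l] <- drop(stats::cor(rl, rv))
  }
  new("LobeProfileMap", voxels = as.integer(seedIdx),
      values = pmin(pmax(vals, -1), 1), lobes = names(lobes),
      dims = dim(bold@data)[1:3])
}

# Average the L/R columns of a profile-value matrix over bilateral pairs.
# Midline ROIs are kept unmerged. Returns values plus per-column labels.
.mergeBilateral <- function(values, roiIds, roiset) {
  pairs <- roiset@pairs
  out <- NULL
  labels <- character(0)
  used <- integer(0)
  for (p in seq_len(nrow(pairs))) {
    li <- match(pairs[p, 1], roiIds); ri <- match(pairs[p, 2], roiIds)
    if (is.na(li) || is.na(ri)) next
    out <- cbind(out, (values[, li] + values[, ri]) / 2)
    nm <- roiset@names[match(pairs[p, 1], roiset@ids)]
    labels <- c(labels, sub(" ?L$", "", nm))
    used <- c(used, li, ri)
  }
  mid <- setdiff(seq_along(roiIds), used)
  if (length(mid)) {
    out <- cbind(out, values[, mid, drop = FALSE])
    labels <- c(labels, roiset@names[match(roiIds[mid], roiset@ids)])
  }
  colnames(out) <- labels
  out
}
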