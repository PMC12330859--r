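# Synthetic multi-subject BOLD phantom with planted, bilaterally symmetric
# seed clusters. Each planted cluster has a known non-negative mixing-weight
# row over the ROI sources, so Pearson FC profiles of its voxels recover that
# row (up to sampling noise) and every downstream stage is testable without
# any real data.

#' Specification of a synthetic BOLD phantom
#'
#' @slot dims 3D grid shape.
#' @slot nRois number of ROI parcels (must be even: bilateral pairs).
#' @slot kTrue number of planted clusters per hemispheric seed blob.
#' @slot profileMatrix kTrue x nRois non-negative mixing weights; row c is the
#'   weight of each ROI source in the series of cluster-c voxels.
#' @slot nTimepoints,tr series length and repetition time (s).
#' @slot noiseSd standard deviation of the additive white voxel noise, in
#'   units of the unit-variance ROI source signals.
#' @slot borderMixWidth width (voxels) of the linear blending zone across
#'   planted cluster borders; 0 disables mixing.
#' @slot symmetry when TRUE the planted parcellation is mirror-symmetric
#'   across the mid-sagittal grid plane.
#' @slot sharedSources when TRUE the two members of each bilateral ROI pair
#'   share one source signal (homotopic connectivity); when FALSE every ROI
#'   has an independent source.
#' @slot minCosDist minimum pairwise cosine distance between profile rows.
#' @slot seed integer seed fixing the anatomy.
#'
#' @export
setClass("PhantomSpec",
  representation(dims = "integer", nRois = "integer", kTrue = "integer",
                 profileMatrix = "matrix", nTimepoints = "integer",
                 tr = "numeric", noiseSd = "numeric",
                 borderMixWidth = "numeric", symmetry = "logical",
                 sharedSources = "logical", minCosDist = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  w <- object@profileMatrix
  if (nrow(w) != object@kTrue || ncol(w) != object@nRois)
    msg <- c(msg, "profileMatrix must be kTrue x nRois")
  if (any(w < 0)) msg <- c(msg, "mixing weights must be non-negative")
  if (any(rowSums(w > 0) == 0L))
    msg <- c(msg, "each profile row needs at least one positive weight")
  if (object@nRois %% 2L != 0L)
    msg <- c(msg, "nRois must be even (bilateral pairs)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (nrow(w) > 1L) {
    wn <- w / sqrt(rowSums(w^2))
    cs <- wn %*% t(wn)
    dmin <- min(1 - cs[upper.tri(cs)])
    if (dmin < object@minCosDist - 1e-12)
      msg <- c(msg, sprintf(
        "profile rows too collinear: min cosine distance %.3f < %.3f",
        dmin, object@minCosDist))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid, %d ROIs, k_true=%d, t=%d, noise_sd=%.2g, symmetry=%s\n",
              paste(object@dims, collapse = "x"), object@nRois, object@kTrue,
              object@nTimepoints, object@noiseSd, object@symmetry))
})

#' Default mixing-weight matrix for a phantom
#'
#' Each planted cluster loads weight 1 on one bilateral ROI pair (both
#' members) and a small baseline weight on every other ROI, giving
#' well-separated but non-orthogonal profile directions. Optionally one
#' cluster is given a balanced mix of two pairs: a "pulvinar analogue" whose
#' profile is dominated by two lobes at once, the situation where
#' winner-takes-all assignment breaks down but profile clustering does not.
#'
#' @param kTrue number of clusters.
#' @param nRois number of ROIs (even; pairs are columns (2i-1, 2i)).
#' @param base baseline weight on non-dominant ROIs.
#' @param mixedCluster optional cluster index to make a two-pair mix; give
#'   it pairs no other cluster dominates (e.g. pairs 5 and 6 with
#'   \code{nRois = 12} and four single-pair clusters) so the mix is a new
#'   direction, not a copy of existing ones.
#' @param mixedPairs the two pair indices the mixed cluster loads on.
#' @return kTrue x nRois weight matrix.
#' @export
phantomProfileMatrix <- function(kTrue, nRois, base = 0.05,
                                 mixedCluster = NULL, mixedPairs = c(5L, 6L)) {
  nPairs <- nRois %/% 2L
  w <- matrix(base, kTrue, nRois)
  for (c in seq_len(kTrue)) {
    p <- ((c - 1L) %% nPairs) + 1L
    w[c, c(2L * p - 1L, 2L * p)] <- 1
  }
  if (!is.null(mixedCluster)) {
    w[mixedCluster, ] <- base
    for (p in mixedPairs) w[mixedCluster, c(2L * p - 1L, 2L * p)] <- 1
  }
  w
}

#' Construct a phantom specification
#'
#' Defaults describe the reference phantom used throughout the test-bench:
#' a 24^3 grid hosting 10 ROI parcels (5 bilateral pairs, one per lobe),
#' 5 planted clusters per hemisphere, 600 timepoints at TR = 0.392 s, unit
#' source-to-noise ratio and a 1-voxel border blending zone.
#'
#' @param dims,nRois,kTrue,nTimepoints,tr,noiseSd,borderMixWidth,symmetry,seed
#'   see \linkS4class{PhantomSpec}.
#' @param profileMatrix mixing weights; default
#'   \code{phantomProfileMatrix(kTrue, nRois)}.
#' @param minCosDist minimum pairwise cosine distance between rows.
#' @return a validated \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(dims = c(24L, 24L, 24L), nRois = 10L, kTrue = 5L,
                        profileMatrix = phantomProfileMatrix(kTrue, nRois),
                        nTimepoints = 600L, tr = 0.392, noiseSd = 1,
                        borderMixWidth = 1, symmetry = TRUE,
                        sharedSources = FALSE, minCosDist = 0.2, seed = 1L) {
  new("PhantomSpec", dims = as.integer(dims), nRois = as.integer(nRois),
      kTrue = as.integer(kTrue), profileMatrix = profileMatrix,
      nTimepoints = as.integer(nTimepoints), tr = tr, noiseSd = noiseSd,
      borderMixWidth = borderMixWidth, symmetry = symmetry,
      sharedSources = sharedSources, minCosDist = minCosDist,
      seed = as.integer(seed))
}

#' Ground truth of a phantom: anatomy, planted labels, mixing weights
#'
#' @slot seedMask \linkS4class{LabelVolume}: 1 = left blob, 2 = right blob.
#' @slot trueParcellation \linkS4class{LabelVolume} of planted cluster labels.
#' @slot roiParcels \linkS4class{LabelVolume} of the ROI parcels.
#' @slot roiset the matching \linkS4class{RoiSet}.
#' @slot profileMatrix copy of the planted mixing weights.
#' @slot voxels linear indices of the seed voxels.
#' @slot weights V x nRois effective per-voxel weights (border-blended).
#' @slot borderVoxels linear indices of voxels inside the blending zone.
#'
#' @export
setClass("PhantomTruth",
  representation(seedMask = "LabelVolume", trueParcellation = "LabelVolume",
                 roiParcels = "LabelVolume", roiset = "RoiSet",
                 profileMatrix = "matrix", voxels = "integer",
                 weights = "matrix", borderVoxels = "integer"))

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d seed voxels (%d border), %d clusters, %d ROIs\n",
              length(object@voxels), length(object@borderVoxels),
              max(object@trueParcellation@data),
              nrow(object@roiset@pairs) * 2L + sum(object@roiset@hemisphere == "mid")))
})

.lin3 <- function(d, i, j, k) i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)

.boxIndices <- function(d, xr, yr, zr) {
  g <- expand.grid(i = xr, j = yr, k = zr)
  .lin3(d, g$i, g$j, g$k)
}

#' Build the phantom anatomy and planted ground truth
#'
#' ROI parcels are placed as boxes along the lateral faces of the grid (left
#' members at low x, right members mirrored), the seed structure is two
#' mirror-placed central blobs, and each blob is split into kTrue contiguous
#' slabs along z. With \code{symmetry = TRUE} the planted parcellation maps
#' onto itself under reflection across the mid-sagittal plane; otherwise the
#' right-hemisphere labels are cyclically shifted so it does not. Voxels
#' within \code{borderMixWidth} of another cluster get linearly blended
#' mixing weights and are flagged as border voxels. Deterministic given the
#' spec (the layout is purely geometric).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param voxelSize isotropic voxel size in mm.
#' @return a \linkS4class{PhantomTruth}
#' @export
makePhantomAnatomy <- function(spec, voxelSize = 2) {
  d <- spec@dims
  nPairs <- spec@nRois %/% 2L
  if (d[1] %% 2L != 0L)
    stop("first grid dimension must be even (mid-sagittal plane between voxels)")
  affine <- diag(c(rep(voxelSize, 3), 1))

  # ROI parcels: boxes at the left face, tiled along z; mirrored to the right.
  zlo <- 3L; zhi <- d[3] - 2L
  if (zhi - zlo + 1L < 2L * nPairs)
    stop(sprintf("infeasible spec: grid too small to host %d ROI pairs", nPairs))
  zb <- floor(seq(zlo, zhi + 1L, length.out = nPairs + 1L))
  ylo <- max(3L, ceiling(d[2] * 0.2)); yhi <- min(d[2] - 2L, floor(d[2] * 0.8))
  roi <- array(0L, d)
  for (p in seq_len(nPairs)) {
    zr <- zb[p]:(zb[p + 1L] - 1L)
    # one-voxel gap between stacked parcels limits smoothing cross-talk
    if (length(zr) >= 3L) zr <- zr[-length(zr)]
    left <- .boxIndices(d, 1:2, ylo:yhi, zr)
    roi[left] <- 2L * p - 1L
  }
  mirror <- mirrorIndexMap(d, 1L)
  leftIdx <- which(roi > 0L)
  roi[mirror[leftIdx]] <- roi[leftIdx] + 1L

  lobes <- c("temporal", "parietal", "frontal", "occipital", "limbic")
  pairLobe <- lobes[((seq_len(nPairs) - 1L) %% 5L) + 1L]
  ids <- seq_len(spec@nRois)
  rs <- roiSet(ids = ids,
               names = sprintf("roi%02d%s", ids, c("L", "R")[(ids %% 2L == 0L) + 1L]),
               hemisphere = c("L", "R")[((ids + 1L) %% 2L) + 1L],
               lobe = rep(pairLobe, each = 2L),
               pair = ifelse(ids %% 2L == 1L, ids + 1L, ids - 1L))
  roiLut <- data.frame(id = rs@ids, name = rs@names, hemisphere = rs@hemisphere,
                       lobe_group = rs@lobe, stringsAsFactors = FALSE)

  # Seed blobs: a central box per hemisphere, clear of the ROI shell.
  xlo <- 4L; xhi <- d[1] %/% 2L - 2L
  sylo <- max(4L, ceiling(d[2] * 0.28)); syhi <- min(d[2] - 3L, floor(d[2] * 0.75))
  szlo <- 5L; szhi <- d[3] - 4L
  nz <- szhi - szlo + 1L
  blobVox <- (xhi - xlo + 1L) * (syhi - sylo + 1L) * nz
  if (xhi < xlo || syhi < sylo || nz < spec@kTrue ||
      blobVox < spec@kTrue * 30L)
    stop(sprintf(
      "infeasible spec: cannot host %d clusters of >= 30 voxels per hemisphere on a %s grid",
      spec@kTrue, paste(d, collapse = "x")))

  seedMask <- array(0L, d)
  parc <- array(0L, d)
  zcut <- floor(seq(szlo, szhi + 1L, length.out = spec@kTrue + 1L))
  for (c in seq_len(spec@kTrue)) {
    zr <- zcut[c]:(zcut[c + 1L] - 1L)
    li <- .boxIndices(d, xlo:xhi, sylo:syhi, zr)
    seedMask[li] <- 1L
    parc[li] <- c
  }
  leftSeed <- which(seedMask == 1L)
  seedMask[mirror[leftSeed]] <- 2L
  rightLab <- if (spec@symmetry) parc[leftSeed]
              else (parc[leftSeed] %% spec@kTrue) + 1L
  parc[mirror[leftSeed]] <- rightLab

  voxels <- which(seedMask > 0L)
  labs <- parc[voxels]

  # Border blending: weight of the nearest other cluster ramps linearly from
  # 0.5 at the border (distance 1 voxel) to 0 at distance 1 + borderMixWidth.
  W <- spec@profileMatrix[labs, , drop = FALSE]
  border <- integer(0)
  if (spec@borderMixWidth > 0) {
    coords <- arrayInd(voxels, d)
    for (c in seq_len(spec@kTrue)) {
      inC <- labs == c
      if (!any(inC) || all(inC)) next
      A <- coords[inC, , drop = FALSE]
      B <- coords[!inC, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      nearest <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(A)), nearest)]))
      alpha <- 0.5 * pmax(0, (spec@borderMixWidth + 1 - dmin) / spec@borderMixWidth)
      mix <- which(alpha > 0)
      if (length(mix)) {
        rows <- which(inC)[mix]
        otherLab <- labs[!inC][nearest[mix]]
        W[rows, ] <- (1 - alpha[mix]) * spec@profileMatrix[labs[rows], , drop = FALSE] +
                     alpha[mix] * spec@profileMatrix[otherLab, , drop = FALSE]
        border <- c(border, voxels[rows])
      }
    }
    border <- sort(unique(border))
  }

  seedLut <- data.frame(id = 1:2, name = c("seed_left", "seed_right"),
                        hemisphere = c("L", "R"), lobe_group = "none",
                        stringsAsFactors = FALSE)
  parcLut <- data.frame(id = seq_len(spec@kTrue),
                        name = sprintf("cluster%d", seq_len(spec@kTrue)),
                        hemisphere = "mid", lobe_group = "none",
                        stringsAsFactors = FALSE)
  new("PhantomTruth",
      seedMask = labelVolume(seedMask, lut = seedLut, affine = affine),
      trueParcellation = labelVolume(parc, lut = parcLut, affine = affine),
      roiParcels = labelVolume(roi, lut = roiLut, affine = affine),
      roiset = rs, profileMatrix = spec@profileMatrix,
      voxels = as.integer(voxels), weights = W,
      borderVoxels = as.integer(border))
}

#' Simulate one subject's BOLD series from a phantom truth
#'
#' ROI source signals are independent unit-variance white Gaussian series.
#' Every voxel receives independent N(0, noiseSd) noise; ROI voxels add their
#' parcel's source, seed voxels add the weighted source mixture of their
#' (border-blended) cluster weights. Deterministic given `subjectSeed`.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param spec the \linkS4class{PhantomSpec} used to build it.
#' @param subjectSeed integer seed for this subject.
#' @param subjectId,ageGroup metadata attached to the result.
#' @return a \linkS4class{BoldSeries}
#' @export
simulateSubject <- function(truth, spec, subjectSeed,
                            subjectId = sprintf("sub-%06d", subjectSeed),
                            ageGroup = "group") {
  d <- spec@dims
  t <- spec@nTimepoints
  withSeed(subjectSeed, {
    S <- matrix(stats::rnorm(spec@nRois * t), spec@nRois, t)
    if (isTRUE(spec@sharedSources)) {
      for (p in seq_len(spec@nRois %/% 2L)) S[2L * p, ] <- S[2L * p - 1L, ]
    }
    X <- matrix(stats::rnorm(prod(d) * t, sd = max(spec@noiseSd, 0)), prod(d), t)
    if (spec@noiseSd == 0) X[] <- 0
    roiArr <- truth@roiParcels@data
    for (r in seq_len(spec@nRois)) {
      idx <- which(roiArr == r)
      X[idx, ] <- X[idx, ] + matrix(S[r, ], length(idx), t, byrow = TRUE)
    }
    X[truth@voxels, ] <- X[truth@voxels, ] + truth@weights %*% S
    boldSeries(array(X, dim = c(d, t)), tr = spec@tr,
               affine = truth@seedMask@affine,
               subjectId = subjectId, ageGroup = ageGroup)
  })
}

#' Simulate a cohort of phantom subjects
#'
#' Per-subject seeds are derived from `cohortSeed` by a fixed fold, so any
#' single subject can be regenerated in isolation.
#'
#' @param truth,spec phantom truth and spec.
#' @param nSubjects number of subjects (>= 1).
#' @param cohortSeed master seed.
#' @param ageGroups age-group keys recycled across subjects (default one
#'   group).
#' @return list with `bold` (list of \linkS4class{BoldSeries}) and `metadata`
#'   (data.frame: subjectId, ageGroup, seed).
#' @export
simulateCohort <- function(truth, spec, nSubjects, cohortSeed,
                           ageGroups = "group") {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  grp <- rep_len(as.character(ageGroups), nSubjects)
  ids <- sprintf("sub-%03d", seq_len(nSubjects))
  seeds <- vapply(seq_len(nSubjects), function(i) childSeed(cohortSeed, i), 1L)
  bold <- lapply(seq_len(nSubjects), function(i)
    simulateSubject(truth, spec, seeds[i], subjectId = ids[i],
                    ageGroup = grp[i]))
  list(bold = bold,
       metadata = data.frame(subjectId = ids, ageGroup = grp, seed = seeds,
                             stringsAsFactors = FALSE))
}

#' Write a phantom (anatomy + cohort) to a directory
#'
#' Writes per-subject BOLD NIfTIs, the anatomy label volumes with their luts,
#' and the cohort metadata TSV.
#'
#' @param truth,spec phantom truth and spec.
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @export
writePhantom <- function(truth, spec, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeParcellation(truth@seedMask, file.path(dir, "seed_mask.nii.gz"))
  writeParcellation(truth@trueParcellation,
                    file.path(dir, "true_parcellation.nii.gz"))
  writeParcellation(truth@roiParcels, file.path(dir, "roi_parcels.nii.gz"))
  writeRoiConfig(truth@roiset, file.path(dir, "roiset.yaml"))
  for (i in seq_along(cohort$bold)) {
    b <- cohort$bold[[i]]
    writeBold(b, file.path(dir, sprintf("%s_bold.nii.gz", b@subjectId)))
  }
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
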