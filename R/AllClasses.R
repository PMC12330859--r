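#' @import methods
NULL

#' One subject's 4D BOLD acquisition
#'
#' Container for a single subject's blood-oxygenation-level-dependent (BOLD)
#' time series on a regular 3D grid, together with the repetition time and the
#' grid-to-world affine. All volumes taking part in one analysis are assumed to
#' live on the same grid (no registration is performed by this package).
#'
#' @slot data 4D numeric array (x, y, z, t); stored as doubles.
#' @slot tr repetition time in seconds.
#' @slot affine 4x4 grid-to-world affine; voxel sizes are the column norms of
#'   its upper-left 3x3 block.
#' @slot subjectId subject identifier.
#' @slot ageGroup opaque age-group key used to group subjects.
#'
#' @export
setClass("BoldSeries",
  representation(data = "array", tr = "numeric", affine = "matrix",
                 subjectId = "character", ageGroup = "character"))

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else if (dim(object@data)[4] < 2L)
    msg <- c(msg, "need at least 2 timepoints")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  nbad <- sum(!is.finite(object@data))
  if (nbad > 0L)
    msg <- c(msg, sprintf("%d non-finite voxel value(s) in BOLD data", nbad))
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Integer label volume with lookup table
#'
#' A 3D non-negative integer grid where 0 is reserved for background, plus a
#' lookup table (lut) describing every non-zero label: its name, hemisphere
#' (\code{"L"}, \code{"R"} or \code{"mid"}) and lobe group (\code{"temporal"},
#' \code{"parietal"}, \code{"frontal"}, \code{"occipital"}, \code{"limbic"} or
#' \code{"none"}). Used for ROI parcels, seed-structure masks and parcellation
#' outputs alike.
#'
#' @slot data 3D integer array.
#' @slot affine 4x4 grid-to-world affine.
#' @slot lut data.frame with columns \code{id}, \code{name}, \code{hemisphere},
#'   \code{lobe_group}.
#'
#' @export
setClass("LabelVolume",
  representation(data = "array", affine = "matrix", lut = "data.frame"))

.hemis <- c("L", "R", "mid")
.lobes <- c("temporal", "parietal", "frontal", "occipital", "limbic", "none")

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!is.integer(object@data))
    msg <- c(msg, "data must be stored as integers")
  else if (any(object@data < 0L))
    msg <- c(msg, "labels must be non-negative (0 is background)")
  need <- c("id", "name", "hemisphere", "lobe_group")
  if (!all(need %in% names(object@lut)))
    msg <- c(msg, sprintf("lut must have columns %s", paste(need, collapse = ", ")))
  else {
    present <- setdiff(unique(as.vector(object@data)), 0L)
    missing <- setdiff(present, object@lut$id)
    if (length(missing))
      msg <- c(msg, sprintf("label(s) %s present in volume but absent from lut",
                            paste(sort(missing), collapse = ", ")))
    if (anyDuplicated(object@lut$id))
      msg <- c(msg, "duplicate ids in lut")
    if (!all(object@lut$hemisphere %in% .hemis))
      msg <- c(msg, "lut hemisphere must be one of L, R, mid")
    if (!all(object@lut$lobe_group %in% .lobes))
      msg <- c(msg, sprintf("lut lobe_group must be one of %s",
                            paste(.lobes, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Ordered ROI set defining the connectivity-profile axis
#'
#' Fixes the order of the R regions of interest that form the axis of every
#' connectivity profile, the left/right bilateral pairing used for bilateral
#' merging, and the grouping of ROIs into lobes used by the winner-takes-all
#' baseline. Midline ROIs (hemisphere \code{"mid"}) belong to no pair and are
#' excluded from bilateral merging.
#'
#' @slot ids ordered integer ROI ids (the profile axis).
#' @slot names ROI names, parallel to \code{ids}.
#' @slot hemisphere hemisphere per ROI ("L", "R" or "mid").
#' @slot lobe lobe group per ROI.
#' @slot pairs 2-column integer matrix of (left id, right id) bilateral pairs.
#'
#' @export
setClass("RoiSet",
  representation(ids = "integer", names = "character", hemisphere = "character",
                 lobe = "character", pairs = "matrix"))

setValidity("RoiSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate ROI ids")
  if (length(object@names) != n || length(object@hemisphere) != n ||
      length(object@lobe) != n)
    msg <- c(msg, "names, hemisphere and lobe must parallel ids")
  if (!all(object@hemisphere %in% .hemis))
    msg <- c(msg, "hemisphere must be one of L, R, mid")
  if (!all(object@lobe %in% .lobes))
    msg <- c(msg, "unknown lobe group")
  p <- object@pairs
  if (ncol(p) != 2L)
    msg <- c(msg, "pairs must have two columns")
  else if (nrow(p)) {
    if (!all(p %in% object@ids))
      msg <- c(msg, "pair member not among ROI ids")
    else {
      hemi <- object@hemisphere[match(as.vector(p), object@ids)]
      hemi <- matrix(hemi, ncol = 2L)
      if (!all(hemi[, 1] == "L" & hemi[, 2] == "R"))
        msg <- c(msg, "each pair must be (left id, right id)")
      if (anyDuplicated(as.vector(p)))
        msg <- c(msg, "an ROI appears in more than one pair")
      lhs <- object@lobe[match(p[, 1], object@ids)]
      rhs <- object@lobe[match(p[, 2], object@ids)]
      if (!all(lhs == rhs))
        msg <- c(msg, "paired ROIs must share a lobe group")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-voxel functional connectivity profiles
#'
#' For each voxel of the seed structure, its functional connectivity (FC) to
#' each of the R ROIs: Pearson r, or Fisher-Z transformed values. Voxels are
#' addressed by linear index into the 3D grid whose dimensions are recorded in
#' \code{dims}.
#'
#' @slot voxels integer vector of linear voxel indices (seed-structure voxels).
#' @slot values V x R numeric matrix of FC values.
#' @slot scale \code{"pearson_r"} or \code{"fisher_z"}.
#' @slot roiIds integer ROI ids labelling the columns, in RoiSet order.
#' @slot dims dimensions of the underlying 3D grid.
#'
#' @export
setClass("ProfileMap",
  representation(voxels = "integer", values = "matrix", scale = "character",
                 roiIds = "integer", dims = "integer"))

setValidity("ProfileMap", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@voxels))
    msg <- c(msg, "one profile row per voxel required")
  if (ncol(object@values) != length(object@roiIds))
    msg <- c(msg, "one column per ROI required")
  if (!object@scale %in% c("pearson_r", "fisher_z"))
    msg <- c(msg, "scale must be pearson_r or fisher_z")
  if (object@scale == "pearson_r" &&
      length(object@values) && max(abs(object@values)) > 1 + 1e-8)
    msg <- c(msg, "pearson_r values must lie in [-1, 1]")
  if (object@scale == "fisher_z" && any(!is.finite(object@values)))
    msg <- c(msg, "fisher_z values must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-voxel partial-correlation profiles to the five lobes
#'
#' For the winner-takes-all baseline: each seed voxel's partial correlation to
#' each of the five merged lobes (temporal, parietal, frontal, occipital,
#' limbic), controlling for the other four.
#'
#' @slot voxels integer linear voxel indices.
#' @slot values V x 5 matrix of partial correlations.
#' @slot lobes lobe names labelling the columns.
#' @slot dims dimensions of the underlying 3D grid.
#'
#' @export
setClass("LobeProfileMap",
  representation(voxels = "integer", values = "matrix", lobes = "character",
                 dims = "integer"))

setValidity("LobeProfileMap", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@voxels))
    msg <- c(msg, "one profile row per voxel required")
  if (ncol(object@values) != length(object@lobes))
    msg <- c(msg, "one column per lobe required")
  if (length(object@values) && max(abs(object@values)) > 1 + 1e-8)
    msg <- c(msg, "partial correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' A labelled parcellation of the seed structure
#'
#' Cluster labels 1..k on the seed-structure voxels (0 elsewhere), with
#' provenance: the method that produced it, the random seed, and the bootstrap
#' replicate id where applicable.
#'
#' @slot data 3D integer array of labels (0 = background / unassigned).
#' @slot affine 4x4 grid-to-world affine.
#' @slot k number of clusters.
#' @slot method one of \code{"knit"}, \code{"wta"}, \code{"consensus"}.
#' @slot seed integer random seed used (NA where not applicable).
#' @slot bootstrapId bootstrap replicate id (NA outside ensembles).
#'
#' @export
setClass("Parcellation",
  representation(data = "array", affine = "matrix", k = "integer",
                 method = "character", seed = "integer", bootstrapId = "integer"))

setValidity("Parcellation", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!is.integer(object@data))
    msg <- c(msg, "labels must be integers")
  else if (any(object@data < 0L) || any(object@data > object@k))
    msg <- c(msg, "labels must lie in {0, 1, ..., k}")
  if (!object@method %in% c("knit", "wta", "consensus"))
    msg <- c(msg, "method must be knit, wta or consensus")
  if (length(msg)) msg else TRUE
})

#' Consensus parcellation with per-voxel vote counts
#'
#' The result of a majority vote across a label-matched bootstrap ensemble.
#' Retains, for every seed voxel, the number of ensemble members that voted
#' for each label; the uncertainty map is derived from these counts.
#'
#' @slot voxels integer linear indices of seed voxels (rows of voteCounts).
#' @slot voteCounts V x k matrix of per-label vote counts.
#' @slot nTotal ensemble size the votes were drawn from.
#'
#' @export
setClass("ConsensusParcellation", contains = "Parcellation",
  representation(voxels = "integer", voteCounts = "matrix", nTotal = "integer"))

#' Ordered collection of label-matched bootstrap parcellations
#'
#' @slot members list of \linkS4class{Parcellation}, all label-matched to a
#'   common reference and sharing the seed mask and k.
#' @slot scheme \code{"subjects"} or \code{"timepoints"}.
#' @slot fraction resampling fraction in (0, 1].
#' @slot subsets list of integer vectors: the subject (or timepoint) subset
#'   each member was built from.
#' @slot memberProfiles list of the group-averaged \linkS4class{ProfileMap}
#'   each member was clustered on (used by downstream cluster profiling).
#' @slot masterSeed the master seed all member seeds were derived from.
#'
#' @export
setClass("ParcellationEnsemble",
  representation(members = "list", scheme = "character", fraction = "numeric",
                 subsets = "list", memberProfiles = "list", masterSeed = "integer"))

setValidity("ParcellationEnsemble", function(object) {
  msg <- character()
  if (!length(object@members))
    msg <- c(msg, "ensemble must have at least one member")
  if (!all(vapply(object@members, is, TRUE, "Parcellation")))
    msg <- c(msg, "members must be Parcellation objects")
  if (!object@scheme %in% c("subjects", "timepoints"))
    msg <- c(msg, "scheme must be subjects or timepoints")
  if (object@fraction <= 0 || object@fraction > 1)
    msg <- c(msg, "fraction must lie in (0, 1]")
  if (length(object@members) > 1L) {
    k0 <- object@members[[1]]@k
    m0 <- object@members[[1]]@data > 0L
    for (m in object@members[-1]) {
      if (m@k != k0) { msg <- c(msg, "members must share k"); break }
      if (!identical(m@data > 0L, m0)) {
        msg <- c(msg, "members must share the seed mask"); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Voxel-wise uncertainty of a consensus parcellation
#'
#' U(v) = 1 - N_c*(v)/N_total, the complement of the majority-label proportion
#' across bootstrap members: 0 where all members agree, at most 1 - 1/N_total.
#' The scalar summary uBar is the sum of U(v) over all seed voxels divided by
#' the number of subjects in the group, so groups of different sizes are
#' comparable.
#'
#' @slot u 3D numeric array of U(v) (0 outside the seed mask).
#' @slot voxels integer linear indices of seed voxels.
#' @slot uBar normalized average uncertainty.
#' @slot nTotal number of bootstraps.
#' @slot nSubjectsNorm subject count used to normalize uBar.
#'
#' @export
setClass("UncertaintyMap",
  representation(u = "array", voxels = "integer", uBar = "numeric",
                 nTotal = "integer", nSubjectsNorm = "integer"))

setValidity("UncertaintyMap", function(object) {
  msg <- character()
  uu <- object@u[object@voxels]
  if (length(uu) && (min(uu) < 0 || max(uu) > 1 - 1 / object@nTotal + 1e-12))
    msg <- c(msg, "U(v) must lie in [0, 1 - 1/N_total]")
  if (length(msg)) msg else TRUE
})
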