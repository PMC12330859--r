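# Post-hoc cluster characterization and across-age developmental metrics.

#' Per-cluster connectivity profiles with significance flags
#'
#' For each ROI: the median FC over the cluster's voxels within each
#' bootstrap member, averaged across members; then z-scored across the ROI
#' axis per cluster. ROIs with z above +1 are flagged significantly
#' connected, below -1 significantly disconnected. Optionally the L/R ROI
#' columns are bilaterally merged (averaged) before the median.
#'
#' @param ensemble a matched \linkS4class{ParcellationEnsemble} carrying its
#'   member profiles.
#' @param roiset the \linkS4class{RoiSet}.
#' @param bilateralMerge merge L/R ROI pairs before profiling (default
#'   FALSE).
#' @param zThreshold significance threshold on the z-scored profile
#'   (default 1).
#' @return list with `median` (k x R matrix, mean-of-medians FC), `z`
#'   (z-scored across ROIs), `connected` and `disconnected` (logical k x R).
#' @export
clusterProfiles <- function(ensemble, roiset, bilateralMerge = FALSE,
                            zThreshold = 1) {
  members <- ensemble@members
  profs <- ensemble@memberProfiles
  if (!length(profs) || length(profs) != length(members))
    stop("ensemble does not carry one profile map per member")
  k <- members[[1]]@k
  vals1 <- profs[[1]]@values
  cols <- if (bilateralMerge)
    .mergeBilateral(vals1, profs[[1]]@roiIds, roiset)
  else vals1
  R <- ncol(cols)
  acc <- matrix(0, k, R)
  n <- matrix(0, k, R)
  for (b in seq_along(members)) {
    vals <- profs[[b]]@values
    if (bilateralMerge) vals <- .mergeBilateral(vals, profs[[b]]@roiIds, roiset)
    lab <- members[[b]]@data[profs[[b]]@voxels]
    for (c in seq_len(k)) {
      rows <- lab == c
      if (!any(rows)) next
      acc[c, ] <- acc[c, ] + apply(vals[rows, , drop = FALSE], 2L, stats::median)
      n[c, ] <- n[c, ] + 1
    }
  }
  if (any(n[, 1] == 0))
    stop(sprintf("cluster(s) %s empty in every bootstrap",
                 paste(which(n[, 1] == 0), collapse = ", ")))
  med <- acc / n
  sdr <- apply(med, 1L, stats::sd)
  if (any(sdr == 0))
    stop("zero variance across ROIs; z-scored profile undefined")
  z <- (med - rowMeans(med)) / sdr
  colnames(med) <- colnames(z) <- if (bilateralMerge) colnames(cols)
    else roiset@names[match(profs[[1]]@roiIds, roiset@ids)]
  list(median = med, z = z,
       connected = z > zThreshold, disconnected = z < -zThreshold)
}

#' Relative cluster volumes across bootstrap members
#'
#' Per member, each cluster's voxel count divided by the seed-structure
#' voxel count (rows sum to 1); mean and sd are taken across members.
#'
#' @param ensemble a matched \linkS4class{ParcellationEnsemble} (or a list
#'   of \linkS4class{Parcellation}s).
#' @return list with `perMember` (members x k matrix of fractions) and
#'   `table` (data.frame: cluster, mean, sd).
#' @export
relativeVolumes <- function(ensemble) {
  members <- if (is(ensemble, "ParcellationEnsemble")) ensemble@members
             else ensemble
  k <- members[[1]]@k
  perMember <- t(vapply(members, function(m) {
    lab <- m@data[m@data > 0L]
    tabulate(lab, nbins = k) / length(lab)
  }, numeric(k)))
  tab <- data.frame(cluster = seq_len(k),
                    mean = colMeans(perMember),
                    sd = apply(perMember, 2L, stats::sd))
  list(perMember = perMember, table = tab)
}

#' Bilateral clustering symmetry index
#'
#' Mirrors each hemisphere's labels onto the other across the mid-sagittal
#' grid plane and scores per-voxel agreement (1 if the superposed voxels
#' carry the same cluster, 0 otherwise; mirrored voxels landing outside the
#' opposite seed mask count as disagreement). The index is the mean of the
#' two direction-wise agreement rates: 1 = perfectly symmetric,
#' 0 = no mirrored voxel agrees.
#'
#' @param parc a \linkS4class{Parcellation}.
#' @param seedMask \linkS4class{LabelVolume} with hemisphere labels
#'   (1 = left, 2 = right), or a list of two logical arrays.
#' @param axis grid axis orthogonal to the mid-sagittal plane (default 1).
#' @return the symmetry index in [0, 1].
#' @export
symmetryIndex <- function(parc, seedMask, axis = 1L) {
  if (is(seedMask, "LabelVolume")) {
    left <- which(seedMask@data == 1L)
    right <- which(seedMask@data == 2L)
  } else {
    left <- which(seedMask[[1]])
    right <- which(seedMask[[2]])
  }
  if (!length(left) || !length(right)) stop("empty hemisphere mask")
  mir <- mirrorIndexMap(dim(parc@data), axis)
  lab <- parc@data
  inRight <- array(FALSE, dim(lab)); inRight[right] <- TRUE
  inLeft <- array(FALSE, dim(lab)); inLeft[left] <- TRUE
  agreeLR <- sum(inRight[mir[left]] & lab[left] == lab[mir[left]] &
                   lab[left] > 0L)
  agreeRL <- sum(inLeft[mir[right]] & lab[right] == lab[mir[right]] &
                   lab[right] > 0L)
  0.5 * (agreeLR / length(left) + agreeRL / length(right))
}

#' Ipsilateral and contralateral connectivity indices
#'
#' Ri = mean FC(right seed voxels to right-hemisphere ROIs) /
#'      mean FC(left seed voxels to left-hemisphere ROIs);
#' Rc = mean FC(right seed to left ROIs) / mean FC(left seed to right ROIs).
#' Both are 1 under exact hemispheric exchange symmetry. Signed FC is used
#' by default; set `absolute = TRUE` to average |FC| instead. Midline ROIs
#' are excluded.
#'
#' @param profiles a \linkS4class{ProfileMap} over the whole seed structure.
#' @param seedMask \linkS4class{LabelVolume} with 1 = left, 2 = right seed
#'   voxels.
#' @param roiset the \linkS4class{RoiSet}.
#' @param absolute average absolute FC values (default FALSE).
#' @return list with elements `Ri` and `Rc`.
#' @export
lateralityIndices <- function(profiles, seedMask, roiset, absolute = FALSE) {
  hemiOfVox <- seedMask@data[profiles@voxels]
  rowsL <- hemiOfVox == 1L
  rowsR <- hemiOfVox == 2L
  if (!any(rowsL) || !any(rowsR)) stop("empty hemisphere in seed mask")
  hemiOfRoi <- roiset@hemisphere[match(profiles@roiIds, roiset@ids)]
  colsL <- hemiOfRoi == "L"
  colsR <- hemiOfRoi == "R"
  if (!any(colsL) || !any(colsR)) stop("RoiSet has no lateralized ROIs")
  vals <- profiles@values
  if (absolute) vals <- abs(vals)
  m <- function(rows, cols) mean(vals[rows, cols, drop = FALSE])
  denomI <- m(rowsL, colsL)
  denomC <- m(rowsL, colsR)
  if (denomI == 0 || denomC == 0) stop("zero denominator in laterality index")
  list(Ri = m(rowsR, colsR) / denomI, Rc = m(rowsR, colsL) / denomC)
}

#' Global connectivity of the seed structure to each bilateral ROI
#'
#' The absolute FC of every seed voxel to every ROI, averaged over voxels
#' and subjects, then averaged between the two members of each bilateral ROI
#' pair. No bootstrapping; all subjects are pooled. Midline ROIs are
#' reported unmerged.
#'
#' @param profileList per-subject \linkS4class{ProfileMap}s (pearson_r).
#' @param roiset the \linkS4class{RoiSet}.
#' @return data.frame with columns `roi` (pair or midline name) and `fc`.
#' @export
globalThalamicConnectivity <- function(profileList, roiset) {
  ref <- profileList[[1]]
  perRoi <- rowMeans(vapply(profileList, function(p) {
    if (!identical(p@roiIds, ref@roiIds))
      stop("profile maps do not share the ROI axis")
    colMeans(abs(p@values))
  }, numeric(length(ref@roiIds))))
  merged <- .mergeBilateral(matrix(perRoi, nrow = 1L), ref@roiIds, roiset)
  data.frame(roi = colnames(merged), fc = drop(merged),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ROI-ROI connectivity matrices per age group
#'
#' Per group: the Pearson correlation matrix of the ROI-averaged time
#' series, computed per subject over the first `nSubjects` subjects of the
#' group (metadata order) and averaged; symmetric with unit diagonal. Also
#' returns the difference matrices between consecutive groups (declared
#' order) and the global scalar per group: the mean absolute off-diagonal
#' value.
#'
#' @param cohortBold list of preprocessed \linkS4class{BoldSeries}.
#' @param labels \linkS4class{LabelVolume} of ROI parcels.
#' @param roiset the \linkS4class{RoiSet}.
#' @param metadata data.frame with subjectId and ageGroup, parallel to
#'   `cohortBold`.
#' @param groupOrder ordered group keys (default: order of first
#'   appearance).
#' @param nSubjects subjects used per group (default 25).
#' @return list with `matrices`, `differences` (named "B-A") and `global`.
#' @export
roiRoiConnectivity <- function(cohortBold, labels, roiset, metadata,
                               groupOrder = unique(metadata$ageGroup),
                               nSubjects = 25L) {
  R <- length(roiset@ids)
  roiIdx <- lapply(roiset@ids, function(id) which(labels@data == id))
  if (any(vapply(roiIdx, length, 1L) == 0L)) stop("empty ROI")
  mats <- list()
  for (g in groupOrder) {
    subj <- which(metadata$ageGroup == g)
    if (length(subj) < nSubjects)
      stop(sprintf("group '%s' has %d subjects, need %d", g, length(subj),
                   nSubjects))
    subj <- subj[seq_len(nSubjects)]
    M <- matrix(0, R, R)
    for (s in subj) {
      S <- vapply(roiIdx, function(idx)
        rowMeans(.seriesMatrix(cohortBold[[s]], idx)),
        numeric(nTimepoints(cohortBold[[s]])))
      M <- M + stats::cor(S)
    }
    M <- M / length(subj)
    diag(M) <- 1
    nm <- roiset@names
    dimnames(M) <- list(nm, nm)
    mats[[as.character(g)]] <- M
  }
  diffs <- list()
  if (length(groupOrder) > 1L)
    for (i in 2:length(groupOrder)) {
      a <- as.character(groupOrder[i - 1L]); b <- as.character(groupOrder[i])
      diffs[[paste0(b, "-", a)]] <- mats[[b]] - mats[[a]]
    }
  glob <- vapply(mats, function(M) mean(abs(M[row(M) != col(M)])), 1)
  list(matrices = mats, differences = diffs, global = glob)
}
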