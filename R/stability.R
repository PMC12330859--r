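# Bootstrap ensembles, voxel-wise uncertainty, CoV-of-IoU variability and
# silhouette diagnostics for choosing the number of clusters.

#' Subjects-bootstrap parcellation ensemble
#'
#' Each member draws ceiling(fraction * N) subjects without replacement,
#' group-averages their Fisher-Z profiles, clusters them with spherical
#' k-means and is label-matched (Hungarian) to the reference: by default the
#' first member, or an externally supplied parcellation (e.g. the reference
#' group's first bootstrap in cross-group comparisons). Member seeds are
#' derived from `masterSeed`, so the ensemble is fully deterministic.
#'
#' @param subjectProfiles list of per-subject \linkS4class{ProfileMap}s on
#'   the fisher_z scale.
#' @param fraction subject fraction per bootstrap, in (0, 1] (default 0.75).
#' @param nBootstraps ensemble size (default 40).
#' @param k number of clusters.
#' @param masterSeed master seed.
#' @param reference optional external reference \linkS4class{Parcellation}.
#' @param nInit k-means++ restarts per member.
#' @param affine affine attached to member volumes.
#' @return a \linkS4class{ParcellationEnsemble} (scheme "subjects").
#' @export
subjectsBootstrap <- function(subjectProfiles, fraction = 0.75,
                              nBootstraps = 40L, k, masterSeed,
                              reference = NULL, nInit = 10L,
                              affine = diag(4)) {
  N <- length(subjectProfiles)
  if (N < 2L) stop("need at least 2 subjects to bootstrap")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  nPick <- as.integer(ceiling(fraction * N))
  members <- vector("list", nBootstraps)
  subsets <- vector("list", nBootstraps)
  memberProfiles <- vector("list", nBootstraps)
  for (b in seq_len(nBootstraps)) {
    pick <- withSeed(childSeed(masterSeed, b, 1L), sample.int(N, nPick))
    prof <- groupAverageProfiles(subjectProfiles[pick])
    parc <- knitCluster(prof, k, seed = childSeed(masterSeed, b, 2L),
                        nInit = nInit, affine = affine)
    parc@bootstrapId <- b
    subsets[[b]] <- sort(pick)
    memberProfiles[[b]] <- prof
    members[[b]] <- parc
  }
  ref <- if (is.null(reference)) members[[1]] else reference
  members <- lapply(members, matchLabels, reference = ref)
  new("ParcellationEnsemble", members = members, scheme = "subjects",
      fraction = fraction, subsets = subsets,
      memberProfiles = memberProfiles, masterSeed = as.integer(masterSeed))
}

#' Timepoints-bootstrap parcellation ensemble
#'
#' Fixes one random subset of `nSubjects` subjects, then builds each member
#' from a random floor(fraction * t) subset of timepoints (drawn without
#' replacement, temporal order preserved), recomputing FC profiles before
#' clustering. Removes the subject-count confound when comparing variability
#' across groups of different sizes.
#'
#' @param cohortBold list of preprocessed \linkS4class{BoldSeries} (one per
#'   subject).
#' @param seedMask,labels,roiset seed mask, ROI parcels and profile axis.
#' @param nSubjects fixed number of subjects used (default 25).
#' @param fraction timepoint fraction per bootstrap (default 0.75).
#' @param nBootstraps ensemble size (default 10).
#' @param k number of clusters.
#' @param masterSeed master seed.
#' @param reference optional external reference \linkS4class{Parcellation}.
#' @param nInit k-means++ restarts per member.
#' @return a \linkS4class{ParcellationEnsemble} (scheme "timepoints").
#' @export
timepointsBootstrap <- function(cohortBold, seedMask, labels, roiset,
                                nSubjects = 25L, fraction = 0.75,
                                nBootstraps = 10L, k, masterSeed,
                                reference = NULL, nInit = 10L) {
  N <- length(cohortBold)
  if (N < nSubjects)
    stop(sprintf("cohort has %d subjects, need %d", N, nSubjects))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  t <- nTimepoints(cohortBold[[1]])
  nT <- as.integer(floor(fraction * t))
  if (nT < 30L)
    stop(sprintf("only %d timepoints per bootstrap; need at least 30", nT))
  subjects <- withSeed(childSeed(masterSeed, 0L), sort(sample.int(N, nSubjects)))
  seedIdx <- .maskIndices(seedMask)
  roiIdx <- which(labels@data %in% roiset@ids)
  roiOf <- labels@data[roiIdx]
  dims <- dim(cohortBold[[1]]@data)[1:3]
  affine <- if (is(seedMask, "LabelVolume")) seedMask@affine else diag(4)
  seedMats <- lapply(cohortBold[subjects], .seriesMatrix, which = seedIdx)
  roiMats <- lapply(cohortBold[subjects], .seriesMatrix, which = roiIdx)
  members <- vector("list", nBootstraps)
  subsets <- vector("list", nBootstraps)
  memberProfiles <- vector("list", nBootstraps)
  for (b in seq_len(nBootstraps)) {
    tp <- withSeed(childSeed(masterSeed, b, 1L), sort(sample.int(t, nT)))
    profs <- lapply(seq_along(subjects), function(s) {
      vals <- .fcCore(seedMats[[s]][tp, , drop = FALSE],
                      roiMats[[s]][tp, , drop = FALSE], roiOf, roiset@ids)
      fisherZ(new("ProfileMap", voxels = as.integer(seedIdx),
                  values = pmin(pmax(vals, -1), 1), scale = "pearson_r",
                  roiIds = roiset@ids, dims = dims))
    })
    prof <- groupAverageProfiles(profs)
    parc <- knitCluster(prof, k, seed = childSeed(masterSeed, b, 2L),
                        nInit = nInit, affine = affine)
    parc@bootstrapId <- b
    subsets[[b]] <- tp
    memberProfiles[[b]] <- prof
    members[[b]] <- parc
  }
  ref <- if (is.null(reference)) members[[1]] else reference
  members <- lapply(members, matchLabels, reference = ref)
  new("ParcellationEnsemble", members = members, scheme = "timepoints",
      fraction = fraction, subsets = subsets,
      memberProfiles = memberProfiles, masterSeed = as.integer(masterSeed))
}

#' Voxel-wise uncertainty map of a consensus parcellation
#'
#' U(v) = 1 - N_c*(v) / N_total, the complement of the majority-label
#' proportion across the ensemble: 0 where all members agree, bounded by
#' 1 - 1/N_total. The scalar uBar sums U(v) over all seed voxels (each voxel
#' belongs to exactly one consensus cluster) and divides by the group's
#' subject count, making groups of different sizes comparable.
#'
#' @param ensemble the matched \linkS4class{ParcellationEnsemble}.
#' @param consensus the \linkS4class{ConsensusParcellation} from
#'   \code{\link{majorityVote}} of the same ensemble.
#' @param nSubjectsNorm subject count used to normalize uBar.
#' @return an \linkS4class{UncertaintyMap}.
#' @export
uncertaintyMap <- function(ensemble, consensus, nSubjectsNorm) {
  if (consensus@nTotal != length(ensemble@members))
    stop("consensus was not built from this ensemble (N_total differs)")
  maskIdx <- consensus@voxels
  if (!identical(maskIdx, which(ensemble@members[[1]]@data > 0L)))
    stop("consensus and ensemble are not on the same seed mask")
  counts <- consensus@voteCounts
  lab <- consensus@data[maskIdx]
  maxCount <- counts[cbind(seq_along(maskIdx), lab)]
  if (any(maxCount < apply(counts, 1L, max)))
    stop("consensus labels do not carry the majority vote of this ensemble")
  u <- 1 - maxCount / consensus@nTotal
  arr <- array(0, dim(consensus@data))
  arr[maskIdx] <- u
  new("UncertaintyMap", u = arr, voxels = maskIdx,
      uBar = sum(u) / nSubjectsNorm, nTotal = consensus@nTotal,
      nSubjectsNorm = as.integer(nSubjectsNorm))
}

#' CoV of IoU across every bootstrap pair
#'
#' For every unordered pair of ensemble members and every cluster label:
#' IoU = |A intersect B| / |A union B|. Per cluster, the coefficient of
#' variation (sd/mean) over pairs summarizes variability; the scalar summary
#' is the mean CoV across clusters. Clusters empty in every member are
#' excluded (and reported); a CoV from a single pair, or with zero mean IoU,
#' is flagged degenerate rather than silently 0 or infinite.
#'
#' @param ensemble a matched \linkS4class{ParcellationEnsemble} with at
#'   least 2 members.
#' @return list with `iou` (data.frame: memberA, memberB, cluster, iou),
#'   `perCluster` (data.frame: cluster, mean, sd, cov, nPairs, degenerate),
#'   `summary` (mean CoV across non-degenerate clusters), and
#'   `excludedClusters`.
#' @export
covIoU <- function(ensemble) {
  members <- ensemble@members
  N <- length(members)
  if (N < 2L) stop("need at least 2 ensemble members")
  k <- members[[1]]@k
  maskIdx <- which(members[[1]]@data > 0L)
  L <- vapply(members, function(m) m@data[maskIdx], integer(length(maskIdx)))
  inCluster <- lapply(seq_len(k), function(c) L == c)  # voxels x members
  pairs <- utils::combn(N, 2L)
  rows <- list()
  for (c in seq_len(k)) {
    M <- inCluster[[c]]
    sizes <- colSums(M)
    if (all(sizes == 0L)) next
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      if (sizes[a] == 0L && sizes[b] == 0L) next  # undefined, skip pair
      inter <- sum(M[, a] & M[, b])
      union <- sizes[a] + sizes[b] - inter
      rows[[length(rows) + 1L]] <-
        data.frame(memberA = a, memberB = b, cluster = c,
                   iou = inter / union)
    }
  }
  iou <- do.call(rbind, rows)
  present <- sort(unique(iou$cluster))
  excluded <- setdiff(seq_len(k), present)
  perCluster <- do.call(rbind, lapply(present, function(c) {
    x <- iou$iou[iou$cluster == c]
    m <- mean(x)
    s <- if (length(x) > 1L) stats::sd(x) else 0
    degenerate <- length(x) < 2L || m == 0
    data.frame(cluster = c, mean = m, sd = s,
               cov = if (m > 0) s / m else NA_real_,
               nPairs = length(x), degenerate = degenerate)
  }))
  ok <- !is.na(perCluster$cov)
  list(iou = iou, perCluster = perCluster,
       summary = if (any(ok)) mean(perCluster$cov[ok]) else NA_real_,
       excludedClusters = excluded)
}

#' Mean silhouette score of a parcellation under cosine distance
#'
#' Proximity of each profile to its own cluster versus the nearest other
#' cluster, averaged over seed voxels; the distance is cosine, matching the
#' clustering. Values close to 1 indicate compact, well-separated clusters.
#'
#' @param profiles the \linkS4class{ProfileMap} the parcellation was built
#'   on.
#' @param parcellation a \linkS4class{Parcellation} with k >= 2.
#' @return mean silhouette width in [-1, 1].
#' @export
silhouetteScore <- function(profiles, parcellation) {
  lab <- parcellation@data[profiles@voxels]
  keep <- lab > 0L
  lab <- lab[keep]
  if (length(unique(lab)) < 2L)
    stop("silhouette requires at least 2 non-empty clusters")
  X <- profiles@values[keep, , drop = FALSE]
  X <- X / sqrt(rowSums(X^2))
  D <- 1 - X %*% t(X)
  D[D < 0] <- 0
  sil <- cluster::silhouette(lab, stats::as.dist(D))
  mean(sil[, "sil_width"])
}

#' Cluster-number diagnostics over a k grid
#'
#' For each k: the subjects-bootstrap CoV-of-IoU summary, optionally the
#' timepoints-bootstrap summary, and the mean and sd of the per-member
#' silhouette scores. The table ranks candidate k; no automatic winner is
#' declared — the number of clusters is a study-level choice.
#'
#' @param subjectProfiles list of per-subject fisher_z
#'   \linkS4class{ProfileMap}s.
#' @param kGrid candidate cluster counts (default 2:7).
#' @param fraction,nBootstraps subjects-bootstrap parameters.
#' @param masterSeed master seed.
#' @param nInit k-means++ restarts per member.
#' @param timepointArgs optional named list forwarded to
#'   \code{\link{timepointsBootstrap}} (cohortBold, seedMask, labels, roiset,
#'   nSubjects, fraction, nBootstraps); NULL skips the timepoints scheme.
#' @return data.frame with one row per k.
#' @export
selectK <- function(subjectProfiles, kGrid = 2:7, fraction = 0.75,
                    nBootstraps = 40L, masterSeed = 1L, nInit = 10L,
                    timepointArgs = NULL) {
  rows <- lapply(kGrid, function(k) {
    ens <- subjectsBootstrap(subjectProfiles, fraction = fraction,
                             nBootstraps = nBootstraps, k = k,
                             masterSeed = childSeed(masterSeed, k, 1L),
                             nInit = nInit)
    covS <- covIoU(ens)$summary
    sil <- vapply(seq_along(ens@members), function(b)
      silhouetteScore(ens@memberProfiles[[b]], ens@members[[b]]), 1)
    covT <- NA_real_
    if (!is.null(timepointArgs)) {
      ensT <- do.call(timepointsBootstrap,
                      c(timepointArgs,
                        list(k = k, masterSeed = childSeed(masterSeed, k, 2L),
                             nInit = nInit)))
      covT <- covIoU(ensT)$summary
    }
    data.frame(k = k, covIoUSubjects = covS, covIoUTimepoints = covT,
               silhouetteMean = mean(sil), silhouetteSd = stats::sd(sil))
  })
  do.call(rbind, rows)
}
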