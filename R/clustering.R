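# Core parcellation machinery: spherical (cosine) k-means on connectivity
# profiles, the winner-takes-all baseline, Hungarian label matching,
# majority-vote consensus and small-component pruning.

.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d <- pmax(0, 1 - drop(X %*% centers[1L, ]))
    for (c in 2:k) {
      i <- if (sum(d) <= 0) sample.int(n, 1L)
           else sample.int(n, 1L, prob = d)
      centers[c, ] <- X[i, ]
      d <- pmin(d, pmax(0, 1 - drop(X %*% centers[c, ])))
    }
  }
  centers
}

# One spherical k-means run from a kmeans++ start. Rows of X must be unit
# norm. Objective = sum over points of (1 - cosine to assigned centroid);
# both steps (assignment, normalized-mean centroid update) are monotone, so
# the recorded objective trace is non-increasing.
.skmeansOnce <- function(X, k, maxIter, tol) {
  n <- nrow(X)
  C <- .kmeansppInit(X, k)
  trace <- numeric(0)
  objOld <- Inf
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    S <- X %*% t(C)
    assign <- max.col(S, ties.method = "first")
    fit <- S[cbind(seq_len(n), assign)]
    obj <- sum(1 - fit)
    trace <- c(trace, obj)
    for (c in seq_len(k)) {
      rows <- assign == c
      if (!any(rows)) {          # re-seed an empty cluster at the worst fit
        C[c, ] <- X[which.min(fit), ]
      } else {
        m <- colSums(X[rows, , drop = FALSE])
        nm <- sqrt(sum(m^2))
        C[c, ] <- if (nm > 0) m / nm else X[which(rows)[1L], ]
      }
    }
    if (objOld - obj < tol && it > 1L) break
    objOld <- obj
  }
  list(assign = assign, centers = C, objective = obj, trace = trace)
}

#' Spherical k-means on connectivity profiles
#'
#' Cosine-distance k-means: profile rows are scaled to unit norm, centroids
#' are renormalized means, assignment maximizes cosine similarity.
#' Initialization is kmeans++ (on cosine distance) restarted \code{nInit}
#' times; the run with the lowest objective wins. Deterministic given
#' \code{seed}. Rows with zero norm are pre-assigned label 0 and excluded
#' from clustering.
#'
#' @param profiles a \linkS4class{ProfileMap} (any scale).
#' @param k number of clusters (2..V).
#' @param seed integer seed.
#' @param nInit,maxIter,tol restart count, iteration cap, convergence
#'   tolerance on the objective decrease.
#' @param affine grid-to-world affine attached to the output volume.
#' @return a \linkS4class{Parcellation} with method \code{"knit"}; the
#'   attribute \code{"objectiveTrace"} holds the winning run's objective per
#'   iteration.
#' @export
knitCluster <- function(profiles, k, seed, nInit = 10L, maxIter = 300L,
                        tol = 1e-6, affine = diag(4)) {
  V <- length(profiles@voxels)
  k <- as.integer(k)
  if (k < 1L || k > V) stop("need 1 <= k <= number of seed voxels")
  X <- profiles@values
  norms <- sqrt(rowSums(X^2))
  live <- norms > 0
  Xn <- X[live, , drop = FALSE] / norms[live]
  nDistinct <- nrow(unique(round(Xn, 10L)))
  if (k > nDistinct)
    stop(sprintf("k = %d exceeds the %d distinct profile directions",
                 k, nDistinct))
  best <- withSeed(seed, {
    b <- NULL
    for (i in seq_len(nInit)) {
      run <- .skmeansOnce(Xn, k, maxIter, tol)
      if (is.null(b) || run$objective < b$objective) b <- run
    }
    b
  })
  lab <- integer(V)
  lab[live] <- best$assign
  arr <- array(0L, profiles@dims)
  arr[profiles@voxels] <- lab
  out <- new("Parcellation", data = arr,
             affine = affine, k = k, method = "knit",
             seed = as.integer(seed), bootstrapId = NA_integer_)
  attr(out, "objectiveTrace") <- best$trace
  attr(out, "centers") <- best$centers
  out
}

#' Winner-takes-all assignment from lobe profiles
#'
#' Each voxel is assigned the lobe with the maximal partial correlation;
#' exact ties go to the earliest lobe in the axis order (temporal first).
#' Invariant to any strictly increasing transform of a voxel's profile.
#'
#' @param lobeProfiles a \linkS4class{LobeProfileMap}.
#' @param affine grid-to-world affine attached to the output volume.
#' @return a \linkS4class{Parcellation} with method \code{"wta"} and
#'   k = number of lobes; label i is lobe i in axis order.
#' @export
wtaAssign <- function(lobeProfiles, affine = diag(4)) {
  vals <- lobeProfiles@values
  if (any(!is.finite(vals))) stop("lobe profiles must be finite")
  lab <- max.col(vals, ties.method = "first")
  arr <- array(0L, lobeProfiles@dims)
  arr[lobeProfiles@voxels] <- lab
  new("Parcellation", data = arr, affine = affine,
      k = ncol(vals), method = "wta",
      seed = NA_integer_, bootstrapId = NA_integer_)
}

#' Match cluster ids to a reference parcellation (Hungarian)
#'
#' Permutes the labels of \code{parc} to maximize the total number of voxels
#' agreeing with \code{reference}, via the linear-assignment formulation with
#' cost = -overlap (optionally -IoU). When \code{parc} uses fewer labels than
#' the reference, the missing labels are padded with zero-cost assignments.
#'
#' @param parc,reference \linkS4class{Parcellation}s on the same seed mask.
#' @param cost \code{"overlap"} (default) or \code{"iou"}.
#' @return \code{parc} with permuted labels and k = max(k, reference k).
#' @export
matchLabels <- function(parc, reference, cost = c("overlap", "iou")) {
  cost <- match.arg(cost)
  mp <- parc@data > 0L
  mr <- reference@data > 0L
  if (!identical(mp, mr)) stop("parcellations are not on the same seed mask")
  K <- max(parc@k, reference@k)
  lp <- parc@data[mp]
  lr <- reference@data[mr]
  O <- matrix(0, K, K)   # O[i, j] = |{ref == i & parc == j}|
  tab <- table(factor(lr, levels = seq_len(K)), factor(lp, levels = seq_len(K)))
  O[] <- as.numeric(tab)
  M <- if (cost == "overlap") O else {
    sizeR <- tabulate(lr, nbins = K)
    sizeP <- tabulate(lp, nbins = K)
    U <- outer(sizeR, sizeP, "+") - O
    ifelse(U > 0, O / U, 0)
  }
  a <- solveAssignment(-M)   # a[i] = parc label assigned to ref label i
  relabel <- integer(K)
  relabel[a] <- seq_len(K)   # parc label j -> ref label relabel[j]
  arr <- parc@data
  arr[mp] <- relabel[lp]
  methods::initialize(parc, data = arr, k = K)
}

#' Majority-vote consensus of a label-matched ensemble
#'
#' Per voxel, the most frequent label across members; ties go to the
#' smallest label id (deterministic and order-independent). The per-voxel
#' vote counts are retained for the uncertainty map.
#'
#' @param ensemble a \linkS4class{ParcellationEnsemble} whose members are
#'   label-matched to a common reference.
#' @return a \linkS4class{ConsensusParcellation}.
#' @export
majorityVote <- function(ensemble) {
  members <- ensemble@members
  if (!length(members)) stop("empty ensemble")
  k <- members[[1]]@k
  maskIdx <- which(members[[1]]@data > 0L)
  L <- vapply(members, function(m) m@data[maskIdx], integer(length(maskIdx)))
  L <- matrix(L, nrow = length(maskIdx))
  counts <- t(apply(L, 1L, tabulate, nbins = k))
  lab <- max.col(counts, ties.method = "first")  # first max = smallest label
  arr <- array(0L, dim(members[[1]]@data))
  arr[maskIdx] <- lab
  new("ConsensusParcellation", data = arr, affine = members[[1]]@affine,
      k = k, method = "consensus", seed = ensemble@masterSeed,
      bootstrapId = NA_integer_, voxels = as.integer(maskIdx),
      voteCounts = counts, nTotal = length(members))
}

#' Absorb small clusters surrounded by a dominant neighbor
#'
#' Connected components (26-connectivity) of each label with fewer than
#' \code{minSize} voxels are relabelled to the neighboring label when more
#' than \code{surroundFraction} of the component's face-adjacent (6-connected)
#' outside neighbors carry that one (non-background) label. Passes repeat
#' until nothing changes, so the operation is idempotent; no new labels are
#' ever introduced.
#'
#' @param parc a \linkS4class{Parcellation}.
#' @param minSize components strictly smaller than this are candidates
#'   (default 16 voxels).
#' @param surroundFraction required fraction of same-label outside neighbors
#'   (default 0.5, strict).
#' @param connectivity neighborhood defining components (6 or 26).
#' @return the pruned \linkS4class{Parcellation}.
#' @export
pruneSmallComponents <- function(parc, minSize = 16L, surroundFraction = 0.5,
                                 connectivity = 26L) {
  arr <- parc@data
  d <- dim(arr)
  offs6 <- neighborOffsets(6L)
  repeat {
    changed <- FALSE
    snapshot <- arr
    for (lab in sort(setdiff(unique(as.vector(snapshot)), 0L))) {
      comps <- connectedComponents(snapshot == lab, connectivity)
      for (c in seq_len(max(comps))) {
        vox <- which(comps == c)
        if (length(vox) >= minSize) next
        co <- arrayInd(vox, d)
        nb <- do.call(rbind, lapply(seq_len(nrow(offs6)), function(o)
          sweep(co, 2L, as.integer(offs6[o, ]), "+")))
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
        lin <- setdiff(lin, vox)
        if (!length(lin)) next
        nbLab <- snapshot[lin]
        tab <- tabulate(nbLab[nbLab > 0L], nbins = parc@k)
        if (!any(tab > 0)) next
        dom <- which.max(tab)
        if (dom != lab && tab[dom] > surroundFraction * length(nbLab)) {
          arr[vox] <- dom
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  methods::initialize(parc, data = arr)
}
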