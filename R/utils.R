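# Internal helpers shared across modules: seed derivation, grid checks,
# mirroring and 3D connected components.

# Derive a child seed from a master seed and a salt path, by a fixed
# linear-congruential fold. Keeps every derived seed in [1, 2^31 - 2] so
# set.seed() always accepts it, and lets any pipeline stage be rerun in
# isolation from the master seed alone.
childSeed <- function(master, ...) {
  salts <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (x in salts) {
    s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Hard error unless two volumes share grid shape and affine (tol 1e-4):
# registration is out of scope, all inputs must be on one grid.
assertSameGrid <- function(a, b, what = "volumes") {
  da <- dim(a@data); db <- dim(b@data)
  if (!identical(unname(da[1:3]), unname(db[1:3])))
    stop(sprintf("%s have different grid shapes (%s vs %s)", what,
                 paste(da[1:3], collapse = "x"), paste(db[1:3], collapse = "x")))
  if (max(abs(a@affine - b@affine)) > 1e-4)
    stop(sprintf("%s have different affines (tolerance 1e-4); all inputs must share one grid",
                 what))
  invisible(TRUE)
}

# Map of linear indices to their mirror across the mid-sagittal grid plane
# of `axis` (coordinate x -> n + 1 - x). Returns an integer vector m such
# that m[i] is the mirror of linear index i.
mirrorIndexMap <- function(dims, axis = 1L) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  idx[, axis] <- dims[axis] + 1L - idx[, axis]
  as.integer(idx[, 1] + dims[1] * (idx[, 2] - 1L) +
               dims[1] * dims[2] * (idx[, 3] - 1L))
}

# Mirror a 3D array across the mid-sagittal plane of `axis`.
mirrorVolume <- function(x, axis = 1L) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[axis]
  switch(axis,
         x[n:1, , , drop = FALSE],
         x[, n:1, , drop = FALSE],
         x[, , n:1, drop = FALSE])
}

neighborOffsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
  } else stop("connectivity must be 6 or 26")
}

# Label the connected components of a 3D logical mask. Returns an integer
# array of the same shape: 0 outside the mask, component ids 1..n inside.
connectedComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- neighborOffsets(connectivity)
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  comp <- 0L
  for (s in idx) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    stack <- s
    labels[s] <- comp
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      vc <- arrayInd(v, d)
      nb <- sweep(offs, 2L, as.integer(vc), "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[mask[lin] & labels[lin] == 0L]
      if (length(new)) {
        labels[new] <- comp
        stack <- c(stack, new)
      }
    }
  }
  labels
}

# Adjusted Rand Index between two labelings, delegated to mclust.
#' Adjusted Rand Index between two parcellations
#'
#' Chance-corrected agreement between two labelings of the same voxels,
#' typically a recovered parcellation against a planted ground truth.
#' Labels are compared only at voxels labelled (> 0) in both inputs, and
#' voxels listed in \code{exclude} (e.g. border-mix voxels of a phantom)
#' are dropped first.
#'
#' @param a,b \linkS4class{Parcellation} objects (or integer arrays/vectors).
#' @param exclude optional integer linear indices of voxels to ignore.
#' @return the Adjusted Rand Index (1 = identical partitions).
#' @export
parcellationARI <- function(a, b, exclude = NULL) {
  la <- if (is(a, "Parcellation")) a@data else a
  lb <- if (is(b, "Parcellation")) b@data else b
  la <- as.vector(la); lb <- as.vector(lb)
  stopifnot(length(la) == length(lb))
  keep <- la > 0L & lb > 0L
  if (!is.null(exclude)) keep[exclude] <- FALSE
  if (!any(keep)) stop("no overlapping labelled voxels to compare")
  mclust::adjustedRandIndex(la[keep], lb[keep])
}
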