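# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small 3-cluster phantom with one simulated subject and its FC profiles.
tinyPhantom <- function() {
  cached("tinyPhantom", {
    spec <- phantomSpec(dims = c(20L, 20L, 20L), nRois = 6L, kTrue = 3L,
                        profileMatrix = phantomProfileMatrix(3L, 6L),
                        nTimepoints = 400L, noiseSd = 1, seed = 2L)
    truth <- makePhantomAnatomy(spec)
    mask <- volumeData(truth@roiParcels) > 0L | volumeData(truth@seedMask) > 0L
    bold <- simulateSubject(truth, spec, 42L)
    pp <- preprocessBold(bold, mask = mask)
    prof <- voxelRoiFC(pp, truth@seedMask, truth@roiParcels, truth@roiset)
    list(spec = spec, truth = truth, mask = mask, bold = bold, pp = pp,
         pearson = prof, z = fisherZ(prof))
  })
}

# Noise-free, unblended phantom: FC profiles are exact planted directions.
cleanPhantom <- function() {
  cached("cleanPhantom", {
    spec <- phantomSpec(dims = c(20L, 20L, 20L), nRois = 6L, kTrue = 3L,
                        profileMatrix = phantomProfileMatrix(3L, 6L),
                        nTimepoints = 200L, noiseSd = 0, borderMixWidth = 0,
                        seed = 7L)
    truth <- makePhantomAnatomy(spec)
    bold <- simulateSubject(truth, spec, 11L)
    prof <- voxelRoiFC(bold, truth@seedMask, truth@roiParcels, truth@roiset)
    list(spec = spec, truth = truth, bold = bold, pearson = prof,
         z = fisherZ(prof))
  })
}

# A toy 6-ROI RoiSet (3 bilateral pairs over 3 lobes).
toyRoiSet <- function() {
  roiSet(ids = 1:6, hemisphere = c("L", "R", "L", "R", "L", "R"),
         lobe = rep(c("temporal", "parietal", "frontal"), each = 2L),
         pair = c(2L, 1L, 4L, 3L, 6L, 5L))
}

# Bare Parcellation from a 3D integer array.
mkParc <- function(arr, k, method = "knit") {
  new("Parcellation", data = arr, affine = diag(4), k = as.integer(k),
      method = method, seed = NA_integer_, bootstrapId = NA_integer_)
}

# Ensemble of parcellations sharing one mask, from a voxels x members label
# matrix laid out on a minimal grid.
mkEnsemble <- function(labelMatrix, k, scheme = "subjects") {
  V <- nrow(labelMatrix)
  dims <- c(V, 1L, 1L)
  members <- lapply(seq_len(ncol(labelMatrix)), function(b) {
    arr <- array(0L, dims)
    arr[seq_len(V)] <- as.integer(labelMatrix[, b])
    mkParc(arr, k)
  })
  new("ParcellationEnsemble", members = members, scheme = scheme,
      fraction = 1, subsets = rep(list(integer(0)), ncol(labelMatrix)),
      memberProfiles = list(), masterSeed = 1L)
}

# ProfileMap from a plain matrix (voxels laid out linearly).
mkProfiles <- function(values, scale = "pearson_r", dims = NULL) {
  V <- nrow(values)
  if (is.null(dims)) dims <- c(V, 1L, 1L)
  new("ProfileMap", voxels = seq_len(V), values = values, scale = scale,
      roiIds = seq_len(ncol(values)), dims = as.integer(dims))
}

# Exhaustive-permutation oracle for label matching: best relabeling of parc
# maximizing overlap with ref (both integer vectors, labels 1..k).
bruteForceMatch <- function(parc, ref, k) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- -Inf
  for (p in perms(seq_len(k))) {
    agree <- sum(p[parc] == ref)
    if (agree > best) best <- agree
  }
  best
}
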