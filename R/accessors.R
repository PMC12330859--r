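#' @describeIn BoldSeries-class number of timepoints
#' @param x,object an object of the documented class
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @export
setMethod("nTimepoints", "BoldSeries", function(x) dim(x@data)[4])

#' Repetition time in seconds
#' @param x a \linkS4class{BoldSeries}
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @export
setMethod("repetitionTime", "BoldSeries", function(x) x@tr)

#' Voxel sizes (mm per axis) implied by an object's affine
#' @param x an object with an affine slot
#' @export
setGeneric("voxelSizes", function(x) standardGeneric("voxelSizes"))

.affineVoxelSizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
setMethod("voxelSizes", "BoldSeries", function(x) .affineVoxelSizes(x@affine))
#' @export
setMethod("voxelSizes", "LabelVolume", function(x) .affineVoxelSizes(x@affine))

#' Raw data array of a volume object
#' @param x a \linkS4class{BoldSeries}, \linkS4class{LabelVolume} or
#'   \linkS4class{Parcellation}
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @export
setMethod("volumeData", "BoldSeries", function(x) x@data)
#' @export
setMethod("volumeData", "LabelVolume", function(x) x@data)
#' @export
setMethod("volumeData", "Parcellation", function(x) x@data)

#' Label lookup table
#' @param x a \linkS4class{LabelVolume}
#' @export
setGeneric("lutTable", function(x) standardGeneric("lutTable"))

#' @export
setMethod("lutTable", "LabelVolume", function(x) x@lut)

#' Profile value matrix (V voxels x R targets)
#' @param x a \linkS4class{ProfileMap} or \linkS4class{LobeProfileMap}
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @export
setMethod("profileValues", "ProfileMap", function(x) x@values)
#' @export
setMethod("profileValues", "LobeProfileMap", function(x) x@values)

#' Linear voxel indices of the seed-structure voxels
#' @param x a profile map, consensus parcellation or uncertainty map
#' @export
setGeneric("voxelIndices", function(x) standardGeneric("voxelIndices"))

#' @export
setMethod("voxelIndices", "ProfileMap", function(x) x@voxels)
#' @export
setMethod("voxelIndices", "LobeProfileMap", function(x) x@voxels)
#' @export
setMethod("voxelIndices", "ConsensusParcellation", function(x) x@voxels)
#' @export
setMethod("voxelIndices", "UncertaintyMap", function(x) x@voxels)

#' Number of clusters of a parcellation
#' @param x a \linkS4class{Parcellation} or \linkS4class{ParcellationEnsemble}
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @export
setMethod("nClusters", "Parcellation", function(x) x@k)
#' @export
setMethod("nClusters", "ParcellationEnsemble", function(x) x@members[[1]]@k)

#' Ensemble members
#' @param x a \linkS4class{ParcellationEnsemble}
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))

#' @export
setMethod("ensembleMembers", "ParcellationEnsemble", function(x) x@members)

#' Normalized average uncertainty
#' @param x an \linkS4class{UncertaintyMap}
#' @export
setGeneric("uBar", function(x) standardGeneric("uBar"))

#' @export
setMethod("uBar", "UncertaintyMap", function(x) x@uBar)

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldSeries '%s' (%s): %dx%dx%d grid, %d timepoints, TR %.3g s\n",
              object@subjectId, object@ageGroup, d[1], d[2], d[3], d[4],
              object@tr))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelVolume: %dx%dx%d grid, %d label(s)\n",
              d[1], d[2], d[3], nrow(object@lut)))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d ROIs (%d bilateral pairs, %d midline), lobes: %s\n",
              length(object@ids), nrow(object@pairs),
              sum(object@hemisphere == "mid"),
              paste(sort(unique(object@lobe)), collapse = ", ")))
})

setMethod("show", "ProfileMap", function(object) {
  cat(sprintf("ProfileMap: %d voxels x %d ROIs [%s]\n",
              length(object@voxels), length(object@roiIds), object@scale))
})

setMethod("show", "LobeProfileMap", function(object) {
  cat(sprintf("LobeProfileMap: %d voxels x %d lobes (partial correlation)\n",
              length(object@voxels), length(object@lobes)))
})

setMethod("show", "Parcellation", function(object) {
  sz <- tabulate(object@data[object@data > 0L], nbins = object@k)
  cat(sprintf("Parcellation [%s]: k=%d, %d labelled voxels (%s)\n",
              object@method, object@k, sum(sz),
              paste(sz, collapse = "/")))
})

setMethod("show", "ParcellationEnsemble", function(object) {
  cat(sprintf("ParcellationEnsemble: %d members, scheme=%s, fraction=%.2f, k=%d\n",
              length(object@members), object@scheme, object@fraction,
              nClusters(object)))
})

setMethod("show", "UncertaintyMap", function(object) {
  uu <- object@u[object@voxels]
  cat(sprintf("UncertaintyMap: %d voxels, mean U=%.4f, uBar=%.4f (N_total=%d)\n",
              length(object@voxels), mean(uu), object@uBar, object@nTotal))
})
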