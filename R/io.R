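# NIfTI, lookup-table and ROI-config I/O.

.affineFromNifti <- function(img) {
  m <- unclass(RNifti::xform(img))
  attributes(m) <- list(dim = c(4L, 4L))
  m
}

#' Construct a BoldSeries from an array
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr repetition time in seconds.
#' @param affine 4x4 grid-to-world affine; defaults to `voxelSize` times the
#'   identity.
#' @param voxelSize isotropic voxel size in mm used when `affine` is missing.
#' @param subjectId,ageGroup subject metadata.
#' @return a \linkS4class{BoldSeries}
#' @export
boldSeries <- function(data, tr, affine = NULL, voxelSize = 2,
                       subjectId = "subject", ageGroup = "group") {
  if (is.null(affine)) affine <- diag(c(rep(voxelSize, 3), 1))
  storage.mode(data) <- "double"
  new("BoldSeries", data = data, tr = tr, affine = affine,
      subjectId = subjectId, ageGroup = ageGroup)
}

#' Construct a LabelVolume from an array and a lookup table
#'
#' @param data 3D integer-valued array (0 = background).
#' @param lut data.frame with columns id, name, hemisphere, lobe_group; when
#'   missing, a minimal lut covering the labels present is generated.
#' @param affine 4x4 affine, defaults to `voxelSize` times the identity.
#' @param voxelSize isotropic voxel size in mm used when `affine` is missing.
#' @return a \linkS4class{LabelVolume}
#' @export
labelVolume <- function(data, lut = NULL, affine = NULL, voxelSize = 2) {
  if (is.null(affine)) affine <- diag(c(rep(voxelSize, 3), 1))
  if (!is.integer(data)) {
    if (max(abs(data - round(data))) > 1e-6)
      stop("label volume is not integer-valued")
    data <- array(as.integer(round(data)), dim = dim(data))
  }
  if (is.null(lut)) {
    ids <- setdiff(sort(unique(as.vector(data))), 0L)
    lut <- data.frame(id = ids, name = sprintf("label%02d", ids),
                      hemisphere = rep("mid", length(ids)),
                      lobe_group = rep("none", length(ids)),
                      stringsAsFactors = FALSE)
  }
  new("LabelVolume", data = data, affine = affine, lut = lut)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path path to a 4D NIfTI-1 file (.nii or .nii.gz).
#' @param tr repetition time in seconds; when NULL the header pixdim[4] is
#'   used.
#' @param subjectId,ageGroup subject metadata attached to the series.
#' @return a \linkS4class{BoldSeries}; data are promoted to doubles whatever
#'   the on-disk type.
#' @export
readBold <- function(path, tr = NULL, subjectId = "subject",
                     ageGroup = "group") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is not 4D (found %d dimension(s))", path, length(d)))
  nbad <- sum(!is.finite(img))
  if (nbad > 0L)
    stop(sprintf("'%s' contains %d non-finite voxel value(s)", path, nbad))
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop("no usable TR in header; pass tr explicitly")
  }
  boldSeries(array(as.numeric(img), dim = d), tr = tr,
             affine = .affineFromNifti(img),
             subjectId = subjectId, ageGroup = ageGroup)
}

#' Read a label volume and its lookup table
#'
#' The lookup table is a 4-column TSV (id, name, hemisphere, lobe_group) and
#' must cover every non-zero label in the volume. Float-typed volumes whose
#' values sit exactly on integers are accepted and cast.
#'
#' @param niftiPath path to a 3D integer-valued NIfTI file.
#' @param lutPath path to the TSV lookup table.
#' @return a \linkS4class{LabelVolume}
#' @export
readLabels <- function(niftiPath, lutPath) {
  img <- RNifti::readNifti(niftiPath)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a 3D label volume", niftiPath))
  lut <- utils::read.delim(lutPath, stringsAsFactors = FALSE)
  need <- c("id", "name", "hemisphere", "lobe_group")
  if (!all(need %in% names(lut)))
    stop(sprintf("lut '%s' must have columns %s", lutPath,
                 paste(need, collapse = ", ")))
  labelVolume(array(as.numeric(img), dim = d), lut = lut,
              affine = .affineFromNifti(img))
}

.writeVolume <- function(data, affine, path, datatype) {
  img <- RNifti::asNifti(data)
  vox <- .affineVoxelSizes(affine)
  RNifti::pixdim(img) <- if (length(dim(data)) == 4L) c(vox, 1) else vox
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a parcellation (or any label volume) to NIfTI + lut TSV
#'
#' Writing then reading back (\code{\link{readLabels}}) reproduces the label
#' grid bit-exactly.
#'
#' @param parc a \linkS4class{LabelVolume} or \linkS4class{Parcellation}.
#' @param path output NIfTI path (.nii or .nii.gz).
#' @param lutPath output TSV path for the lookup table; default replaces the
#'   NIfTI extension with \code{.lut.tsv}. NULL skips the lut.
#' @export
writeParcellation <- function(parc, path, lutPath = .defaultLutPath(path)) {
  if (is(parc, "Parcellation"))
    parc <- labelVolume(parc@data, lut = .parcLut(parc), affine = parc@affine)
  if (dir.exists(path))
    stop(sprintf("'%s' is a directory", path))
  if (all(parc@data == 0L))
    warning("parcellation contains only background (label 0)")
  .writeVolume(parc@data, parc@affine, path, datatype = "int32")
  if (!is.null(lutPath))
    utils::write.table(parc@lut, lutPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

.defaultLutPath <- function(path) sub("\\.nii(\\.gz)?$", ".lut.tsv", path)

.parcLut <- function(parc) {
  ids <- seq_len(parc@k)
  data.frame(id = ids, name = sprintf("cluster%d", ids),
             hemisphere = "mid", lobe_group = "none", stringsAsFactors = FALSE)
}

#' Write a BoldSeries to a 4D NIfTI file
#'
#' @param bold a \linkS4class{BoldSeries}.
#' @param path output path; data are written as float32.
#' @export
writeBold <- function(bold, path) {
  .writeVolume(bold@data, bold@affine, path, datatype = "float")
  invisible(path)
}

#' Build a RoiSet from per-ROI descriptors
#'
#' @param ids ordered integer ROI ids: this order is the profile axis.
#' @param names,hemisphere,lobe per-ROI descriptors parallel to `ids`.
#' @param pair for each ROI the id of its contralateral partner, or NA for
#'   midline ROIs; the mapping must be symmetric (pair of pair is self).
#' @return a \linkS4class{RoiSet}
#' @export
roiSet <- function(ids, names = sprintf("roi%02d", ids),
                   hemisphere, lobe, pair = rep(NA_integer_, length(ids))) {
  ids <- as.integer(ids)
  pair <- as.integer(pair)
  if (anyDuplicated(ids)) stop("duplicate ROI ids")
  has <- !is.na(pair)
  if (any(has)) {
    back <- pair[match(pair[has], ids)]
    if (any(is.na(back)) || !all(back == ids[has]))
      stop("bilateral pairs must be symmetric (pair of pair must be self)")
  }
  left <- has & hemisphere == "L"
  pairs <- cbind(ids[left], pair[left])
  if (any(has & hemisphere == "mid"))
    stop("midline ROIs cannot belong to a bilateral pair")
  new("RoiSet", ids = ids, names = as.character(names),
      hemisphere = as.character(hemisphere), lobe = as.character(lobe),
      pairs = matrix(as.integer(pairs), ncol = 2L))
}

#' Load a RoiSet from a YAML/JSON config
#'
#' The config holds an ordered `rois` list, each entry with fields `id`,
#' `name`, `hemisphere` (L/R/mid), `lobe` and optionally `pair` (the id of
#' the contralateral partner). The file order fixes the profile axis.
#'
#' @param path path to the YAML (or JSON) config.
#' @return a \linkS4class{RoiSet}
#' @export
loadRoiConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (is.null(cfg$rois)) stop("config must declare a 'rois' list")
  getf <- function(f, default = NA) {
    vapply(cfg$rois, function(r) {
      v <- r[[f]]
      if (is.null(v)) default else v
    }, default)
  }
  roiSet(ids = as.integer(getf("id", NA_integer_)),
         names = getf("name", NA_character_),
         hemisphere = getf("hemisphere", NA_character_),
         lobe = getf("lobe", NA_character_),
         pair = as.integer(getf("pair", NA_integer_)))
}

#' Write a RoiSet to a YAML config
#'
#' The written file round-trips through \code{\link{loadRoiConfig}},
#' preserving the profile-axis order.
#'
#' @param roiset a \linkS4class{RoiSet}.
#' @param path output YAML path.
#' @export
writeRoiConfig <- function(roiset, path) {
  pairOf <- rep(NA_integer_, length(roiset@ids))
  for (p in seq_len(nrow(roiset@pairs))) {
    l <- match(roiset@pairs[p, 1], roiset@ids)
    r <- match(roiset@pairs[p, 2], roiset@ids)
    pairOf[l] <- roiset@ids[r]
    pairOf[r] <- roiset@ids[l]
  }
  rois <- lapply(seq_along(roiset@ids), function(i) {
    entry <- list(id = roiset@ids[i], name = roiset@names[i],
                  hemisphere = roiset@hemisphere[i], lobe = roiset@lobe[i])
    if (!is.na(pairOf[i])) entry$pair <- pairOf[i]
    entry
  })
  yaml::write_yaml(list(rois = rois), path)
  invisible(path)
}

#' The bundled default 40-ROI configuration
#'
#' Twenty bilateral pairs covering cortical areas, deep brain structures
#' (hippocampus, amygdala, parahippocampal gyrus, caudate nucleus) and the
#' cerebellum, in a left/right-interleaved order that this file fixes and
#' documents.
#'
#' @return a \linkS4class{RoiSet} with 40 ROIs.
#' @export
defaultRoiConfig <- function() {
  loadRoiConfig(system.file("extdata", "roiset_dhcp40.yaml",
                            package = "knitparc", mustWork = TRUE))
}

#' ROI ids of each lobe, in WTA lobe order
#'
#' @param roiset a \linkS4class{RoiSet}
#' @return named list of integer id vectors for temporal, parietal, frontal,
#'   occipital and limbic lobes.
#' @export
lobeGroups <- function(roiset) {
  lobes <- c("temporal", "parietal", "frontal", "occipital", "limbic")
  out <- lapply(lobes, function(l) roiset@ids[roiset@lobe == l])
  names(out) <- lobes
  out
}
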