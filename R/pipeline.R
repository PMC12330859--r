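# End-to-end orchestration: (simulate ->) preprocess -> FC -> bootstrap ->
# consensus -> uncertainty -> metrics, with a single master seed fanned out
# to stage seeds by a fixed derivation so every stage can be rerun in
# isolation. Reruns with an identical config and inputs produce identical
# outputs.

#' Assemble a pipeline run configuration
#'
#' All stage parameters with their standard defaults: 5 discarded
#' timepoints, 3 mm FWHM smoothing, 0.08 Hz low-pass, k = 5 clusters,
#' 75% subject bootstraps (40 replicates), 75% timepoint bootstraps
#' (10 replicates, 25 subjects), 16-voxel component pruning, +-1 z-score
#' significance threshold and candidate grid k = 2..7.
#'
#' @param phantom a \linkS4class{PhantomSpec} plus cohort size: list with
#'   elements `spec`, `nSubjects`, optional `ageGroups`; used when no file
#'   inputs are given.
#' @param inputs named list of file inputs: `boldPaths`, `tr`, `labelsPath`,
#'   `labelsLutPath`, `seedMaskPath`, `seedLutPath`, `roiConfigPath`,
#'   optional `metadata` (data.frame subjectId/ageGroup).
#' @param nDiscard,fwhmMm,cutoffHz preprocessing parameters.
#' @param k,kGrid cluster count and diagnostic grid.
#' @param fraction,nSubjectBootstraps,nTimepointBootstraps,timepointSubjects
#'   bootstrap parameters.
#' @param minComponent pruning threshold (voxels).
#' @param zThreshold cluster-profile significance threshold.
#' @param masterSeed master seed; all stage seeds derive from it.
#' @param outDir optional output directory; NULL keeps results in memory.
#' @return a validated config list of class `knitConfig`.
#' @export
knitConfig <- function(phantom = list(spec = phantomSpec(), nSubjects = 10L),
                       inputs = NULL, nDiscard = 5L, fwhmMm = 3,
                       cutoffHz = 0.08, k = 5L, kGrid = 2:7,
                       fraction = 0.75, nSubjectBootstraps = 40L,
                       nTimepointBootstraps = 10L, timepointSubjects = 25L,
                       minComponent = 16L, zThreshold = 1, masterSeed = 1L,
                       outDir = NULL) {
  cfg <- list(phantom = phantom, inputs = inputs, nDiscard = nDiscard,
              fwhmMm = fwhmMm, cutoffHz = cutoffHz, k = as.integer(k),
              kGrid = as.integer(kGrid), fraction = fraction,
              nSubjectBootstraps = as.integer(nSubjectBootstraps),
              nTimepointBootstraps = as.integer(nTimepointBootstraps),
              timepointSubjects = as.integer(timepointSubjects),
              minComponent = as.integer(minComponent),
              zThreshold = zThreshold, masterSeed = as.integer(masterSeed),
              outDir = outDir)
  class(cfg) <- "knitConfig"
  validateConfig(cfg)
  cfg
}

#' Validate a pipeline configuration before any compute
#'
#' @param cfg a `knitConfig` list.
#' @return invisibly TRUE; errors describe the offending field.
#' @export
validateConfig <- function(cfg) {
  if (cfg$k < 2L) stop("config: k must be >= 2")
  if (cfg$fraction <= 0 || cfg$fraction > 1)
    stop("config: fraction must lie in (0, 1]")
  if (cfg$nDiscard < 0L) stop("config: nDiscard must be >= 0")
  if (cfg$fwhmMm < 0) stop("config: fwhmMm must be >= 0")
  if (cfg$nSubjectBootstraps < 1L) stop("config: need >= 1 subject bootstrap")
  if (cfg$minComponent < 0L) stop("config: minComponent must be >= 0")
  if (is.null(cfg$phantom) && is.null(cfg$inputs))
    stop("config: either phantom or inputs must be given")
  if (!is.null(cfg$inputs)) {
    need <- c("boldPaths", "labelsPath", "labelsLutPath", "seedMaskPath",
              "seedLutPath", "roiConfigPath")
    for (f in need) {
      if (is.null(cfg$inputs[[f]]))
        stop(sprintf("config: inputs$%s is required", f))
    }
    paths <- c(cfg$inputs$boldPaths, cfg$inputs$labelsPath,
               cfg$inputs$labelsLutPath, cfg$inputs$seedMaskPath,
               cfg$inputs$seedLutPath, cfg$inputs$roiConfigPath)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("config: missing input file(s): %s",
                   paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

.stageLog <- function(run, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  message(line)
  c(run, line)
}

#' Run the full parcellation pipeline
#'
#' Stages: load-or-simulate, preprocess, per-subject FC, subjects-bootstrap
#' ensemble, majority-vote consensus with small-component pruning,
#' uncertainty map, the WTA baseline (same bootstrap subsets), and the
#' summary metrics. Any stage failure aborts with the stage name. With
#' `outDir` set, all volumes, tables, the serialized config and a manifest
#' (input checksums, package version, seeds) are written there.
#'
#' @param cfg a `knitConfig` from \code{\link{knitConfig}}.
#' @return (invisibly) a list with the truth (phantom runs), ensembles,
#'   consensus parcellations, uncertainty map, metrics and the log.
#' @export
runPipeline <- function(cfg) {
  validateConfig(cfg)
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    labels <- stage("load", readLabels(inp$labelsPath, inp$labelsLutPath))
    seedMask <- stage("load", readLabels(inp$seedMaskPath, inp$seedLutPath))
    roiset <- stage("load", loadRoiConfig(inp$roiConfigPath))
    meta <- inp$metadata
    if (is.null(meta))
      meta <- data.frame(subjectId = sprintf("sub-%03d",
                                             seq_along(inp$boldPaths)),
                         ageGroup = "group", stringsAsFactors = FALSE)
    cohort <- stage("load", lapply(seq_along(inp$boldPaths), function(i)
      readBold(inp$boldPaths[i], tr = inp$tr,
               subjectId = meta$subjectId[i], ageGroup = meta$ageGroup[i])))
    log <- .stageLog(log, "load", "%d subjects, %d ROIs",
                     length(cohort), length(roiset@ids))
  } else {
    spec <- cfg$phantom$spec
    truth <- stage("simulate", makePhantomAnatomy(spec))
    sim <- stage("simulate", simulateCohort(
      truth, spec, cfg$phantom$nSubjects,
      cohortSeed = childSeed(cfg$masterSeed, 101L),
      ageGroups = cfg$phantom$ageGroups %||% "group"))
    cohort <- sim$bold
    meta <- sim$metadata
    labels <- truth@roiParcels
    seedMask <- truth@seedMask
    roiset <- truth@roiset
    log <- .stageLog(log, "simulate", "%d subjects on %s grid, k_true=%d",
                     length(cohort), paste(spec@dims, collapse = "x"),
                     spec@kTrue)
  }
  for (b in cohort) assertSameGrid(b, labels, "BOLD and labels")

  # --- preprocess + FC ------------------------------------------------------
  analysisMask <- labels@data > 0L | seedMask@data > 0L
  cohort <- stage("preprocess", lapply(cohort, preprocessBold,
                                       nDiscard = cfg$nDiscard,
                                       fwhmMm = cfg$fwhmMm,
                                       cutoffHz = cfg$cutoffHz,
                                       mask = analysisMask))
  log <- .stageLog(log, "preprocess",
                   "discard=%d fwhm=%gmm lowpass=%gHz, %d timepoints kept",
                   cfg$nDiscard, cfg$fwhmMm, cfg$cutoffHz %||% NA,
                   nTimepoints(cohort[[1]]))
  pearson <- stage("fc", lapply(cohort, voxelRoiFC, seedMask = seedMask,
                                labels = labels, roiset = roiset))
  zprofiles <- stage("fc", lapply(pearson, fisherZ))
  log <- .stageLog(log, "fc", "%d seed voxels x %d ROIs per subject",
                   length(zprofiles[[1]]@voxels), length(roiset@ids))

  # --- KNIT ensemble + consensus -------------------------------------------
  ensemble <- stage("bootstrap", subjectsBootstrap(
    zprofiles, fraction = cfg$fraction,
    nBootstraps = cfg$nSubjectBootstraps, k = cfg$k,
    masterSeed = childSeed(cfg$masterSeed, 202L),
    affine = labels@affine))
  consensusRaw <- stage("consensus", majorityVote(ensemble))
  consensus <- stage("consensus", pruneSmallComponents(
    consensusRaw, minSize = cfg$minComponent))
  uncert <- stage("uncertainty", uncertaintyMap(ensemble, consensusRaw,
                                                nSubjectsNorm = length(cohort)))
  log <- .stageLog(log, "consensus", "k=%d, %d bootstraps, uBar=%.4f",
                   cfg$k, cfg$nSubjectBootstraps, uncert@uBar)

  # --- WTA baseline on the same bootstrap subsets ---------------------------
  lobeProfiles <- stage("wta", lapply(cohort, partialCorrLobes,
                                      seedMask = seedMask, labels = labels,
                                      roiset = roiset))
  wtaMembers <- stage("wta", lapply(seq_along(ensemble@subsets), function(b) {
    pick <- ensemble@subsets[[b]]
    vals <- Reduce(`+`, lapply(lobeProfiles[pick],
                               function(p) p@values)) / length(pick)
    lp <- methods::initialize(lobeProfiles[[1]], values = vals)
    parc <- wtaAssign(lp, affine = labels@affine)
    parc@bootstrapId <- b
    parc
  }))
  wtaEnsemble <- new("ParcellationEnsemble", members = wtaMembers,
                     scheme = "subjects", fraction = cfg$fraction,
                     subsets = ensemble@subsets, memberProfiles = list(),
                     masterSeed = childSeed(cfg$masterSeed, 202L))
  wtaConsensus <- stage("wta", pruneSmallComponents(
    majorityVote(wtaEnsemble), minSize = cfg$minComponent))
  log <- .stageLog(log, "wta", "5-lobe WTA consensus built")

  # --- metrics --------------------------------------------------------------
  groupProfile <- groupAverageProfiles(zprofiles)
  pooledPearson <- methods::initialize(
    groupProfile, values = tanh(groupProfile@values), scale = "pearson_r")
  metrics <- stage("metrics", list(
    volumesKnit = relativeVolumes(ensemble),
    volumesWta = relativeVolumes(wtaEnsemble),
    symmetryKnit = symmetryIndex(consensus, seedMask),
    symmetryWta = symmetryIndex(wtaConsensus, seedMask),
    clusterProfiles = clusterProfiles(ensemble, roiset,
                                      zThreshold = cfg$zThreshold),
    laterality = lateralityIndices(pooledPearson, seedMask, roiset),
    globalFc = globalThalamicConnectivity(pearson, roiset)))
  if (!is.null(truth)) {
    # ARI is invariant to label permutation, so no matching is needed here
    metrics$ariKnit <- parcellationARI(consensus, truth@trueParcellation@data,
                                       exclude = truth@borderVoxels)
    metrics$ariWta <- parcellationARI(wtaConsensus,
                                      truth@trueParcellation@data,
                                      exclude = truth@borderVoxels)
  }
  log <- .stageLog(log, "metrics", "symmetry knit=%.3f wta=%.3f",
                   metrics$symmetryKnit, metrics$symmetryWta)

  run <- list(config = cfg, truth = truth, metadata = meta,
              profiles = zprofiles, pearson = pearson,
              ensemble = ensemble, consensus = consensus,
              consensusRaw = consensusRaw, uncertainty = uncert,
              wtaEnsemble = wtaEnsemble, wtaConsensus = wtaConsensus,
              metrics = metrics, log = log)
  if (!is.null(cfg$outDir)) .writeRun(run, cfg$outDir)
  invisible(run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeParcellation(run$consensus, file.path(dir, "consensus_knit.nii.gz"))
  writeParcellation(run$wtaConsensus, file.path(dir, "consensus_wta.nii.gz"))
  .writeVolume(run$uncertainty@u, run$consensus@affine,
               file.path(dir, "uncertainty.nii.gz"), datatype = "float")
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  m <- run$metrics
  tsv(m$volumesKnit$table, "volumes_knit.tsv")
  tsv(m$volumesWta$table, "volumes_wta.tsv")
  tsv(data.frame(cluster = rownames(m$clusterProfiles$z) %||%
                   seq_len(nrow(m$clusterProfiles$z)),
                 m$clusterProfiles$z, check.names = FALSE),
      "cluster_profiles_z.tsv")
  tsv(data.frame(metric = c("symmetry_knit", "symmetry_wta", "uBar",
                            "Ri", "Rc"),
                 value = c(m$symmetryKnit, m$symmetryWta,
                           run$uncertainty@uBar,
                           m$laterality$Ri, m$laterality$Rc)),
      "summary_metrics.tsv")
  tsv(m$globalFc, "global_fc.tsv")
  cfgOut <- run$config
  cfgOut$phantom <- NULL   # not serializable as plain YAML; recorded below
  cfgOut$outDir <- NULL    # the directory the file sits in
  yaml::write_yaml(cfgOut[!vapply(cfgOut, is.null, TRUE)],
                   file.path(dir, "config.yaml"))
  inputFiles <- unlist(run$config$inputs[c("boldPaths", "labelsPath",
                                           "labelsLutPath", "seedMaskPath",
                                           "seedLutPath", "roiConfigPath")])
  manifest <- list(
    package = "knitparc",
    version = as.character(utils::packageVersion("knitparc")),
    masterSeed = run$config$masterSeed,
    k = run$config$k,
    nSubjects = nrow(run$metadata),
    phantom = !is.null(run$truth),
    inputChecksums = if (length(inputFiles))
      as.list(tools::md5sum(inputFiles)) else NULL,
    log = run$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Side-by-side comparison of KNIT and WTA on one run
#'
#' @param run result of \code{\link{runPipeline}}.
#' @return list with `report` (one row per method: k used, symmetry index,
#'   ARI against planted truth where available, largest relative cluster
#'   volume) and `volumes` (per-method mean relative volumes).
#' @export
compareMethods <- function(run) {
  if (is.null(run$consensus) || is.null(run$wtaConsensus))
    stop("run is missing one of the method outputs")
  m <- run$metrics
  report <- data.frame(
    method = c("knit", "wta"),
    k = c(run$consensus@k, run$wtaConsensus@k),
    symmetry = c(m$symmetryKnit, m$symmetryWta),
    ari = c(m$ariKnit %||% NA_real_, m$ariWta %||% NA_real_),
    largestVolume = c(max(m$volumesKnit$table$mean),
                      max(m$volumesWta$table$mean)))
  list(report = report,
       volumes = list(knit = m$volumesKnit$table, wta = m$volumesWta$table))
}
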