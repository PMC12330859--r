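# Bootstrap ensembles, uncertainty, CoV of IoU, silhouette, k selection.

test_that("subjects bootstrap draws ceiling(fraction N) and is deterministic", {
  fix <- tinyPhantom()
  profs <- lapply(1:8, function(i) {
    v <- profileValues(fix$z) + matrix(rnorm(length(fix$z@values), sd = 0.05),
                                       nrow = nrow(fix$z@values))
    methods::initialize(fix$z, values = v)
  })
  ens <- subjectsBootstrap(profs, fraction = 0.75, nBootstraps = 5L, k = 3L,
                           masterSeed = 17L, nInit = 4L)
  expect_true(all(lengths(ens@subsets) == 6L))   # ceiling(0.75 * 8)
  ens2 <- subjectsBootstrap(profs, fraction = 0.75, nBootstraps = 5L, k = 3L,
                            masterSeed = 17L, nInit = 4L)
  expect_identical(lapply(ensembleMembers(ens), volumeData),
                   lapply(ensembleMembers(ens2), volumeData))
  expect_error(subjectsBootstrap(profs, fraction = 0, k = 3, masterSeed = 1),
               "fraction")
})

test_that("fraction = 1 subject bootstraps collapse to identical members", {
  fix <- tinyPhantom()
  profs <- lapply(1:4, function(i) fix$z)
  ens <- subjectsBootstrap(profs, fraction = 1, nBootstraps = 6L, k = 3L,
                           masterSeed = 23L, nInit = 4L)
  labs <- lapply(ensembleMembers(ens), volumeData)
  for (l in labs[-1]) expect_identical(l, labs[[1]])
  cv <- covIoU(ens)
  expect_equal(cv$summary, 0)
})

test_that("timepoint bootstraps resample floor(fraction t) ordered timepoints", {
  fix <- cleanPhantom()
  cohort <- list(fix$bold, simulateSubject(fix$truth, fix$spec, 12L))
  ens <- timepointsBootstrap(cohort, fix$truth@seedMask,
                             fix$truth@roiParcels, fix$truth@roiset,
                             nSubjects = 2L, fraction = 0.75,
                             nBootstraps = 3L, k = 3L, masterSeed = 9L,
                             nInit = 3L)
  expect_true(all(lengths(ens@subsets) == floor(0.75 * 200)))
  expect_true(all(vapply(ens@subsets, function(s) !is.unsorted(s), TRUE)))
  # noise-free phantom: every member recovers the same parcellation
  labs <- lapply(ensembleMembers(ens), volumeData)
  for (l in labs[-1]) expect_identical(l, labs[[1]])
  expect_equal(covIoU(ens)$summary, 0)
  expect_error(
    timepointsBootstrap(cohort, fix$truth@seedMask, fix$truth@roiParcels,
                        fix$truth@roiset, nSubjects = 5L, k = 3,
                        masterSeed = 1L),
    "subjects")
})

test_that("uncertainty reproduces hand counts and the unanimity identity", {
  # 40 members: voxel 1 unanimous, voxel 2 split 25/15
  L <- rbind(rep(1L, 40), c(rep(1L, 25), rep(2L, 15)))
  ens <- mkEnsemble(L, k = 2)
  cons <- majorityVote(ens)
  um <- uncertaintyMap(ens, cons, nSubjectsNorm = 10L)
  u <- um@u[voxelIndices(um)]
  expect_equal(u[1], 0)
  expect_equal(u[2], 0.375)           # 1 - 25/40
  expect_equal(uBar(um), 0.375 / 10)
  expect_lte(max(u), 1 - 1 / 40)

  unan <- mkEnsemble(matrix(2L, 5, 8), k = 2)
  umu <- uncertaintyMap(unan, majorityVote(unan), nSubjectsNorm = 3L)
  expect_equal(uBar(umu), 0)
  expect_error(uncertaintyMap(ens, majorityVote(unan), 1L), "N_total")
})

test_that("CoV of IoU matches hand arithmetic on a 3-member toy ensemble", {
  # 10 voxels, k = 2
  m1 <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  m2 <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  m3 <- c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2)
  ens <- mkEnsemble(cbind(m1, m2, m3), k = 2)
  cv <- covIoU(ens)
  # hand: cluster 1 pair IoUs: (4/5, 2/5, 2/4); cluster 2: (5/6, 5/8, 6/8)
  iou1 <- c(4 / 5, 2 / 5, 2 / 4)
  iou2 <- c(5 / 6, 5 / 8, 6 / 8)
  expect_equal(sort(cv$iou$iou[cv$iou$cluster == 1]), sort(iou1))
  expect_equal(sort(cv$iou$iou[cv$iou$cluster == 2]), sort(iou2))
  expect_equal(cv$perCluster$cov,
               c(sd(iou1) / mean(iou1), sd(iou2) / mean(iou2)),
               tolerance = 1e-12)
  expect_equal(cv$summary,
               mean(c(sd(iou1) / mean(iou1), sd(iou2) / mean(iou2))),
               tolerance = 1e-12)
})

test_that("degenerate CoV cases are flagged, not silently numeric", {
  # two members only: single pair per cluster
  two <- mkEnsemble(cbind(c(1, 1, 2, 2), c(1, 1, 2, 2)), k = 2)
  cv <- covIoU(two)
  expect_true(all(cv$perCluster$degenerate))
  expect_equal(cv$perCluster$cov, c(0, 0))
  # disjoint cluster 1 across the pair: zero-mean IoU -> NA cov, flagged
  dis <- mkEnsemble(cbind(c(1, 2, 2, 2), c(2, 2, 2, 1)), k = 2)
  cvd <- covIoU(dis)
  expect_true(is.na(cvd$perCluster$cov[1]))
  expect_true(cvd$perCluster$degenerate[1])
  # a label empty in every member is excluded and reported
  no3 <- mkEnsemble(cbind(c(1, 1, 2, 2), c(1, 2, 2, 1)), k = 3)
  expect_equal(covIoU(no3)$excludedClusters, 3L)
  expect_error(covIoU(mkEnsemble(matrix(1L, 3, 1), k = 1)), "2 ensemble")
})

test_that("CoV of IoU is invariant to member order and global relabeling", {
  withr::with_seed(13, L <- matrix(sample.int(3, 120, replace = TRUE), 20))
  base <- covIoU(mkEnsemble(L, k = 3))$summary
  expect_equal(covIoU(mkEnsemble(L[, c(4, 2, 6, 1, 3, 5)], k = 3))$summary,
               base)
  perm <- c(3L, 1L, 2L)
  expect_equal(covIoU(mkEnsemble(matrix(perm[L], nrow(L)), k = 3))$summary,
               base)
})

test_that("silhouette separates tight orthogonal clusters and rejects k = 1", {
  vals <- rbind(matrix(rep(c(1, 0, 0), 30), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 1, 0), 30), ncol = 3, byrow = TRUE)) +
    matrix(rnorm(180, sd = 0.01), ncol = 3)
  pm <- mkProfiles(vals, scale = "fisher_z")
  arr <- array(0L, c(60, 1, 1))
  arr[1:60] <- rep(1:2, each = 30)
  expect_gt(silhouetteScore(pm, mkParc(arr, 2L)), 0.9)

  # labels orthogonal to the real two-cloud structure: each label holds half
  # of each cloud, so own-cluster distances exceed other-cluster distances
  # and the score is non-positive
  arr2 <- array(0L, c(60, 1, 1))
  arr2[1:60] <- rep(1:2, 30)
  expect_lte(silhouetteScore(pm, mkParc(arr2, 2L)), 0)
  arr3 <- array(1L, c(60, 1, 1))
  expect_error(silhouetteScore(pm, mkParc(arr3, 1L)), "2")
})

test_that("selectK reports one diagnostic row per candidate k", {
  fix <- tinyPhantom()
  profs <- lapply(1:5, function(i) {
    v <- profileValues(fix$z) + matrix(rnorm(length(fix$z@values), sd = 0.1),
                                       nrow = nrow(fix$z@values))
    methods::initialize(fix$z, values = v)
  })
  rep1 <- selectK(profs, kGrid = 2L, nBootstraps = 4L, masterSeed = 3L,
                  nInit = 3L)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$k, 2L)
  expect_true(is.finite(rep1$covIoUSubjects))
  expect_true(is.finite(rep1$silhouetteMean))
})
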