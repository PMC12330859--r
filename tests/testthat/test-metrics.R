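# Cluster characterization and developmental summary metrics.

test_that("cluster profiles take median-within, mean-across bootstraps", {
  # one bootstrap, one cluster of 3 voxels: median of (0.1, 0.2, 0.9) = 0.2
  vals <- cbind(c(0.1, 0.2, 0.9), c(0.5, 0.6, 0.7))
  prof <- mkProfiles(vals, scale = "fisher_z")
  arr <- array(0L, c(3, 1, 1)); arr[1:3] <- 1L
  member <- mkParc(arr, 2L)  # cluster 2 empty in every bootstrap -> error
  ens <- new("ParcellationEnsemble", members = list(member),
             scheme = "subjects", fraction = 1, subsets = list(1L),
             memberProfiles = list(prof), masterSeed = 1L)
  expect_error(clusterProfiles(ens, toyRoiSet()), "empty")

  arrB <- array(0L, c(3, 1, 1)); arrB[1:3] <- c(1L, 1L, 2L)
  ensB <- new("ParcellationEnsemble", members = list(mkParc(arrB, 2L)),
              scheme = "subjects", fraction = 1, subsets = list(1L),
              memberProfiles = list(prof), masterSeed = 1L)
  rs <- roiSet(ids = 1:2, hemisphere = c("mid", "mid"), lobe = c("none", "none"))
  cp <- clusterProfiles(ensB, rs)
  expect_equal(unname(cp$median[1, ]), c(median(c(0.1, 0.2)), 0.55))
  expect_equal(unname(cp$median[2, ]), c(0.9, 0.7))
  # z-profile is standardized across the ROI axis
  expect_equal(rowMeans(cp$z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(cp$z, 1, sd), c(1, 1), tolerance = 1e-12)
})

test_that("constant-across-ROI profiles make the z-score an explicit error", {
  vals <- matrix(0.3, 3, 2)
  prof <- mkProfiles(vals, scale = "fisher_z")
  arr <- array(0L, c(3, 1, 1)); arr[1:3] <- c(1L, 1L, 2L)
  ens <- new("ParcellationEnsemble", members = list(mkParc(arr, 2L)),
             scheme = "subjects", fraction = 1, subsets = list(1L),
             memberProfiles = list(prof), masterSeed = 1L)
  rs <- roiSet(ids = 1:2, hemisphere = c("mid", "mid"), lobe = c("none", "none"))
  expect_error(clusterProfiles(ens, rs), "zero variance")
})

test_that("significance flags follow the planted connectivity of a phantom", {
  fix <- tinyPhantom()
  profs <- lapply(1:4, function(i) {
    b <- simulateSubject(fix$truth, fix$spec, 300L + i)
    fisherZ(voxelRoiFC(b, fix$truth@seedMask, fix$truth@roiParcels,
                       fix$truth@roiset))
  })
  ens <- subjectsBootstrap(profs, nBootstraps = 4L, k = 3L, masterSeed = 5L,
                           nInit = 4L)
  cp <- clusterProfiles(ens, fix$truth@roiset)
  # each planted cluster loads one bilateral pair; that pair must be flagged
  w <- fix$spec@profileMatrix
  for (c in 1:3) {
    dominant <- which(w[c, ] == max(w[c, ]))
    flagged <- which(cp$connected[c, ])
    expect_true(length(flagged) > 0)
    expect_true(all(flagged %in% dominant) || all(dominant %in% flagged))
  }
})

test_that("relative volumes conserve mass and match hand arithmetic", {
  arr1 <- array(0L, c(10, 10, 1))
  arr1[1:100] <- c(rep(1L, 30), rep(2L, 70))
  m1 <- mkParc(arr1, 2L)
  rv1 <- relativeVolumes(list(m1))
  expect_equal(rv1$table$mean, c(0.3, 0.7))

  arr2 <- arr1; arr2[1:100] <- c(rep(1L, 50), rep(2L, 50))
  rv2 <- relativeVolumes(list(m1, mkParc(arr2, 2L)))
  expect_equal(rowSums(rv2$perMember), c(1, 1), tolerance = 1e-12)
  expect_equal(rv2$table$mean, c(0.4, 0.6))
  expect_equal(rv2$table$sd, c(0.1414, 0.1414), tolerance = 1e-3)
})

test_that("symmetry index hits the closed-form endpoints and the hand case", {
  dims <- c(4L, 3L, 1L)
  mkSeed <- function() {
    s <- array(0L, dims)
    s[1:2, , 1] <- 1L   # left
    s[3:4, , 1] <- 2L   # right
    labelVolume(s, lut = data.frame(id = 1:2, name = c("l", "r"),
                                    hemisphere = c("L", "R"),
                                    lobe_group = "none"))
  }
  seed <- mkSeed()
  symm <- array(0L, dims)
  symm[1:2, , 1] <- c(1L, 2L)
  symm[3:4, , 1] <- c(2L, 1L)   # mirror of the left half
  expect_equal(symmetryIndex(mkParc(symm, 2L), seed), 1)

  anti <- array(0L, dims)
  anti[1:2, , 1] <- 1L
  anti[3:4, , 1] <- 2L
  expect_equal(symmetryIndex(mkParc(anti, 2L), seed), 0)

  # hand-built: 6 voxels per side, 4 mirrored matches -> 4/6
  hand <- symm
  hand[1, 1, 1] <- 2L
  hand[2, 2, 1] <- 1L
  expect_equal(symmetryIndex(mkParc(hand, 2L), seed),
               0.5 * (4 / 6 + 4 / 6), tolerance = 1e-12)
  expect_equal(symmetryIndex(mkParc(hand, 2L), seed), 0.667, tolerance = 1e-3)

  # reflection invariance
  mirrored <- mkParc(knitparc:::mirrorVolume(hand, 1L), 2L)
  expect_equal(symmetryIndex(mirrored, seed),
               symmetryIndex(mkParc(hand, 2L), seed))
})

test_that("laterality indices satisfy their symmetry and scaling laws", {
  dims <- c(4L, 2L, 1L)
  seedArr <- array(0L, dims)
  seedArr[1:2, , 1] <- 1L; seedArr[3:4, , 1] <- 2L
  seed <- labelVolume(seedArr, lut = data.frame(
    id = 1:2, name = c("l", "r"), hemisphere = c("L", "R"),
    lobe_group = "none"))
  rs <- toyRoiSet()   # odd ids L, even ids R
  voxels <- which(seedArr > 0L)
  hemi <- seedArr[voxels]
  withr::with_seed(2, base <- matrix(runif(8 * 6, 0.1, 0.5), 8, 6))
  # exchange-symmetric FC: right rows are left rows with L/R columns swapped
  swap <- c(2, 1, 4, 3, 6, 5)
  base[hemi == 2L, ] <- base[hemi == 1L, swap]
  pm <- new("ProfileMap", voxels = as.integer(voxels), values = base,
            scale = "pearson_r", roiIds = rs@ids, dims = dims)
  li <- lateralityIndices(pm, seed, rs)
  expect_equal(li$Ri, 1, tolerance = 1e-12)
  expect_equal(li$Rc, 1, tolerance = 1e-12)

  doubled <- base
  doubled[hemi == 2L, ] <- pmin(2 * doubled[hemi == 2L, ], 1)
  pm2 <- methods::initialize(pm, values = doubled)
  li2 <- lateralityIndices(pm2, seed, rs)
  expect_equal(li2$Ri, 2, tolerance = 1e-12)
  expect_equal(li2$Rc, 2, tolerance = 1e-12)

  # swapping hemisphere labels of both seed and ROIs inverts the ratios
  seedSwap <- labelVolume(array(3L - seedArr, dims) %% 3L, lut = lutTable(seed))
  seedSwap@data[seedArr == 0L] <- 0L
  rsSwap <- roiSet(ids = rs@ids, hemisphere = c("R", "L")[match(rs@hemisphere,
                                                                c("L", "R"))],
                   lobe = rs@lobe,
                   pair = c(2L, 1L, 4L, 3L, 6L, 5L))
  li3 <- lateralityIndices(pm2, seedSwap, rsSwap)
  expect_equal(li3$Ri, 1 / li2$Ri, tolerance = 1e-12)
  expect_equal(li3$Rc, 1 / li2$Rc, tolerance = 1e-12)
})

test_that("global connectivity averages |FC| and merges bilateral pairs", {
  rs <- toyRoiSet()
  pm <- mkProfiles(matrix(-0.3, 5, 6))
  g <- globalThalamicConnectivity(list(pm), rs)
  expect_equal(g$fc, rep(0.3, 3))

  vals <- matrix(0, 5, 6)
  vals[, 1] <- 0.2; vals[, 2] <- 0.4   # pair (1, 2) -> merged 0.3
  g2 <- globalThalamicConnectivity(list(mkProfiles(vals)), rs)
  expect_equal(g2$fc[1], 0.3)
})

test_that("ROI-ROI matrices are symmetric with unit diagonal, and groups gate", {
  fix <- tinyPhantom()
  spec <- phantomSpec(dims = c(20L, 20L, 20L), nRois = 6L, kTrue = 3L,
                      profileMatrix = phantomProfileMatrix(3L, 6L),
                      nTimepoints = 120L, sharedSources = TRUE, seed = 2L)
  cohort <- simulateCohort(fix$truth, spec, 4L, 70L,
                           ageGroups = c("a", "a", "b", "b"))
  rr <- roiRoiConnectivity(cohort$bold, fix$truth@roiParcels,
                           fix$truth@roiset, cohort$metadata,
                           groupOrder = c("a", "b"), nSubjects = 2L)
  M <- rr$matrices[["a"]]
  expect_equal(dim(M), c(6L, 6L))
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(unname(diag(M)), rep(1, 6))
  expect_equal(names(rr$differences), "b-a")
  expect_equal(rr$differences[["b-a"]], rr$matrices[["b"]] - rr$matrices[["a"]])
  expect_true(all(rr$global >= 0))
  # L/R pair members share one source here: their entry beats all entries
  # between ROIs with independent sources
  indep <- c(M[1, 3], M[1, 4], M[1, 5], M[1, 6], M[3, 5], M[3, 6])
  expect_gt(M[1, 2], max(indep))
  expect_gt(M[3, 4], max(indep))
  expect_error(
    roiRoiConnectivity(cohort$bold, fix$truth@roiParcels, fix$truth@roiset,
                       cohort$metadata, nSubjects = 3L),
    "need 3")
})
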