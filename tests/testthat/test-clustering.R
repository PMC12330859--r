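# Spherical k-means, WTA, Hungarian matching, consensus, pruning.

test_that("spherical k-means separates orthogonal directions perfectly", {
  vals <- rbind(matrix(rep(c(0.9, 0, 0), 100), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 0.9, 0), 100), ncol = 3, byrow = TRUE))
  vals <- vals + matrix(rnorm(600, sd = 1e-3), ncol = 3)
  p <- knitCluster(mkProfiles(vals), k = 2, seed = 3)
  lab <- volumeData(p)[1:200]
  expect_equal(length(unique(lab[1:100])), 1L)
  expect_equal(length(unique(lab[101:200])), 1L)
  expect_false(lab[1] == lab[101])
})

test_that("cosine clustering is scale-invariant and k is capped by directions", {
  x <- c(0.12, 0.16, 0)
  vals <- matrix(rep(c(1, 2, 5), each = 3), 9, 1) %*% matrix(x, 1, 3)
  p1 <- knitCluster(mkProfiles(vals), k = 1, seed = 1)
  expect_equal(unique(volumeData(p1)[1:9]), 1L)
  expect_error(knitCluster(mkProfiles(vals), k = 2, seed = 1),
               "distinct profile directions")
})

test_that("the k-means objective is non-increasing and zero-norm rows sit out", {
  fix <- tinyPhantom()
  vals <- profileValues(fix$z)
  vals[3, ] <- 0
  pm <- methods::initialize(fix$z, values = vals)
  p <- knitCluster(pm, k = 3, seed = 11)
  tr <- attr(p, "objectiveTrace")
  expect_true(all(diff(tr) <= 1e-9))
  expect_equal(volumeData(p)[voxelIndices(pm)[3]], 0L)
  expect_true(all(volumeData(p)[voxelIndices(pm)[-3]] > 0L))
})

test_that("knitCluster is deterministic given its seed", {
  fix <- tinyPhantom()
  p1 <- knitCluster(fix$z, k = 3, seed = 21)
  p2 <- knitCluster(fix$z, k = 3, seed = 21)
  expect_identical(volumeData(p1), volumeData(p2))
})

test_that("WTA takes the argmax with ties to the earlier lobe", {
  vals <- rbind(c(0.1, 0.5, 0.2, 0.0, -0.1),
                c(0.3, 0.3, 0.0, 0.0, 0.0))
  lp <- new("LobeProfileMap", voxels = 1:2, values = vals,
            lobes = c("temporal", "parietal", "frontal", "occipital",
                      "limbic"),
            dims = c(2L, 1L, 1L))
  p <- wtaAssign(lp)
  expect_equal(volumeData(p)[1:2], c(2L, 1L))
})

test_that("WTA is invariant to monotone transforms of a voxel's profile", {
  withr::with_seed(8, vals <- matrix(runif(50, -0.5, 0.5), 10, 5))
  lp <- new("LobeProfileMap", voxels = 1:10, values = vals,
            lobes = letters[1:5], dims = c(10L, 1L, 1L))
  p1 <- wtaAssign(lp)
  lp2 <- methods::initialize(lp, values = tanh(3 * vals))  # strictly monotone
  expect_identical(volumeData(wtaAssign(lp2)), volumeData(p1))
})

test_that("Hungarian label matching undoes a permutation and fixes identity", {
  fix <- tinyPhantom()
  ref <- knitCluster(fix$z, k = 3, seed = 5)
  perm <- c(3L, 1L, 2L)
  arr <- volumeData(ref)
  arr[arr > 0L] <- perm[arr[arr > 0L]]
  shuffled <- methods::initialize(ref, data = arr)
  expect_identical(volumeData(matchLabels(shuffled, ref)), volumeData(ref))
  expect_identical(volumeData(matchLabels(ref, ref)), volumeData(ref))
  bad <- methods::initialize(ref, data = array(0L, dim(volumeData(ref))))
  expect_error(matchLabels(bad, ref), "mask")
})

test_that("Hungarian matching equals exhaustive search on random instances", {
  withr::with_seed(42, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      n <- 200L
      a <- sample.int(k, n, replace = TRUE)
      b <- sample.int(k, n, replace = TRUE)
      dims <- c(n, 1L, 1L)
      arrA <- array(0L, dims); arrA[1:n] <- a
      arrB <- array(0L, dims); arrB[1:n] <- b
      matched <- matchLabels(mkParc(arrA, k), mkParc(arrB, k))
      agree <- sum(volumeData(matched)[1:n] == b)
      expect_equal(agree, bruteForceMatch(a, b, k))
    }
  })
})

test_that("majority vote returns the member on unanimous ensembles", {
  withr::with_seed(3, lab <- sample.int(4, 30, replace = TRUE))
  ens <- mkEnsemble(matrix(lab, 30, 7), k = 4)
  cons <- majorityVote(ens)
  expect_equal(volumeData(cons)[1:30], lab)
  expect_equal(cons@nTotal, 7L)
})

test_that("majority vote counts votes and breaks ties toward smaller ids", {
  L <- cbind(matrix(1L, 2, 25), matrix(2L, 2, 15))   # 25 vs 15
  L[2, ] <- c(rep(1L, 20), rep(2L, 20))              # exact 20/20 tie
  cons <- majorityVote(mkEnsemble(L, k = 2))
  expect_equal(volumeData(cons)[1:2], c(1L, 1L))
  expect_equal(cons@voteCounts[1, ], c(25, 15))
  expect_equal(cons@voteCounts[2, ], c(20, 20))
  # permuting member order changes nothing
  cons2 <- majorityVote(mkEnsemble(L[, sample.int(40)], k = 2))
  expect_identical(volumeData(cons2), volumeData(cons))
})

test_that("small surrounded components are absorbed at the stated threshold", {
  base <- array(0L, c(12, 12, 12))
  base[2:11, 2:11, 2:11] <- 1L
  mk <- function(islandDims) {
    arr <- base
    arr[4:(3 + islandDims[1]), 4:(3 + islandDims[2]), 4:(3 + islandDims[3])] <- 2L
    mkParc(arr, 2L)
  }
  p15 <- mk(c(5, 3, 1))    # 15-voxel island inside cluster 1
  pr15 <- pruneSmallComponents(p15, 16L)
  expect_true(all(volumeData(pr15)[volumeData(p15) == 2L] == 1L))

  p16 <- mk(c(4, 4, 1))    # exactly 16: boundary of "less than 16"
  pr16 <- pruneSmallComponents(p16, 16L)
  expect_identical(volumeData(pr16), volumeData(p16))

  # idempotence and label conservation
  expect_identical(volumeData(pruneSmallComponents(pr15, 16L)),
                   volumeData(pr15))
  expect_true(all(volumeData(pr15) %in% c(0L, 1L)))
})

test_that("components not dominantly surrounded are left untouched", {
  arr <- array(0L, c(10, 10, 10))
  arr[2:9, 2:9, 2:5] <- 1L
  arr[2:9, 2:9, 6:9] <- 2L
  # a small cluster-3 plate at the 1/2 interface: neighbors split evenly
  arr[4:6, 4:6, 5:6] <- 3L
  p <- mkParc(arr, 3L)
  pr <- pruneSmallComponents(p, 16L + 3L)
  expect_true(any(volumeData(pr) == 3L))
})
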