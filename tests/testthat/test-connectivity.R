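# FC profiles, Fisher-Z, group averaging, partial correlations.

test_that("roiMeanSeries averages voxel series and rejects empty ROIs", {
  arr <- array(0, c(3, 1, 1, 4))
  arr[1, 1, 1, ] <- 1:4
  arr[2, 1, 1, ] <- 1:4
  arr[3, 1, 1, ] <- c(9, 9, 9, 9)
  lab <- labelVolume(array(c(1L, 1L, 2L), c(3, 1, 1)),
                     lut = data.frame(id = 1:2, name = c("a", "b"),
                                      hemisphere = "mid", lobe_group = "none"))
  b <- boldSeries(arr, tr = 1)
  expect_equal(roiMeanSeries(b, lab, 1L), as.numeric(1:4))
  expect_equal(roiMeanSeries(b, lab, 2L), rep(9, 4))
  expect_error(roiMeanSeries(b, lab, 7L), "empty")
})

test_that("voxel-ROI FC hits the exact correlation on degenerate designs", {
  t <- 20L
  x <- rnorm(t)
  arr <- array(rnorm(4 * t, sd = 1), c(4, 1, 1, t))
  arr[1, 1, 1, ] <- x          # seed voxel
  arr[2, 1, 1, ] <- x          # ROI 1: identical
  arr[3, 1, 1, ] <- -x         # ROI 2: negated
  seed <- array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1))
  lab <- labelVolume(array(c(0L, 1L, 2L, 0L), c(4, 1, 1)))
  rs <- roiSet(ids = 1:2, hemisphere = c("mid", "mid"),
               lobe = c("none", "none"))
  prof <- voxelRoiFC(boldSeries(arr, tr = 1), seed, lab, rs)
  expect_equal(profileValues(prof)[1, ], c(1, -1), tolerance = 1e-12)
})

test_that("independent white-noise series correlate near zero at t = 2295", {
  t <- 2295L
  withr::with_seed(99, {
    r <- sapply(1:200, function(i) cor(rnorm(t), rnorm(t)))
  })
  # null sd ~ 1/sqrt(t) ~ 0.021, so |r| < 0.05 with probability > 0.95
  expect_gt(mean(abs(r) < 0.05), 0.9)
})

test_that("FC profiles are invariant to positive rescaling of a voxel series", {
  fix <- cleanPhantom()
  truth <- fix$truth
  b2 <- fix$bold
  d <- volumeData(b2)
  v <- voxelIndices(fix$pearson)[1]
  ijk <- arrayInd(v, dim(d)[1:3])
  d[ijk[1], ijk[2], ijk[3], ] <- 7.3 * d[ijk[1], ijk[2], ijk[3], ]
  p2 <- voxelRoiFC(boldSeries(d, tr = b2@tr, affine = b2@affine),
                   truth@seedMask, truth@roiParcels, truth@roiset)
  expect_equal(profileValues(p2)[1, ], profileValues(fix$pearson)[1, ],
               tolerance = 1e-12)
})

test_that("fisherZ matches the closed form, is odd, and clips at the boundary", {
  r <- c(0, 0.5, -0.5, 0.9)
  pm <- mkProfiles(matrix(r, 1))
  z <- profileValues(fisherZ(pm))[1, ]
  expect_equal(z, 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  expect_equal(z[2], 0.549306, tolerance = 1e-6)
  expect_equal(z[3], -z[2], tolerance = 1e-12)

  pm1 <- mkProfiles(matrix(c(1, -1), 1))
  expect_message(zc <- fisherZ(pm1), "clipped 2")
  expect_true(all(is.finite(profileValues(zc))))
  expect_error(fisherZ(zc), "pearson_r")
})

test_that("group averaging is the identity on one subject and cancels z, -z", {
  z <- mkProfiles(matrix(rnorm(12), 4), scale = "fisher_z")
  expect_equal(profileValues(groupAverageProfiles(list(z))),
               profileValues(z))
  zneg <- methods::initialize(z, values = -profileValues(z))
  expect_equal(profileValues(groupAverageProfiles(list(z, zneg))),
               matrix(0, 4, 3), tolerance = 1e-15)
  zb <- methods::initialize(z, voxels = 5:8)
  expect_error(groupAverageProfiles(list(z, zb)), "share")
  # weighted: weight 3:1 equals the affine combination
  expect_equal(profileValues(groupAverageProfiles(list(z, zneg),
                                                  weights = c(3, 1))),
               0.5 * profileValues(z), tolerance = 1e-12)
})

test_that("pooling subjects tightens profile recovery (variance reduction)", {
  fix <- tinyPhantom()
  truth <- fix$truth
  spec <- fix$spec
  w <- spec@profileMatrix / sqrt(rowSums(spec@profileMatrix^2))
  labs <- volumeData(truth@trueParcellation)[voxelIndices(fix$z)]
  interior <- !(voxelIndices(fix$z) %in% truth@borderVoxels)
  cosTo <- function(vals) {
    mean(rowSums((vals / sqrt(rowSums(vals^2))) * w[labs, ])[interior])
  }
  profs <- lapply(1:6, function(i) {
    b <- simulateSubject(truth, spec, 100L + i)
    fisherZ(voxelRoiFC(b, truth@seedMask, truth@roiParcels, truth@roiset))
  })
  single <- sapply(profs, function(p) cosTo(profileValues(p)))
  pooled <- cosTo(profileValues(groupAverageProfiles(profs)))
  expect_gte(pooled, stats::median(single))
})

test_that("partial correlation isolates the driving lobe and flags rank loss", {
  t <- 500L
  withr::with_seed(5, {
    L <- matrix(rnorm(t * 5), t, 5)           # independent lobe series
    vox <- L[, 2] + rnorm(t)                  # driven by lobe 2 only
    orth <- rnorm(t)
  })
  resid <- function(y, X) stats::lm.fit(cbind(1, X), y)$residuals
  pc <- sapply(1:5, function(l)
    cor(resid(vox, L[, -l]), resid(L[, l], L[, -l])))
  expect_equal(which.max(pc), 2L)
  expect_gt(pc[2], 5 * max(abs(pc[-2])))
  pcOrth <- sapply(1:5, function(l)
    cor(resid(orth, L[, -l]), resid(L[, l], L[, -l])))
  expect_lt(max(abs(pcOrth)), 0.15)
})

test_that("partialCorrLobes matches the residualization oracle on a phantom", {
  fix <- cleanPhantom()
  truth <- fix$truth
  lob <- partialCorrLobes(fix$bold, truth@seedMask, truth@roiParcels,
                          truth@roiset)
  # oracle: explicit lm-based residualization for one voxel
  lobes <- lobeGroups(truth@roiset)
  lobes <- lobes[lengths(lobes) > 0]
  d <- volumeData(fix$bold)
  X <- matrix(d, nrow = prod(dim(d)[1:3]))
  L <- sapply(lobes, function(ids)
    colMeans(X[which(volumeData(truth@roiParcels) %in% ids), , drop = FALSE]))
  v <- voxelIndices(lob)[17]
  resid <- function(y, Z) stats::lm.fit(cbind(1, Z), y)$residuals
  want <- sapply(seq_along(lobes), function(l)
    cor(resid(X[v, ], L[, -l]), resid(L[, l], L[, -l])))
  expect_equal(profileValues(lob)[17, ], want, tolerance = 1e-8,
               ignore_attr = TRUE)

  # duplicated lobe series are rank-deficient
  labArr <- volumeData(truth@roiParcels)
  labArr[labArr == 3L] <- 1L
  labArr[labArr == 4L] <- 2L  # lobe 2's ROIs now duplicate lobe 1's voxels
  expect_error(
    partialCorrLobes(fix$bold, truth@seedMask,
                     labelVolume(labArr, lut = lutTable(truth@roiParcels),
                                 affine = truth@roiParcels@affine),
                     truth@roiset),
    "empty|rank")
})
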