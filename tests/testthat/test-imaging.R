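# Segmentation, surface extraction, signed distance fields and the alert cloud.

test_that("threshold segmentation recovers the exact structure set on noiseless volumes", {
  spec <- pipeSpec()
  model <- buildPhantom("S1", spec)
  vol <- synthesizeVolume(model)
  seg <- segmentByThreshold(vol, 800)
  truth <- voxelValues(tumorMask(model)) | voxelValues(icaMask(model))
  expect_identical(voxelValues(seg), truth)
})

test_that("a threshold outside the intensity range is rejected", {
  spec <- pipeSpec()
  vol <- synthesizeVolume(buildPhantom("S1", spec))
  expect_error(segmentByThreshold(vol, 1e9), "outside intensity range")
})

test_that("refined segmentation of a noisy volume reaches Dice >= 0.95", {
  spec <- testSpec()
  model <- buildPhantom("S2", spec)
  set.seed(3)
  contrast <- spec@intensities[["tumor"]] - spec@intensities[["bone"]]
  vol <- synthesizeVolume(model, noiseSd = 0.1 * contrast)
  seg <- segmentByThreshold(vol, 800, refineRadius = 1.6, minVolume = 10)
  truth <- voxelValues(tumorMask(model)) | voxelValues(icaMask(model))
  dice <- 2 * sum(voxelValues(seg) & truth) /
    (sum(voxelValues(seg)) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("segmentation is idempotent on a noiseless re-synthesis", {
  spec <- pipeSpec()
  model <- buildPhantom("S3", spec)
  seg1 <- segmentByThreshold(synthesizeVolume(model), 800)
  # re-synthesize an intensity volume from the segmented mask and re-segment
  vol2 <- new("ScanVolume", dims = seg1@dims, spacing = seg1@spacing,
              origin = seg1@origin,
              values = array(ifelse(voxelValues(seg1), 1200, 0),
                             dim = gridDims(seg1)))
  seg2 <- segmentByThreshold(vol2, 600)
  expect_identical(voxelValues(seg2), voxelValues(seg1))
})

test_that("isosurfaces are watertight with volumes matching the voxel count", {
  sm <- sphereMask(10)
  mesh <- extractSurface(sm$mask)
  expect_true(isWatertight(mesh))
  expect_lt(abs(meshVolume(mesh) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3),
            0.05)
  voxVol <- sum(voxelValues(sm$mask)) * prod(gridSpacing(sm$mask))
  expect_lt(abs(meshVolume(mesh) - voxVol) / voxVol, 0.05)
})

test_that("a single-voxel mask yields a closed mesh with nonzero volume", {
  m <- new("LabelMask", dims = c(8L, 8L, 8L), spacing = rep(1, 3),
           origin = c(0, 0, 0), values = array(FALSE, c(8, 8, 8)))
  m@values[4, 4, 4] <- TRUE
  mesh <- extractSurface(m)
  expect_true(isWatertight(mesh))
  expect_gt(meshVolume(mesh), 0)
})

test_that("the carotid mask isosurface is watertight", {
  mesh <- extractSurface(icaMask(testModel("S3")))
  expect_true(isWatertight(mesh))
})

test_that("empty masks are rejected by surface extraction and distance fields", {
  m <- new("LabelMask", dims = c(8L, 8L, 8L), spacing = rep(1, 3),
           origin = c(0, 0, 0), values = array(FALSE, c(8, 8, 8)))
  expect_error(extractSurface(m), "empty")
  expect_error(signedDistance(m), "empty")
  m@values[] <- TRUE
  expect_error(signedDistance(m), "full")
})

test_that("signed distance matches the analytic value at a sphere center", {
  sm <- sphereMask(5)
  f <- signedDistance(sm$mask)
  d <- distanceAt(f, matrix(sm$center, 1))
  expect_lt(abs(d - (-5)), 0.4) # half a voxel
})

test_that("sphere radii 3-15 mm are recovered within one voxel", {
  for (r in c(3, 8, 15)) {
    sm <- sphereMask(r)
    f <- signedDistance(sm$mask)
    expect_lt(abs(distanceAt(f, matrix(sm$center, 1)) + r), 0.8,
              label = paste("radius", r))
  }
})

test_that("signed distance sign matches mask membership everywhere", {
  set.seed(21)
  v <- array(runif(10^3) < 0.4, c(10, 10, 10))
  v[5, 5, 5] <- TRUE; v[1, 1, 1] <- FALSE
  m <- new("LabelMask", dims = c(10L, 10L, 10L), spacing = rep(1.1, 3),
           origin = c(0, 0, 0), values = v)
  f <- signedDistance(m)
  expect_true(all(voxelValues(f)[v] < 0))
  expect_true(all(voxelValues(f)[!v] > 0))
})

test_that("signed distance equals the brute-force opposite-class minimum", {
  set.seed(8)
  dims <- c(12L, 12L, 12L)
  v <- array(runif(prod(dims)) < 0.3, dims)
  v[6, 6, 6] <- TRUE; v[1, 1, 1] <- FALSE
  m <- new("LabelMask", dims = dims, spacing = c(0.7, 1.1, 0.9),
           origin = c(0, 0, 0), values = v)
  f <- signedDistance(m)
  expect_lt(max(abs(voxelValues(f) - bruteForceSignedEDT(m))), 1e-6)
})

test_that("Euclidean-ball dilation equals thresholding the distance transform", {
  set.seed(13)
  dims <- c(14L, 14L, 14L)
  v <- array(runif(prod(dims)) < 0.08, dims)
  v[7, 7, 7] <- TRUE
  m <- new("LabelMask", dims = dims, spacing = rep(0.8, 3),
           origin = c(0, 0, 0), values = v)
  for (r in c(1.2, 2)) {
    dil <- NaviMargin:::.dilateMask(m, r)
    expect_identical(voxelValues(dil), bruteForceDilate(m, r),
                     label = paste("radius", r))
  }
})

test_that("the alert cloud offset surface sits at the margin from the vessel", {
  cyl <- cylinderMask()
  cloud <- buildAlertCloud(cyl$mask, 2)
  vesselSurf <- extractSurface(cyl$mask)
  V <- meshVertices(cloud@surfaceMesh)
  offs <- pointsToMeshDistance(V, vesselSurf)
  expect_lt(abs(mean(offs) - 2), 0.4) # half a voxel
  # offset surface radius ~ 4.5 mm over the mid-section
  mid <- V[V[, 3] > 10 & V[, 3] < 28, ]
  radii <- sqrt((mid[, 1] - cyl$axis[1])^2 + (mid[, 2] - cyl$axis[2])^2)
  expect_lt(abs(mean(radii) - 4.5), 0.4)
})

test_that("every alert-cloud voxel lies strictly outside the vessel within the margin", {
  sm <- sphereMask(4)
  cloud <- buildAlertCloud(sm$mask, 2)
  f <- signedDistance(sm$mask)
  idx <- which(voxelValues(cloud@mask))
  co <- sweep(arrayInd(idx, gridDims(sm$mask)) - 1, 2,
              gridSpacing(sm$mask), "*")
  d <- distanceAt(f, co)
  expect_true(all(d > 0))
  expect_true(all(d <= 2 + 0.4))
})

test_that("alert cloud margin validation behaves as specified", {
  sm <- sphereMask(4)
  expect_error(buildAlertCloud(sm$mask, 0), "positive")
  expect_warning(buildAlertCloud(sm$mask, 0.5), "spacing")
})
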