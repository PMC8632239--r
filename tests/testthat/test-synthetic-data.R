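# Phantom generation, volume synthesis and the surgeon-behavior sampler.

test_that("realized tumor-carotid clearances match the preset table at mesh level", {
  expected <- c(S1 = 14.9, S2 = 10.2, S3 = 6.2, S4 = 3.5)
  for (id in names(expected)) {
    model <- buildPhantom(id, voxelize = FALSE)
    expect_lt(abs(measureClearance(model) - expected[[id]]), 0.1,
              label = paste("clearance error", id))
    expect_equal(presetOf(model)@tcClearance, expected[[id]])
  }
})

test_that("voxelized clearance agrees with the mesh-level value within a voxel diagonal", {
  for (id in c("S1", "S4")) {
    model <- testModel(id)
    f <- testFields(id)
    # closest approach of the carotid surface to the tumor, via the tumor
    # distance field sampled on the ICA surface mesh
    surf <- extractSurface(icaMask(model))
    dmin <- min(distanceAt(f$tumor, meshVertices(surf)))
    diagLen <- sqrt(sum(gridSpacing(model@masks$tumor)^2))
    expect_lt(abs(dmin - presetOf(model)@tcClearance), diagLen)
  }
})

test_that("sub-voxel clearance is rejected as unrepresentable", {
  p <- phantomPreset("custom", tcClearance = 0.05)
  expect_error(buildPhantom(p, volumeSpec()), "configuration error")
})

test_that("synthesized volume has the configured grid and exact material map", {
  spec <- pipeSpec()
  model <- buildPhantom("S2", spec)
  vol <- synthesizeVolume(model)
  expect_identical(gridDims(vol), gridDims(spec))
  ii <- spec@intensities
  # material priority: carotid voxels keep the carotid intensity
  expect_true(all(voxelValues(vol)[voxelValues(icaMask(model))] == ii[["ica"]]))
  # midpoint threshold recovers exactly tumor + carotid
  seg <- segmentByThreshold(vol, mean(ii[c("bone", "tumor")]))
  truth <- voxelValues(tumorMask(model)) | voxelValues(icaMask(model))
  expect_identical(voxelValues(seg), truth)
})

test_that("a model with empty masks synthesizes a uniform background volume", {
  spec <- pipeSpec()
  model <- buildPhantom("S1", spec)
  for (nm in names(model@masks))
    model@masks[[nm]]@values[] <- FALSE
  vol <- synthesizeVolume(model)
  expect_true(all(voxelValues(vol) == spec@intensities[["background"]]))
})

test_that("a structure exceeding the field of view is reported by name", {
  small <- volumeSpec(dims = c(64L, 64L, 48L), spacing = 1.6)
  model <- buildPhantom("S1", volumeSpec(), voxelize = FALSE)
  expect_error(synthesizeVolume(model, small), "field of view")
})

test_that("zero-noise ideal poses give clear-margin, carotid-sparing maps on every preset", {
  for (id in c("S1", "S2", "S3", "S4")) {
    f <- testFields(id)
    for (portion in c("superior", "inferior")) {
      pose <- idealPose(testModel(id), portion)
      map <- evaluatePlane(pose, f$tumor, f$ica)
      expect_false(any(map@zone == "R"), label = paste(id, portion, "no R"))
      s <- summarizePlane(map)
      expect_false(planeFlags(s)[["intratumoral"]],
                   label = paste(id, portion, "clear margin"))
      expect_false(planeFlags(s)[["icaDamaged"]])
    }
  }
})

test_that("zero-noise behavior reproduces the ideal pose exactly", {
  model <- testModel("S3")
  b <- behaviorModel("tumor_guided", rotSd = 0, transSd = 0)
  set.seed(11)
  pose <- samplePointerPose(model, b, "superior")
  ideal <- idealPose(model, "superior")
  expect_equal(pose@tip, ideal@tip, tolerance = 1e-12)
  expect_equal(pose@shaftAxis, ideal@shaftAxis, tolerance = 1e-12)
  expect_equal(pose@roll, ideal@roll, tolerance = 1e-9)
})

test_that("pose sampling is reproducible under a fixed seed", {
  model <- testModel("S3")
  b <- defaultBehavior("unguided")
  set.seed(99); p1 <- samplePointerPose(model, b, "inferior")
  set.seed(99); p2 <- samplePointerPose(model, b, "inferior")
  expect_identical(p1@tip, p2@tip)
  expect_identical(p1@roll, p2@roll)
  expect_identical(p1@angulation, p2@angulation)
})

test_that("unguided poses breach the carotid more often than tumor-guided on S4", {
  model <- testModel("S4")
  f <- testFields("S4")
  frac <- sapply(c("unguided", "tumor_guided"), function(setting) {
    b <- defaultBehavior(setting)
    set.seed(202)
    hits <- replicate(500, {
      pose <- samplePointerPose(model, b, "superior")
      pts <- isolateArea(pose, planeSamplingSpec(step = 1))
      any(distanceAt(f$ica, pts) <= 0)
    })
    mean(hits)
  })
  expect_gt(frac[["unguided"]], frac[["tumor_guided"]])
})

test_that("the study runner produces the full factorial and is byte-reproducible", {
  spec <- testSpec()
  presets <- list("S1", "S4")
  r1 <- simulateStudy(presets, nSurgeons = 2, seed = 5, spec = spec)
  expect_length(r1, 2 * 2 * 3 * 2)
  df1 <- recordsTable(r1)
  expect_setequal(unique(df1$setting),
                  c("unguided", "tumor_guided", "carotid_guided"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeRecordsCsv(r1, f1)
  r2 <- simulateStudy(presets, nSurgeons = 2, seed = 5, spec = spec)
  writeRecordsCsv(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # zone fractions are proper distributions
  expect_true(all(abs(rowSums(df1[paste0("pct_", zoneCodes())]) - 100) < 1e-6))
})

test_that("adding surgeons does not perturb existing surgeons' streams", {
  spec <- testSpec()
  r2 <- simulateStudy(list("S1"), nSurgeons = 1, seed = 5, spec = spec)
  r3 <- simulateStudy(list("S1"), nSurgeons = 2, seed = 5, spec = spec)
  df2 <- recordsTable(r2)
  df3 <- recordsTable(r3)
  df3 <- df3[df3$surgeonId == 1L, ]
  rownames(df3) <- NULL
  expect_equal(df2, df3)
})

test_that("an empty preset list is rejected", {
  expect_error(simulateStudy(list(), nSurgeons = 1), "empty preset list")
})
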