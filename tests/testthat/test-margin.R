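# Cutting-plane isolation, zone classification, plane summaries, alerts
# and the rendered color map.

test_that("the default sampling window is a 61 x 23 coplanar lattice", {
  pose <- pointerPose(c(10, 20, 30), c(0, 0, 1), roll = 25)
  pts <- isolateArea(pose)
  expect_identical(attr(pts, "lattice"), c(61L, 23L))
  expect_equal(nrow(pts), 61 * 23)
  fr <- poseFrame(pose)
  offs <- sweep(pts, 2, pose@tip)
  expect_lt(max(abs(offs %*% fr$normal)), 1e-9) # coplanar
  expect_true(all(offs %*% fr$shaft >= -1e-9 & offs %*% fr$shaft <= 30 + 1e-9))
})

test_that("a window with step = length = halfWidth collapses to 2 x 3 points", {
  pose <- pointerPose(c(0, 0, 0), c(1, 0, 0))
  pts <- isolateArea(pose, planeSamplingSpec(2, 2, 2))
  expect_identical(attr(pts, "lattice"), c(2L, 3L))
})

test_that("rolling 180 degrees mirrors the lattice across the shaft line", {
  p0 <- pointerPose(c(1, 2, 3), c(0, 1, 0), roll = 30)
  p1 <- pointerPose(c(1, 2, 3), c(0, 1, 0), roll = 210)
  a <- isolateArea(p0, planeSamplingSpec(4, 2, 1))
  b <- isolateArea(p1, planeSamplingSpec(4, 2, 1))
  lat <- attr(a, "lattice")
  am <- array(a, c(lat, 3)); bm <- array(b, c(lat, 3))
  expect_equal(am, bm[, rev(seq_len(lat[2])), , drop = FALSE],
               tolerance = 1e-9)
})

test_that("zone codes follow the joint-distance definitions", {
  cases <- rbind(
    data.frame(dIca = -0.5, dTumor = 7.0, zone = "R"),
    data.frame(dIca = 1.5, dTumor = 7.0, zone = "O3"),
    data.frame(dIca = 3.0, dTumor = 7.5, zone = "G"),
    data.frame(dIca = 3.0, dTumor = -0.2, zone = "Y1"),
    data.frame(dIca = 1.5, dTumor = -0.1, zone = "O1"),
    data.frame(dIca = 1.5, dTumor = 3.0, zone = "O2"),
    data.frame(dIca = 1.5, dTumor = 11.0, zone = "O4"),
    data.frame(dIca = 3.0, dTumor = 3.0, zone = "Y2"),
    data.frame(dIca = 3.0, dTumor = 12.0, zone = "B"),
    # boundary conventions: 2 mm is still danger; 5 and 10 mm are clear
    data.frame(dIca = 2.0, dTumor = 7.0, zone = "O3"),
    data.frame(dIca = 3.0, dTumor = 5.0, zone = "G"),
    data.frame(dIca = 3.0, dTumor = 10.0, zone = "G"),
    data.frame(dIca = 0.0, dTumor = 7.0, zone = "R"))
  expect_identical(classifyPoint(cases$dIca, cases$dTumor), cases$zone)
  expect_error(classifyPoint(NaN, 1), "finite")
  expect_error(classifyPoint(1, NA_real_), "finite")
})

test_that("the nine zones partition the distance plane (totality and exclusivity)", {
  set.seed(77)
  d <- cbind(runif(1e5, -20, 25), runif(1e5, -20, 25))
  boundary <- expand.grid(dIca = c(-1, 0, 1e-12, 2, 2 + 1e-12, 5),
                          dTumor = c(-1, 0, 1e-12, 5, 5 + 1e-12, 10,
                                     10 + 1e-12, 15))
  dIca <- c(d[, 1], boundary$dIca)
  dTumor <- c(d[, 2], boundary$dTumor)
  z <- classifyPoint(dIca, dTumor)
  expect_true(all(z %in% zoneCodes()))
  expect_true(all(nchar(z) > 0))
  # exclusivity: re-derive membership per zone from the rule and compare
  damage <- dIca <= 0; danger <- dIca > 0 & dIca <= 2; adequate <- dIca > 2
  tin <- dTumor <= 0; tnear <- dTumor > 0 & dTumor < 5
  tclear <- dTumor >= 5 & dTumor <= 10; tfar <- dTumor > 10
  counts <- damage + (danger & tin) + (danger & tnear) + (danger & tclear) +
    (danger & tfar) + (adequate & tin) + (adequate & tnear) +
    (adequate & tclear) + (adequate & tfar)
  expect_true(all(counts == 1L))
})

test_that("a plane through the carotid centerline is flagged damaged", {
  f <- testFields("S2")
  pose <- pointerPose(c(125, 75, 60), c(0, 0, 1))
  map <- evaluatePlane(pose, f$tumor, f$ica)
  expect_gt(sum(map@zone == "R"), 0)
  s <- summarizePlane(map)
  expect_true(planeFlags(s)[["icaDamaged"]])
  expect_false(planeFlags(s)[["icaAdequate"]])
})

test_that("a plane far from both structures is entirely blue", {
  f <- testFields("S1")
  pose <- pointerPose(c(30, 30, 40), c(0, 0, 1))
  map <- evaluatePlane(pose, f$tumor, f$ica)
  expect_true(all(map@zone == "B"))
  s <- summarizePlane(map)
  expect_equal(unname(zoneFractions(s)[["B"]]), 1)
  expect_true(planeFlags(s)[["adequateMargin"]])
  expect_true(planeFlags(s)[["icaAdequate"]])
})

test_that("samples outside the field grid raise an error naming the point", {
  f <- testFields("S1")
  pose <- pointerPose(c(200, 100, 140), c(0, 0, 1))
  expect_error(evaluatePlane(pose, f$tumor, f$ica), "outside the field grid")
})

test_that("interpolated plane distances agree with brute-force voxel search", {
  model <- testModel("S2")
  f <- testFields("S2")
  set.seed(31)
  pose <- samplePointerPose(model, defaultBehavior("unguided"), "superior")
  pts <- isolateArea(pose)
  sel <- pts[sample(nrow(pts), 50), ]
  dT <- distanceAt(f$tumor, sel)
  # brute force against tumor voxel centers / background voxel centers
  mask <- tumorMask(model)
  idx <- which(voxelValues(mask))
  vox <- sweep(sweep(arrayInd(idx, gridDims(mask)) - 1, 2,
                     gridSpacing(mask), "*"), 2, gridOrigin(mask), "+")
  diagLen <- sqrt(sum(gridSpacing(mask)^2))
  for (i in seq_len(nrow(sel))) {
    bf <- sqrt(min(colSums((t(vox) - sel[i, ])^2)))
    if (dT[i] > 0) # outside: distance to nearest structure voxel center
      expect_lt(abs(dT[i] - bf), diagLen)
  }
})

test_that("plane-map distances are Lipschitz along the lattice", {
  f <- testFields("S3")
  map <- evaluatePlane(idealPose(testModel("S3"), "superior"),
                       f$tumor, f$ica)
  step <- map@samplingSpec@step
  tol <- step + sqrt(sum(gridSpacing(testModel("S3")@masks$tumor)^2)) / 2
  for (dm in list(map@dTumor, map@dIca)) {
    expect_true(all(abs(diff(dm)) <= tol))
    expect_true(all(abs(t(diff(t(dm)))) <= tol))
  }
})

test_that("plane summaries match hand-computed fractions and flags", {
  allG <- handMap(matrix(7, 2, 2), matrix(5, 2, 2))
  s <- summarizePlane(allG)
  expect_equal(unname(zoneFractions(s)[["G"]]), 1)
  expect_true(planeFlags(s)[["adequateMargin"]])
  expect_true(planeFlags(s)[["icaAdequate"]])

  # 4 points: R, G, G, Y1
  m <- handMap(dTumor = matrix(c(7, 7, 7, -1), 4, 1),
               dIca = matrix(c(-0.5, 3, 3, 3), 4, 1))
  expect_identical(as.vector(m@zone), c("R", "G", "G", "Y1"))
  s <- summarizePlane(m)
  expect_equal(unname(zoneFractions(s)[c("R", "G", "Y1")]),
               c(0.25, 0.5, 0.25))
  expect_true(planeFlags(s)[["icaDamaged"]])
  expect_true(planeFlags(s)[["intratumoral"]])

  # danger zone: one point within 2 mm, none inside
  m2 <- handMap(dTumor = matrix(7, 3, 1), dIca = matrix(c(1, 3, 4), 3, 1))
  s2 <- summarizePlane(m2)
  expect_true(planeFlags(s2)[["dangerZone"]])
  expect_false(planeFlags(s2)[["icaDamaged"]])
  expect_false(planeFlags(s2)[["icaAdequate"]])
})

test_that("zone fractions are invariant to lattice orientation", {
  f <- testFields("S4")
  set.seed(12)
  pose <- samplePointerPose(testModel("S4"), defaultBehavior("unguided"),
                            "inferior")
  m1 <- evaluatePlane(pose, f$tumor, f$ica)
  flip <- pointerPose(pose@tip, pose@shaftAxis, roll = pose@roll + 180,
                      angulation = pose@angulation)
  m2 <- evaluatePlane(flip, f$tumor, f$ica)
  expect_equal(zoneFractions(summarizePlane(m1)),
               zoneFractions(summarizePlane(m2)))
})

test_that("plane flags are stable under step refinement on ideal poses", {
  for (id in c("S1", "S2", "S3", "S4")) {
    f <- testFields(id)
    pose <- idealPose(testModel(id), "superior")
    s1 <- summarizePlane(evaluatePlane(pose, f$tumor, f$ica,
                                       planeSamplingSpec(step = 0.5)))
    s2 <- summarizePlane(evaluatePlane(pose, f$tumor, f$ica,
                                       planeSamplingSpec(step = 0.25)))
    expect_identical(planeFlags(s1), planeFlags(s2), label = id)
  }
})

test_that("tip alerts match the zone classification at the tip", {
  cyl <- cylinderMask() # 0.8 mm grid, radius 2.5
  f <- signedDistance(cyl$mask)
  tips <- list(breach = c(cyl$axis, 16),
               proximity = c(cyl$axis[1] + 2.5 + 1.2, cyl$axis[2], 16),
               clear = c(cyl$axis[1] + 2.5 + 5, cyl$axis[2], 16))
  for (nm in names(tips)) {
    expect_identical(evaluateAlert(tips[[nm]], f), nm)
    # breach if and only if the tip itself classifies as R
    zone <- classifyPoint(distanceAt(f, matrix(tips[[nm]], 1)), 20)
    expect_identical(zone == "R", nm == "breach")
  }
  expect_error(evaluateAlert(c(-500, 0, 0), f), "outside")
})

test_that("the rendered color map is pixel-exact and byte-stable", {
  f <- testFields("S1")
  map <- evaluatePlane(idealPose(testModel("S1"), "superior"),
                       f$tumor, f$ica)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  renderColormap(map, p1)
  renderColormap(map, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  img <- png::readPNG(p1)
  # data block is one pixel per lattice point inside frame + margins
  expect_identical(dim(img)[1:2],
                   c(61L + 2L * 5L, 23L + 2L * 5L + 8L + 4L))
  # all-G map renders a single interior color
  allG <- handMap(matrix(7, 4, 4), matrix(5, 4, 4))
  p3 <- withr::local_tempfile(fileext = ".png")
  renderColormap(allG, p3)
  img3 <- png::readPNG(p3)
  interior <- img3[6:9, 6:9, ]
  expect_equal(max(abs(sweep(interior, 3, interior[1, 1, ]))), 0)
})

test_that("map CSV and pose JSON round-trip faithfully", {
  f <- testFields("S4")
  pose <- pointerPose(c(110, 90, 70), c(0.1, 0.2, 0.97), roll = 15,
                      angulation = 45, approach = "contralateral",
                      scope = "0")
  map <- evaluatePlane(pose, f$tumor, f$ica, planeSamplingSpec(5, 2, 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeMapCsv(map, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), length(map@zone))
  expect_equal(df$d_tumor, as.vector(map@dTumor), tolerance = 1e-9)
  expect_identical(df$zone, as.vector(map@zone))

  j <- withr::local_tempfile(fileext = ".json")
  writePoseJson(pose, j)
  p2 <- readPoseJson(j)
  expect_equal(p2@tip, pose@tip, tolerance = 1e-12)
  expect_equal(p2@shaftAxis, pose@shaftAxis, tolerance = 1e-12)
  expect_identical(p2@scope, pose@scope)
})
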