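# Shared fixtures, cached across test files (phantoms and distance fields
# are deterministic, so one build serves every test).

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (!exists(key, envir = .fixtureCache)) assign(key, fn(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# working grid for field-based tests: 1.6 mm isotropic, full phantom coverage
testSpec <- function() volumeSpec(dims = c(128L, 128L, 96L), spacing = 1.6)

# coarse grid for pipeline/file tests
pipeSpec <- function() volumeSpec(dims = c(104L, 104L, 80L), spacing = 2)

testModel <- function(id) {
  fixture(paste0("model_", id), function() buildPhantom(id, testSpec()))
}

testFields <- function(id) {
  fixture(paste0("fields_", id), function() {
    m <- testModel(id)
    list(tumor = signedDistance(tumorMask(m)),
         ica = signedDistance(icaMask(m)))
  })
}

# small voxelized sphere mask on an 0.8-mm grid, centered on a voxel center
sphereMask <- function(radius, spacing = 0.8, pad = 4) {
  n <- as.integer(2 * ceiling(radius / spacing) + 2 * pad + 1)
  ctr <- rep(spacing * (n - 1) / 2, 3)
  xs <- spacing * (0:(n - 1))
  g <- expand.grid(x = xs, y = xs, z = xs)
  v <- array(sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                    (g$z - ctr[3])^2) <= radius, rep(n, 3L))
  list(mask = new("LabelMask", dims = rep(n, 3L), spacing = rep(spacing, 3),
                  origin = c(0, 0, 0), values = v),
       center = ctr)
}

# voxelized finite cylinder along z
cylinderMask <- function(radius = 2.5, spacing = 0.8,
                         dims = c(40L, 40L, 48L),
                         zRange = c(4, 33.6)) {
  ax <- spacing * (dims[1:2] - 1) / 2
  xs <- spacing * (0:(dims[1] - 1))
  zs <- spacing * (0:(dims[3] - 1))
  g <- expand.grid(x = xs, y = xs, z = zs)
  v <- array(sqrt((g$x - ax[1])^2 + (g$y - ax[2])^2) <= radius &
               g$z >= zRange[1] & g$z <= zRange[2], dims)
  list(mask = new("LabelMask", dims = dims, spacing = rep(spacing, 3),
                  origin = c(0, 0, 0), values = v), axis = ax)
}

# hand-built MarginPlaneMap from explicit distance matrices
handMap <- function(dTumor, dIca) {
  dTumor <- as.matrix(dTumor); dIca <- as.matrix(dIca)
  nL <- nrow(dTumor); nW <- ncol(dTumor)
  zone <- matrix(classifyPoint(as.vector(dIca), as.vector(dTumor)), nL, nW)
  pts <- cbind(as.vector(row(dTumor)), as.vector(col(dTumor)), 0)
  new("MarginPlaneMap", points = pts, dTumor = dTumor, dIca = dIca,
      zone = zone, pose = pointerPose(c(0, 0, 0), c(0, 0, 1)),
      samplingSpec = planeSamplingSpec(max(1, nL - 1), max(1, (nW - 1) / 2),
                                       1))
}
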