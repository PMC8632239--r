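# Phantom presets, model construction and CBCT-like volume synthesis.

#' Volume specification constructor
#'
#' Defaults mirror the acquisition grid: 256 x 256 x 192 voxels at isotropic
#' 0.8 mm, covering a 20.5 x 20.5 x 15.4 cm field of view, with the first
#' voxel center at the world origin (RAS, mm).
#'
#' @param dims integer(3), voxels per axis.
#' @param spacing voxel size in mm; scalar (isotropic) or numeric(3).
#' @param origin world position (mm) of the first voxel center.
#' @param intensities named attenuation surrogates for background, bone,
#'   tumor, ica and fiducial material. Tumor and carotid must exceed bone.
#' @return a \linkS4class{VolumeSpec}.
#' @export
volumeSpec <- function(dims = c(256L, 256L, 192L), spacing = 0.8,
                       origin = c(0, 0, 0),
                       intensities = c(background = 0, bone = 400,
                                       tumor = 1200, ica = 1500,
                                       fiducial = 2000)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  new("VolumeSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin), intensities = intensities)
}

# Geometry shared by the stock presets (world mm, default 0.8-mm grid):
# tumor body ellipsoid in the maxillary region, a posterior spherical lobe
# reaching toward the carotid, and a straight vertical paraclival carotid
# tube. The lobe center is placed on the line from the body center to the
# carotid axis so that lobe surface-to-tube surface distance is exactly the
# configured clearance.
.PHANTOM_GEOM <- list(
  bodyCenter = c(102, 110, 76), bodySemi = c(25, 20, 18),
  lobeRadius = 9, icaAxis = c(125, 75), icaZ = c(24, 128), icaRadius = 2.5,
  boneCenter = c(102, 102, 76), boneOuter = c(95, 95, 72),
  boneInner = c(91, 91, 68), zSplit = 76)

.presetTable <- data.frame(
  id = c("S1", "S2", "S3", "S4"),
  tcClearance = c(14.9, 10.2, 6.2, 3.5),
  posteriorExtent = c(
    "invasion of the pterygopalatine fossa",
    "invasion of the medial pterygoid plate, pterygoid fossa and base of the pterygoid process",
    "complete invasion of the pterygoid process",
    "invasion of the anterior foramen lacerum and upper parapharyngeal space"),
  stringsAsFactors = FALSE)

#' Stock phantom presets
#'
#' Four tumor/carotid configurations of increasing posterior extension, with
#' tumor-carotid clearances 14.9 (S1), 10.2 (S2), 6.2 (S3) and 3.5 mm (S4).
#'
#' @return named list of \linkS4class{PhantomPreset} objects.
#' @export
phantomPresets <- function() {
  out <- lapply(seq_len(nrow(.presetTable)), function(i)
    phantomPreset(.presetTable$id[i]))
  names(out) <- .presetTable$id
  out
}

#' Retrieve (or construct) a phantom preset
#'
#' @param id one of "S1", "S2", "S3", "S4", or a custom label when
#'   \code{tcClearance} is supplied.
#' @param tcClearance optional custom tumor-carotid clearance (mm) overriding
#'   the stock table.
#' @return a \linkS4class{PhantomPreset}.
#' @export
phantomPreset <- function(id, tcClearance = NULL) {
  g <- .PHANTOM_GEOM
  if (is.null(tcClearance)) {
    row <- .presetTable[.presetTable$id == id, ]
    if (nrow(row) != 1L)
      stop("unknown preset '", id, "'; valid ids: ",
           paste(.presetTable$id, collapse = ", "))
    tcClearance <- row$tcClearance
    extent <- row$posteriorExtent
  } else {
    extent <- "custom configuration"
  }
  u <- .unit(c(g$icaAxis - g$bodyCenter[1:2], 0))
  standoff <- tcClearance + g$icaRadius + g$lobeRadius
  lobeCenter <- c(g$icaAxis - standoff * u[1:2], g$bodyCenter[3])
  icaCtrl <- cbind(g$icaAxis[1], g$icaAxis[2],
                   seq(g$icaZ[1], g$icaZ[2], length.out = 4))
  new("PhantomPreset", id = id, tcClearance = tcClearance,
      posteriorExtent = extent,
      tumorParams = list(bodyCenter = g$bodyCenter, bodySemi = g$bodySemi,
                         lobeCenter = lobeCenter, lobeRadius = g$lobeRadius,
                         posteriorDir = u),
      icaParams = list(controlPoints = icaCtrl, radius = g$icaRadius))
}

# Default fiducial divot directions on the outer bone shell (unit sphere
# parameterization); chosen non-coplanar and well separated.
.FID_DIRS <- rbind(
  c(0.9, 0.1, 0.3), c(-0.8, 0.4, 0.3), c(0.1, 0.9, 0.35),
  c(0.2, -0.9, 0.25), c(-0.3, -0.5, 0.8), c(0.6, 0.5, -0.6))

#' Build a phantom model from a preset
#'
#' Realizes the analytic geometry (tumor = ellipsoid body plus posterior
#' spherical lobe; carotid = swept tube; bone = hollow ellipsoid shell) as
#' surface meshes and voxel occupancy masks, and places registration divots
#' on the bone surface. The realized closest tumor-to-carotid surface
#' distance equals the preset clearance by construction.
#'
#' @param preset a \linkS4class{PhantomPreset} or preset id string.
#' @param spec \linkS4class{VolumeSpec} for the voxel masks.
#' @param voxelize build the voxel masks (set FALSE for mesh-only work).
#' @return a \linkS4class{PhantomModel}.
#' @export
buildPhantom <- function(preset, spec = volumeSpec(), voxelize = TRUE) {
  if (is.character(preset)) preset <- phantomPreset(preset)
  g <- .PHANTOM_GEOM
  tp <- preset@tumorParams
  ip <- preset@icaParams

  minSpacing <- min(spec@spacing)
  if (preset@tcClearance < minSpacing / 2)
    stop("configuration error: clearance ", preset@tcClearance,
         " mm is below half the voxel spacing (", minSpacing,
         " mm) and cannot be represented")

  # feasibility: lobe must stay inside the field of view and anterior of the tube
  lo <- spec@origin - spec@spacing / 2
  hi <- spec@origin + spec@spacing * (spec@dims - 0.5)
  lobeMin <- tp$lobeCenter - tp$lobeRadius
  lobeMax <- tp$lobeCenter + tp$lobeRadius
  if (any(lobeMin < lo) || any(lobeMax > hi))
    stop("configuration error: clearance ", preset@tcClearance,
         " mm places the posterior lobe outside the volume bounds")

  body <- ellipsoidMesh(tp$bodyCenter, tp$bodySemi, nTheta = 96L, nPhi = 48L)
  lobe <- sphereMesh(tp$lobeCenter, tp$lobeRadius, nTheta = 96L, nPhi = 48L)
  ica <- tubeMesh(ip$controlPoints, ip$radius, nAround = 64L, nPer = 24L)
  boneOut <- ellipsoidMesh(g$boneCenter, g$boneOuter, nTheta = 48L, nPhi = 24L)
  boneIn <- ellipsoidMesh(g$boneCenter, g$boneInner, nTheta = 48L, nPhi = 24L)

  masks <- list()
  if (voxelize) {
    tumor <- .voxelizeEllipsoid(spec, tp$bodyCenter, tp$bodySemi)
    lobeM <- .voxelizeSphere(spec, tp$lobeCenter, tp$lobeRadius)
    tumor@values <- tumor@values | lobeM@values
    icaM <- .voxelizeTube(spec, ip$controlPoints, ip$radius)
    bone <- .voxelizeShell(spec, g$boneCenter, g$boneOuter, g$boneInner)
    masks <- list(tumor = tumor, ica = icaM, bone = bone)
  }

  fidTrue <- sweep(sweep(.FID_DIRS / sqrt(rowSums(.FID_DIRS^2)), 2,
                         g$boneOuter, "*"), 2, g$boneCenter, "+")
  fids <- new("FiducialSet", truePositions = fidTrue,
              measuredPositions = fidTrue)

  new("PhantomModel", preset = preset,
      tumorComponents = list(body = body, lobe = lobe),
      tumorMesh = mergeMeshes(list(body, lobe)),
      icaMesh = ica, boneMesh = mergeMeshes(list(boneOut, boneIn)),
      masks = masks, fiducials = fids, spec = spec)
}

#' Measured tumor-to-carotid clearance of a model
#'
#' Closest distance between the tumor and carotid surface meshes (mm),
#' measured independently of the configured preset value.
#'
#' @param model a \linkS4class{PhantomModel}.
#' @return distance in mm.
#' @export
measureClearance <- function(model) {
  meshMinDistance(model@tumorMesh, model@icaMesh)
}

#' Analytic signed distance to the carotid tube
#'
#' Distance from world points to the tube centerline minus the tube radius;
#' negative inside the vessel. This is the real-time proximity oracle used by
#' the simulated navigation alarms.
#'
#' @param model a \linkS4class{PhantomModel}.
#' @param points n x 3 matrix of world points (mm).
#' @return signed distances (mm).
#' @export
icaDistanceAnalytic <- function(model, points) {
  ip <- model@preset@icaParams
  ctr <- .catmullRom(ip$controlPoints, nPer = 24L)
  sqrt(.pointsToSegmentsSq(as.matrix(points), ctr)) - ip$radius
}

# Signed distance to the tumor (union of ellipsoid body and spherical lobe):
# lobe distance is closed-form; body distance uses the tessellated surface
# (accurate to chord error, <0.02 mm at the stock tessellation) with the sign
# taken from the implicit ellipsoid function.
.tumorDistanceAnalytic <- function(model, points) {
  tp <- model@preset@tumorParams
  pts <- as.matrix(points)
  dLobe <- sqrt(rowSums(sweep(pts, 2, tp$lobeCenter)^2)) - tp$lobeRadius
  dBody <- pointsToMeshDistance(pts, model@tumorComponents$body)
  s <- sweep(sweep(pts, 2, tp$bodyCenter), 2, tp$bodySemi, "/")
  dBody <- ifelse(rowSums(s^2) < 1, -dBody, dBody)
  pmin(dLobe, dBody)
}

#' Synthesize a CBCT-like intensity volume
#'
#' Paints material intensities onto the grid with overlap priority
#' carotid > tumor > bone (the vessel is never erased by tumor voxels), adds
#' fiducial divot markers, and optionally additive Gaussian noise.
#'
#' @param model a \linkS4class{PhantomModel} with voxel masks.
#' @param spec \linkS4class{VolumeSpec}; defaults to the model's grid.
#' @param noiseSd additive Gaussian noise SD (intensity units, default 0).
#' @param fiducialRadius radius of painted divot markers (mm); 0 (default)
#'   leaves the divots unpainted (they are carried in the fiducial CSV).
#' @return a \linkS4class{ScanVolume}.
#' @export
synthesizeVolume <- function(model, spec = model@spec, noiseSd = 0,
                             fiducialRadius = 0) {
  .checkInsideFov(model, spec)
  if (!length(model@masks) || !identical(model@spec@dims, spec@dims) ||
      !identical(model@spec@spacing, spec@spacing))
    model <- buildPhantom(model@preset, spec)
  ii <- spec@intensities
  vol <- array(ii[["background"]], dim = spec@dims)
  vol[model@masks$bone@values] <- ii[["bone"]]
  vol[model@masks$tumor@values] <- ii[["tumor"]]
  vol[model@masks$ica@values] <- ii[["ica"]]
  fid <- model@fiducials@truePositions
  for (i in seq_len(nrow(fid))) {
    m <- .voxelizeSphere(spec, fid[i, ], fiducialRadius)
    vol[m@values] <- ii[["fiducial"]]
  }
  if (noiseSd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noiseSd), dim = dim(vol))
  new("ScanVolume", dims = spec@dims, spacing = spec@spacing,
      origin = spec@origin, values = vol)
}

.checkInsideFov <- function(model, spec) {
  lo <- spec@origin - spec@spacing / 2
  hi <- spec@origin + spec@spacing * (spec@dims - 0.5)
  structures <- list(tumor = model@tumorMesh, ica = model@icaMesh,
                     bone = model@boneMesh)
  for (nm in names(structures)) {
    V <- structures[[nm]]@vertices
    if (nrow(V) == 0L) next
    if (any(sweep(V, 2, lo) < 0) || any(sweep(V, 2, hi) > 0))
      stop("structure out of field of view: ", nm)
  }
  invisible(TRUE)
}

#' Construct a fiducial set
#'
#' @param truePositions n x 3 matrix of divot positions (mm), n >= 4,
#'   pairwise separation >= 10 mm, non-coplanar.
#' @param measuredPositions matching tracked positions; defaults to the true
#'   positions (noise-free localization).
#' @return a \linkS4class{FiducialSet}.
#' @export
fiducialSet <- function(truePositions, measuredPositions = truePositions) {
  new("FiducialSet", truePositions = as.matrix(truePositions),
      measuredPositions = as.matrix(measuredPositions))
}

#' Apply localization noise to a model's fiducials
#'
#' @param fids a \linkS4class{FiducialSet}.
#' @param sd isotropic Gaussian noise SD per axis (mm).
#' @return a new \linkS4class{FiducialSet} with noisy measured positions.
#' @export
perturbFiducials <- function(fids, sd = 0.25) {
  tp <- fids@truePositions
  noise <- matrix(stats::rnorm(length(tp), 0, sd), ncol = 3)
  fiducialSet(tp, tp + noise)
}
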