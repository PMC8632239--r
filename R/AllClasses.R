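#' @useDynLib NaviMargin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---- voxel grids -----------------------------------------------------------

#' Virtual base class for objects living on a regular voxel grid
#'
#' World convention: right-handed RAS coordinates in millimeters, voxel
#' indices 0-based, and the center of voxel (0,0,0) sits at \code{origin}.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @slot origin numeric(3), world position (mm) of the first voxel center.
#' @name VoxelGrid-class
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation("VIRTUAL",
  dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Intensity volume on a voxel grid
#'
#' @slot values numeric 3-D array of voxel intensities.
#' @name ScanVolume-class
#' @exportClass ScanVolume
setClass("ScanVolume", contains = "VoxelGrid", representation(values = "array"))

#' Binary occupancy mask on a voxel grid
#'
#' @slot values logical 3-D array; \code{TRUE} marks voxels inside the structure.
#' @name LabelMask-class
#' @exportClass LabelMask
setClass("LabelMask", contains = "VoxelGrid", representation(values = "array"))

#' Signed Euclidean distance field
#'
#' Per-voxel signed distance in mm to a structure surface: negative strictly
#' inside, positive outside. Values at arbitrary world points are obtained by
#' trilinear interpolation (see \code{\link{distanceAt}}).
#'
#' @slot values numeric 3-D array of signed distances (mm).
#' @name DistanceField-class
#' @exportClass DistanceField
setClass("DistanceField", contains = "VoxelGrid", representation(values = "array"))

.checkGridValues <- function(object) {
  if (!identical(dim(object@values), as.integer(object@dims)))
    return("values array dimensions do not match dims")
  TRUE
}
setValidity("ScanVolume", .checkGridValues)
setValidity("LabelMask", function(object) {
  v <- .checkGridValues(object)
  if (!isTRUE(v)) return(v)
  if (!is.logical(object@values)) return("mask values must be logical")
  TRUE
})
setValidity("DistanceField", .checkGridValues)

# ---- meshes ----------------------------------------------------------------

#' Triangle surface mesh in world millimeters
#'
#' @slot vertices numeric matrix (n x 3) of vertex positions (mm).
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @name TriangleMesh-class
#' @exportClass TriangleMesh
setClass("TriangleMesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) > 0 &&
      (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices)))
    return("face indices out of range")
  TRUE
})

# ---- phantom specification -------------------------------------------------

#' Volume synthesis specification
#'
#' Defaults reproduce the acquisition grid used throughout:
#' 256 x 256 x 192 voxels at isotropic 0.8 mm (20 x 20 x 15 cm field of view).
#'
#' @slot dims integer(3) voxels per axis.
#' @slot spacing numeric(3) mm per voxel.
#' @slot origin numeric(3) world mm of first voxel center.
#' @slot intensities named numeric attenuation surrogate per material
#'   (background, bone, tumor, ica, fiducial). Tumor and carotid must exceed
#'   bone, mirroring their much higher X-ray attenuation on CBCT.
#' @name VolumeSpec-class
#' @exportClass VolumeSpec
setClass("VolumeSpec", representation(
  dims = "integer", spacing = "numeric", origin = "numeric",
  intensities = "numeric"))

setValidity("VolumeSpec", function(object) {
  if (any(object@dims < 16L)) return("dims must be at least 16 per axis")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  need <- c("background", "bone", "tumor", "ica", "fiducial")
  if (!all(need %in% names(object@intensities)))
    return(paste("intensities must name:", paste(need, collapse = ", ")))
  ii <- object@intensities
  if (ii["tumor"] <= ii["bone"] || ii["ica"] <= ii["bone"])
    return("tumor and ica intensities must strictly exceed bone")
  TRUE
})

#' Phantom preset: one tumor/carotid difficulty configuration
#'
#' The four stock presets S1-S4 realize decreasing tumor-carotid clearances
#' of 14.9, 10.2, 6.2 and 3.5 mm, i.e. increasing posterior tumor extension
#' toward the internal carotid artery.
#'
#' @slot id preset label (S1..S4 for the stock presets).
#' @slot tcClearance closest tumor-to-carotid surface distance (mm).
#' @slot posteriorExtent free-text description of the posterior extension.
#' @slot tumorParams list: ellipsoid body (center, semiAxes) and posterior
#'   lobe (center, radius).
#' @slot icaParams list: polyline control points (n x 3, mm) and tube radius.
#' @name PhantomPreset-class
#' @exportClass PhantomPreset
setClass("PhantomPreset", representation(
  id = "character", tcClearance = "numeric", posteriorExtent = "character",
  tumorParams = "list", icaParams = "list"))

setValidity("PhantomPreset", function(object) {
  if (object@tcClearance <= 0) return("tcClearance must be positive")
  TRUE
})

#' Registration fiducial set
#'
#' @slot truePositions numeric (n x 3) divot positions in image space (mm).
#' @slot measuredPositions numeric (n x 3) tracked positions after
#'   localization noise, same order.
#' @name FiducialSet-class
#' @exportClass FiducialSet
setClass("FiducialSet", representation(
  truePositions = "matrix", measuredPositions = "matrix"))

setValidity("FiducialSet", function(object) {
  tp <- object@truePositions
  if (nrow(tp) < 4L) return("at least 4 fiducials required")
  if (nrow(object@measuredPositions) != nrow(tp))
    return("true and measured positions must have equal length")
  if (min(stats::dist(tp)) < 10)
    return("fiducials closer than 10 mm")
  ctr <- scale(tp, scale = FALSE)
  if (qr(ctr)$rank < 3L) return("fiducials are coplanar or collinear")
  TRUE
})

#' Generated phantom model
#'
#' Analytic primitives plus their surface meshes and voxel masks for the
#' tumor, the internal carotid artery (ICA) and the bone shell, with
#' registration fiducials and the preset metadata.
#'
#' @slot preset the \linkS4class{PhantomPreset} realized.
#' @slot tumorComponents list of \linkS4class{TriangleMesh}, one per convex
#'   tumor component (ellipsoid body, posterior lobe).
#' @slot tumorMesh combined tumor surface soup.
#' @slot icaMesh carotid tube mesh.
#' @slot boneMesh bone shell mesh.
#' @slot masks list of \linkS4class{LabelMask}: tumor, ica, bone.
#' @slot fiducials \linkS4class{FiducialSet}.
#' @slot spec the \linkS4class{VolumeSpec} used for voxelization.
#' @name PhantomModel-class
#' @exportClass PhantomModel
setClass("PhantomModel", representation(
  preset = "PhantomPreset", tumorComponents = "list",
  tumorMesh = "TriangleMesh", icaMesh = "TriangleMesh", boneMesh = "TriangleMesh",
  masks = "list", fiducials = "FiducialSet", spec = "VolumeSpec"))

# ---- behavior / poses ------------------------------------------------------

#' Simulated surgeon behavior model
#'
#' Angular and translational placement noise around the ideal cutting plane,
#' one of three guidance settings. The carotid-guided setting resamples poses
#' whose plane would breach the carotid (the navigation system's beeping
#' alarm) up to \code{maxResample} times.
#'
#' @slot setting one of "unguided", "tumor_guided", "carotid_guided".
#' @slot rotSd angular placement noise SD (degrees) about the two in-plane axes.
#' @slot transSd translational noise SD (mm) along the plane normal.
#' @slot angulationChoices subset of c(0, 30, 45, 60, 90) degrees.
#' @slot angulationWeights sampling weights for the angulation choices.
#' @slot maxResample carotid-guided only: resampling budget on breach.
#' @name BehaviorModel-class
#' @exportClass BehaviorModel
setClass("BehaviorModel", representation(
  setting = "character", rotSd = "numeric", transSd = "numeric",
  angulationChoices = "numeric", angulationWeights = "numeric",
  maxResample = "integer"))

setValidity("BehaviorModel", function(object) {
  if (!object@setting %in% c("unguided", "tumor_guided", "carotid_guided"))
    return("unknown setting")
  if (object@rotSd < 0 || object@transSd < 0) return("noise SDs must be >= 0")
  if (!all(object@angulationChoices %in% c(0, 30, 45, 60, 90)))
    return("angulationChoices must be within {0, 30, 45, 60, 90}")
  if (length(object@angulationWeights) != length(object@angulationChoices))
    return("angulationWeights must match angulationChoices")
  TRUE
})

#' Tracked-pointer pose defining a virtual cutting plane
#'
#' The cutting plane contains \code{tip} and \code{shaftAxis}; \code{roll}
#' (degrees about the shaft) fixes the plane normal, mirroring planar virtual
#' tool clipping with an osteotome or saw.
#'
#' @slot tip pointer tip, world mm.
#' @slot shaftAxis unit vector of the distal shaft segment (in-plane).
#' @slot roll degrees about the shaft axis fixing the plane orientation.
#' @slot angulation pointer tip angulation, one of 0/30/45/60/90 degrees.
#' @slot approach "ipsilateral", "bilateral" or "contralateral".
#' @slot scope endoscope used, "0" or "45" degrees.
#' @slot breachUnresolved TRUE when carotid-guided resampling was exhausted.
#' @name PointerPose-class
#' @exportClass PointerPose
setClass("PointerPose", representation(
  tip = "numeric", shaftAxis = "numeric", roll = "numeric",
  angulation = "numeric", approach = "character", scope = "character",
  breachUnresolved = "logical"))

setValidity("PointerPose", function(object) {
  if (abs(sqrt(sum(object@shaftAxis^2)) - 1) > 1e-6)
    return("shaftAxis must be a unit vector")
  if (!object@angulation %in% c(0, 30, 45, 60, 90))
    return("angulation must be one of 0, 30, 45, 60, 90")
  TRUE
})

#' Cutting-plane sampling window
#'
#' The analyzed area runs \code{length} mm along the shaft from the tip and
#' \code{halfWidth} mm to each side (defaults 30 and 5.5, i.e. the
#' 30 x 11 mm window), sampled on a \code{step}-mm lattice.
#'
#' @slot length mm along the shaft axis from the tip.
#' @slot halfWidth mm on each side of the shaft line.
#' @slot step lattice spacing, mm.
#' @name PlaneSamplingSpec-class
#' @exportClass PlaneSamplingSpec
setClass("PlaneSamplingSpec", representation(
  length = "numeric", halfWidth = "numeric", step = "numeric"))

setValidity("PlaneSamplingSpec", function(object) {
  if (object@length <= 0 || object@halfWidth <= 0 || object@step <= 0)
    return("length, halfWidth and step must be positive")
  if (object@step > min(object@length, object@halfWidth))
    return("step must not exceed min(length, halfWidth)")
  TRUE
})

#' Evaluated cutting-plane margin map
#'
#' The analysis unit: per lattice point, the signed minimal distances to the
#' tumor and carotid surfaces and the nine-way zone code.
#'
#' @slot points numeric (n x 3) world positions, row-major over the lattice.
#' @slot dTumor,dIca numeric matrices (nLength x nWidth), signed mm.
#' @slot zone character matrix of zone codes (R, O1-O4, Y1, Y2, G, B).
#' @slot pose the \linkS4class{PointerPose} evaluated.
#' @slot samplingSpec the \linkS4class{PlaneSamplingSpec} used.
#' @name MarginPlaneMap-class
#' @exportClass MarginPlaneMap
setClass("MarginPlaneMap", representation(
  points = "matrix", dTumor = "matrix", dIca = "matrix", zone = "matrix",
  pose = "PointerPose", samplingSpec = "PlaneSamplingSpec"))

setValidity("MarginPlaneMap", function(object) {
  d <- dim(object@dTumor)
  if (!identical(dim(object@dIca), d) || !identical(dim(object@zone), d))
    return("dTumor, dIca and zone must share dimensions")
  if (nrow(object@points) != prod(d)) return("points must match lattice size")
  TRUE
})

#' Per-plane zone distribution and safety flags
#'
#' @slot fractions named numeric over the nine zone codes, summing to 1.
#' @slot flags named logical: intratumoral, adequateMargin, icaDamaged,
#'   dangerZone, icaAdequate.
#' @slot nPoints number of lattice points summarized.
#' @name ZoneSummary-class
#' @exportClass ZoneSummary
setClass("ZoneSummary", representation(
  fractions = "numeric", flags = "logical", nPoints = "integer"))

setValidity("ZoneSummary", function(object) {
  if (abs(sum(object@fractions) - 1) > 1e-9) return("fractions must sum to 1")
  if (any(object@fractions < 0)) return("fractions must be non-negative")
  fl <- object@flags
  if (sum(fl[c("icaDamaged", "dangerZone", "icaAdequate")]) != 1L)
    return("exactly one of icaDamaged, dangerZone, icaAdequate must hold")
  if (fl[["intratumoral"]] == fl[["adequateMargin"]])
    return("intratumoral must equal !adequateMargin")
  TRUE
})

# ---- registration ----------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @slot rotation 3 x 3 orthonormal matrix, det = +1.
#' @slot translation numeric(3), mm.
#' @name RigidTransform-class
#' @exportClass RigidTransform
setClass("RigidTransform", representation(
  rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must have det = +1")
  if (length(object@translation) != 3L) return("translation must have length 3")
  TRUE
})

#' Paired-point registration result
#'
#' @slot transform fitted \linkS4class{RigidTransform} (source to target).
#' @slot fre fiducial registration error: RMS residual over pairs, mm.
#' @slot threshold acceptance gate, mm (default 1.0).
#' @slot accepted TRUE iff fre <= threshold.
#' @name RegistrationResult-class
#' @exportClass RegistrationResult
setClass("RegistrationResult", representation(
  transform = "RigidTransform", fre = "numeric", threshold = "numeric",
  accepted = "logical"))

setValidity("RegistrationResult", function(object) {
  if (object@fre < 0) return("fre must be non-negative")
  if (object@accepted != (object@fre <= object@threshold))
    return("accepted must equal fre <= threshold")
  TRUE
})

# ---- alert cloud -----------------------------------------------------------

#' Carotid proximity alert cloud
#'
#' The shell between the vessel surface and its Euclidean offset at
#' \code{margin} mm (default 2), built by volumetric dilation; the navigation
#' system sounds a flow-like alarm when the tool enters it.
#'
#' @slot margin offset distance, mm.
#' @slot mask \linkS4class{LabelMask} of the shell voxels.
#' @slot surfaceMesh \linkS4class{TriangleMesh} of the outer offset surface.
#' @name AlertCloud-class
#' @exportClass AlertCloud
setClass("AlertCloud", representation(
  margin = "numeric", mask = "LabelMask", surfaceMesh = "TriangleMesh"))

# ---- trial records and statistics ------------------------------------------

#' One simulated margin delineation
#'
#' @slot surgeonId integer surgeon index.
#' @slot presetId phantom preset label.
#' @slot setting guidance setting.
#' @slot portion "superior" or "inferior" posterior-margin portion.
#' @slot summary the plane's \linkS4class{ZoneSummary}.
#' @slot pose the recorded \linkS4class{PointerPose}.
#' @name TrialRecord-class
#' @exportClass TrialRecord
setClass("TrialRecord", representation(
  surgeonId = "integer", presetId = "character", setting = "character",
  portion = "character", summary = "ZoneSummary", pose = "PointerPose"))

#' Group comparison across guidance settings
#'
#' @slot zoneStats data.frame: one row per zone code with mean percentage per
#'   setting, Kruskal-Wallis H and p.
#' @slot posthoc named list of pairwise Steel-Dwass-Critchlow-Fligner p-value
#'   matrices, one per zone code.
#' @slot flagTests named list: for intratumoral and icaDamaged, the 2 x k
#'   count table and Fisher exact p.
#' @slot settings settings compared, in column order.
#' @slot alpha significance level recorded with the report.
#' @name GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison", representation(
  zoneStats = "data.frame", posthoc = "list", flagTests = "list",
  settings = "character", alpha = "numeric"))

#' Intraindividual guidance gain
#'
#' Difference, per surgeon, between pooled guided and unguided rates of
#' clear-margin planes and carotid-spared planes (percentage points).
#'
#' @slot perSurgeon data.frame with per-surgeon rates and gains.
#' @slot meanGain named numeric: clearMargin, carotidSpared.
#' @slot rangeGain list of length-2 ranges for the two gains.
#' @name GainResult-class
#' @exportClass GainResult
setClass("GainResult", representation(
  perSurgeon = "data.frame", meanGain = "numeric", rangeGain = "list"))
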