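# Segmentation, surface extraction, signed distance fields and the
# carotid proximity alert cloud.

#' Threshold segmentation with morphological refinement
#'
#' Global thresholding (voxels >= threshold) followed by morphological
#' closing then opening with a Euclidean ball of radius \code{refineRadius},
#' the reproducible surrogate for interactive smoothing of a coarse
#' segmentation. Connected components smaller than \code{minVolume} voxels
#' are removed.
#'
#' @param volume a \linkS4class{ScanVolume}.
#' @param threshold intensity cutoff; must lie within the volume's range.
#' @param refineRadius structuring-ball radius in mm (0 disables refinement).
#' @param minVolume minimum component size in voxels (0 disables).
#' @return a \linkS4class{LabelMask}.
#' @export
segmentByThreshold <- function(volume, threshold, refineRadius = 0,
                               minVolume = 0) {
  rng <- range(volume@values)
  if (threshold < rng[1] || threshold > rng[2])
    stop("threshold ", threshold, " outside intensity range [",
         rng[1], ", ", rng[2], "]")
  mask <- new("LabelMask", dims = volume@dims, spacing = volume@spacing,
              origin = volume@origin, values = volume@values >= threshold)
  if (!any(mask@values))
    stop("empty segmentation at threshold ", threshold)
  if (refineRadius > 0) {
    mask <- .morphClose(mask, refineRadius)
    mask <- .morphOpen(mask, refineRadius)
  }
  if (minVolume > 0) mask <- .dropSmallComponents(mask, minVolume)
  if (!any(mask@values))
    stop("empty segmentation at threshold ", threshold,
         " after refinement")
  mask
}

# Euclidean-ball dilation/erosion realized by thresholding the distance
# transform, so the structuring element is isotropic in mm.
.dilateMask <- function(mask, radius) {
  d <- .cpp_edt(as.vector(mask@values), mask@dims, mask@spacing)
  mask@values <- array(d <= radius, dim = mask@dims)
  mask
}

.erodeMask <- function(mask, radius) {
  d <- .cpp_edt(as.vector(!mask@values), mask@dims, mask@spacing)
  mask@values <- array(d > radius, dim = mask@dims)
  mask
}

.morphClose <- function(mask, radius) .erodeMask(.dilateMask(mask, radius), radius)
.morphOpen <- function(mask, radius) .dilateMask(.erodeMask(mask, radius), radius)

# 6-connected component labelling (flood fill); adequate for the small
# spurious islands this filter targets.
.dropSmallComponents <- function(mask, minVoxels) {
  v <- mask@values
  lab <- array(0L, dim = dim(v))
  d <- dim(v)
  queue <- integer(0)
  nextLab <- 0L
  idxAll <- which(v & lab == 0L)
  for (start in idxAll) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    comp <- integer(0)
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      comp <- c(comp, cur)
      ijk <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- ijk
        nb[, ax] <- nb[, ax] + s
        ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
        lin <- lin[v[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- nextLab
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
    if (length(comp) < minVoxels) v[comp] <- FALSE
  }
  mask@values <- v
  mask
}

#' Extract an isosurface mesh from a mask
#'
#' Marching-tetrahedra isosurface at the 0.5 occupancy level on the
#' voxel-center lattice; the domain is padded with background so masks
#' touching the array border still close. The result is watertight with
#' outward-oriented faces.
#'
#' @param mask a non-empty \linkS4class{LabelMask} (or a
#'   \linkS4class{DistanceField} with \code{level} for offset surfaces).
#' @param level iso level (default 0.5 occupancy).
#' @return a \linkS4class{TriangleMesh} in world mm.
#' @export
extractSurface <- function(mask, level = 0.5) {
  if (is(mask, "LabelMask")) {
    if (!any(mask@values)) stop("cannot extract a surface from an empty mask")
    vals <- as.numeric(mask@values)
    pad <- 0
  } else if (is(mask, "DistanceField")) {
    # continuous iso-level crossing: inside = values below level; negate so
    # "value > level" means inside, preserving sub-voxel interpolation
    if (missing(level)) stop("an iso level (mm) is required for a DistanceField")
    vals <- -as.vector(mask@values)
    level <- -level
    pad <- -1e9
  } else stop("mask must be a LabelMask or DistanceField")
  res <- .cpp_march_tets(vals, mask@dims, mask@spacing,
                         mask@origin, level, pad)
  triangleMesh(res$vertices, res$faces)
}

#' Signed Euclidean distance field of a mask
#'
#' Exact voxel-center signed distances: distance to the nearest structure
#' voxel minus distance to the nearest background voxel, in mm (negative
#' inside). Values at arbitrary points come from trilinear interpolation via
#' \code{\link{distanceAt}}.
#'
#' @param mask a \linkS4class{LabelMask} that is neither empty nor full.
#' @return a \linkS4class{DistanceField}.
#' @export
signedDistance <- function(mask) {
  if (!any(mask@values)) stop("cannot compute distances for an empty mask")
  if (all(mask@values)) stop("cannot compute distances for a full mask (no surface)")
  d <- .cpp_signed_edt(as.vector(mask@values), mask@dims, mask@spacing)
  new("DistanceField", dims = mask@dims, spacing = mask@spacing,
      origin = mask@origin, values = d)
}

#' Sample a distance field at world points
#'
#' Trilinear interpolation on the voxel-center lattice. Points outside the
#' lattice hull raise an error naming the first offending point.
#'
#' @param field a \linkS4class{DistanceField} (or any voxel grid object).
#' @param points n x 3 matrix of world coordinates (mm).
#' @return numeric vector of interpolated values.
#' @export
distanceAt <- function(field, points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be an n x 3 matrix")
  out <- .cpp_trilinear(as.vector(field@values), field@dims, field@spacing,
                        field@origin, pts)
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("point (%.2f, %.2f, %.2f) is outside the field grid",
                 pts[bad, 1], pts[bad, 2], pts[bad, 3]))
  }
  out
}

#' Build the carotid proximity alert cloud
#'
#' Volumetric dilation of the vessel mask by a Euclidean ball of radius
#' \code{margin} (default 2 mm), minus the vessel: the shell whose traversal
#' triggers the proximity alarm. The outer wireframe surface is the
#' continuous \code{margin}-level set of the distance to the vessel surface
#' mesh, so its offset is sub-voxel accurate rather than quantized to the
#' binary dilation.
#'
#' @param icaMask vessel \linkS4class{LabelMask}.
#' @param margin offset in mm (> 0); a warning is issued when margin is below
#'   the voxel spacing (the shell may be disconnected).
#' @return an \linkS4class{AlertCloud}.
#' @export
buildAlertCloud <- function(icaMask, margin = 2) {
  if (!any(icaMask@values)) stop("empty ICA mask")
  if (margin <= 0) stop("margin must be positive")
  if (margin < min(icaMask@spacing))
    warning("margin ", margin, " mm is below the voxel spacing; ",
            "the alert shell may be disconnected")
  dilated <- .dilateMask(icaMask, margin)
  shell <- dilated
  shell@values <- dilated@values & !icaMask@values
  vesselSurf <- extractSurface(icaMask)
  surf <- extractSurface(.meshDistanceField(icaMask, vesselSurf,
                                            maxDist = margin + 2 * max(icaMask@spacing)),
                         level = margin)
  new("AlertCloud", margin = margin, mask = shell, surfaceMesh = surf)
}

# Signed distance-to-mesh sampled on the mask's grid; values beyond maxDist
# of the binary dilation are left at a large positive constant (they cannot
# affect level sets below maxDist).
.meshDistanceField <- function(mask, mesh, maxDist) {
  d <- .cpp_edt(as.vector(mask@values), mask@dims, mask@spacing)
  vals <- array(1e6, dim = mask@dims)
  near <- which(d <= maxDist)
  co <- sweep(sweep(arrayInd(near, mask@dims) - 1, 2, mask@spacing, "*"),
              2, mask@origin, "+")
  dm <- pointsToMeshDistance(co, mesh)
  dm[mask@values[near]] <- -dm[mask@values[near]]
  vals[near] <- dm
  new("DistanceField", dims = mask@dims, spacing = mask@spacing,
      origin = mask@origin, values = vals)
}
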