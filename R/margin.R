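# Cutting-plane isolation, zone classification, plane evaluation,
# proximity alerts and color-map rendering.

#' Plane sampling specification constructor
#'
#' @param length mm along the shaft axis from the tip (default 30).
#' @param halfWidth mm on each side of the shaft line (default 5.5).
#' @param step lattice spacing in mm (default 0.5).
#' @return a \linkS4class{PlaneSamplingSpec}.
#' @export
planeSamplingSpec <- function(length = 30, halfWidth = 5.5, step = 0.5) {
  new("PlaneSamplingSpec", length = length, halfWidth = halfWidth, step = step)
}

#' Pointer pose constructor
#'
#' @param tip pointer tip, world mm.
#' @param shaftAxis distal shaft direction (normalized internally); lies in
#'   the cutting plane.
#' @param roll degrees about the shaft fixing the plane orientation.
#' @param angulation pointer angulation, one of 0, 30, 45, 60, 90 degrees.
#' @param approach surgical approach label.
#' @param scope endoscope label ("0" or "45").
#' @param breachUnresolved carotid-guided resampling exhausted flag.
#' @return a \linkS4class{PointerPose}.
#' @export
pointerPose <- function(tip, shaftAxis, roll = 0, angulation = 60,
                        approach = "bilateral", scope = "45",
                        breachUnresolved = FALSE) {
  new("PointerPose", tip = as.numeric(tip), shaftAxis = .unit(shaftAxis),
      roll = roll, angulation = angulation, approach = approach,
      scope = scope, breachUnresolved = breachUnresolved)
}

# Reference lateral direction for roll = 0: perpendicular to the shaft,
# derived from the most transverse world axis for numerical stability.
.rollReference <- function(shaft) {
  ref <- c(0, 0, 1)
  if (abs(sum(ref * shaft)) > 0.9) ref <- c(1, 0, 0)
  .unit(.cross3(ref, shaft))
}

#' Orthonormal frame of a pointer pose
#'
#' Returns the shaft axis, the in-plane lateral axis (roll degrees about the
#' shaft from the reference direction) and the plane normal
#' (shaft x lateral).
#'
#' @param pose a \linkS4class{PointerPose}.
#' @return list with unit vectors \code{shaft}, \code{lateral}, \code{normal}.
#' @export
poseFrame <- function(pose) {
  s <- pose@shaftAxis
  r0 <- .rollReference(s)
  Rroll <- rotationAboutAxis(s, pose@roll)
  lateral <- as.vector(Rroll %*% r0)
  list(shaft = s, lateral = lateral, normal = .cross3(s, lateral))
}

#' Pose from an explicit frame
#'
#' Builds the \linkS4class{PointerPose} whose \code{\link{poseFrame}}
#' reproduces the given shaft and plane normal (the roll angle is solved
#' for).
#'
#' @param tip pointer tip (mm).
#' @param shaft unit shaft direction.
#' @param normal desired plane normal (must be perpendicular to shaft).
#' @param ... further arguments to \code{\link{pointerPose}}.
#' @return a \linkS4class{PointerPose}.
#' @export
poseFromFrame <- function(tip, shaft, normal, ...) {
  s <- .unit(shaft)
  n <- .unit(normal - sum(normal * s) * s)
  lateral <- .cross3(n, s)
  r0 <- .rollReference(s)
  roll <- atan2(sum(.cross3(r0, lateral) * s), sum(r0 * lateral)) * 180 / pi
  pointerPose(tip, s, roll = roll, ...)
}

#' Isolate the analyzed cutting-plane area
#'
#' Lattice of world points on the cutting plane: \code{length} mm along the
#' shaft from the tip and \code{halfWidth} mm to both sides, at \code{step}
#' mm spacing (defaults give the 30 x 11 mm window as 61 x 23 points).
#'
#' @param pose a \linkS4class{PointerPose}.
#' @param spec a \linkS4class{PlaneSamplingSpec}.
#' @return n x 3 matrix of coplanar points with attribute \code{lattice}
#'   (nLength, nWidth); row order runs fastest along the shaft.
#' @export
isolateArea <- function(pose, spec = planeSamplingSpec()) {
  fr <- poseFrame(pose)
  sSteps <- spec@step * (0:floor(spec@length / spec@step))
  tSteps <- spec@step * (-floor(spec@halfWidth / spec@step):
                           floor(spec@halfWidth / spec@step))
  g <- expand.grid(s = sSteps, t = tSteps)
  pts <- matrix(pose@tip, nrow(g), 3, byrow = TRUE) +
    outer(g$s, fr$shaft) + outer(g$t, fr$lateral)
  attr(pts, "lattice") <- c(length(sSteps), length(tSteps))
  pts
}

#' Zone codes of the joint tumor/carotid classification
#'
#' @return character vector: R, O1, O2, O3, O4, Y1, Y2, G, B.
#' @export
zoneCodes <- function() c("R", "O1", "O2", "O3", "O4", "Y1", "Y2", "G", "B")

#' Classify points by joint distance to carotid and tumor
#'
#' Nine-way partition of the (d_ICA, d_tumor) plane: R into the carotid
#' (d_ICA <= 0); O1-O4 within the 0-2 mm carotid danger zone, subdivided by
#' tumor distance (into tumor / <5 / 5-10 / >10 mm); Y1, Y2, G, B beyond
#' 2 mm from the carotid with the same tumor subdivision. Boundary
#' conventions: d_ICA = 2 falls in the danger zone (an adequate carotid
#' distance is strictly greater than 2 mm); tumor distances of exactly 5 and
#' 10 mm are "clear" (the 5-10 mm band is closed).
#'
#' @param dIca signed distance(s) to the carotid surface, mm.
#' @param dTumor signed distance(s) to the tumor surface, mm.
#' @return character vector of zone codes.
#' @export
classifyPoint <- function(dIca, dTumor) {
  if (length(dIca) != length(dTumor))
    stop("dIca and dTumor must have equal length")
  if (anyNA(dIca) || anyNA(dTumor) || any(!is.finite(dIca)) ||
      any(!is.finite(dTumor)))
    stop("distances must be finite")
  tumorBand <- ifelse(dTumor <= 0, 1L,
               ifelse(dTumor < 5, 2L,
               ifelse(dTumor <= 10, 3L, 4L)))
  out <- character(length(dIca))
  damage <- dIca <= 0
  danger <- !damage & dIca <= 2
  adequate <- dIca > 2
  out[damage] <- "R"
  out[danger] <- c("O1", "O2", "O3", "O4")[tumorBand[danger]]
  out[adequate] <- c("Y1", "Y2", "G", "B")[tumorBand[adequate]]
  out
}

#' Evaluate a cutting plane against tumor and carotid distance fields
#'
#' Samples both signed distance fields at every lattice point of the
#' isolated area (trilinear interpolation) and assigns the zone code per
#' point. Any sample outside a field's grid raises an error naming the
#' point.
#'
#' @param pose a \linkS4class{PointerPose}.
#' @param tumorField,icaField \linkS4class{DistanceField} objects sharing the
#'   pose's world frame.
#' @param spec a \linkS4class{PlaneSamplingSpec}.
#' @return a \linkS4class{MarginPlaneMap}.
#' @export
evaluatePlane <- function(pose, tumorField, icaField,
                          spec = planeSamplingSpec()) {
  pts <- isolateArea(pose, spec)
  lat <- attr(pts, "lattice")
  dT <- distanceAt(tumorField, pts)
  dI <- distanceAt(icaField, pts)
  zone <- classifyPoint(dI, dT)
  new("MarginPlaneMap", points = pts,
      dTumor = matrix(dT, lat[1], lat[2]),
      dIca = matrix(dI, lat[1], lat[2]),
      zone = matrix(zone, lat[1], lat[2]),
      pose = pose, samplingSpec = spec)
}

#' Summarize a margin plane map
#'
#' Zone fractions plus the plane-level safety flags: intratumoral (any point
#' at or inside the tumor surface) versus adequate margin; and exactly one
#' of carotid damaged (any point at or inside the vessel wall), danger zone
#' (no damage but some point within 2 mm) or carotid adequate (all points
#' beyond 2 mm).
#'
#' @param map a \linkS4class{MarginPlaneMap}.
#' @return a \linkS4class{ZoneSummary}.
#' @export
summarizePlane <- function(map) {
  n <- length(map@zone)
  if (n == 0L) stop("empty plane map")
  fr <- as.vector(table(factor(map@zone, levels = zoneCodes()))) / n
  names(fr) <- zoneCodes()
  dT <- map@dTumor; dI <- map@dIca
  intratumoral <- any(dT <= 0)
  icaDamaged <- any(dI <= 0)
  dangerZone <- !icaDamaged && any(dI <= 2)
  flags <- c(intratumoral = intratumoral,
             adequateMargin = !intratumoral,
             icaDamaged = icaDamaged,
             dangerZone = dangerZone,
             icaAdequate = !icaDamaged && !dangerZone)
  new("ZoneSummary", fractions = fr, flags = flags, nPoints = as.integer(n))
}

#' Proximity alert state at the pointer tip
#'
#' Breach when the tip is at or inside the vessel wall (the beeping alarm),
#' proximity within the alert margin (the flow-sound alarm), clear
#' otherwise.
#'
#' @param tip world point (mm), inside the field grid.
#' @param icaField carotid \linkS4class{DistanceField}.
#' @param margin alert margin, mm (default 2).
#' @return one of "breach", "proximity", "clear".
#' @export
evaluateAlert <- function(tip, icaField, margin = 2) {
  d <- distanceAt(icaField, matrix(tip, 1))
  if (d <= 0) "breach" else if (d <= margin) "proximity" else "clear"
}

#' Zone color table
#'
#' @return named character vector of hex colors per zone code.
#' @export
zoneColors <- function() {
  c(R = "#C62828", O1 = "#E65100", O2 = "#EF6C00", O3 = "#F57C00",
    O4 = "#FB8C00", Y1 = "#F9A825", Y2 = "#FDD835", G = "#43A047",
    B = "#1E88E5")
}

#' Render a margin plane map as a color-scaled PNG
#'
#' One pixel per lattice point (optionally integer-upscaled), tip row at the
#' top, lateral axis across; decorated with a frame, 5-mm tick marks on both
#' axes and a zone color legend strip. Output bytes are identical for
#' identical maps.
#'
#' @param map a \linkS4class{MarginPlaneMap}.
#' @param path output PNG path.
#' @param scale integer pixel upscaling of the data block (default 1).
#' @return the path, invisibly.
#' @export
renderColormap <- function(map, path, scale = 1L) {
  cols <- zoneColors()
  zm <- map@zone
  nL <- nrow(zm); nW <- ncol(zm)
  rgb <- grDevices::col2rgb(cols[zm]) / 255 # 3 x (nL*nW), column-major over zm
  data <- array(0, c(nL, nW, 3))
  for (ch in 1:3) data[, , ch] <- matrix(rgb[ch, ], nL, nW)
  if (scale > 1L) {
    ri <- rep(seq_len(nL), each = scale)
    ci <- rep(seq_len(nW), each = scale)
    data <- data[ri, ci, , drop = FALSE]
  }
  h <- dim(data)[1]; w <- dim(data)[2]
  mar <- 4L; frame <- 1L; legendW <- 8L
  H <- h + 2L * (mar + frame)
  W <- w + 2L * (mar + frame) + legendW + mar
  img <- array(1, c(H, W, 3)) # white canvas
  y0 <- mar + frame; x0 <- mar + frame
  img[(y0 - frame + 1L):(y0 + h + frame), (x0 - frame + 1L):(x0 + w + frame), ] <- 0
  img[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), ] <- data
  # 5-mm ticks in the margins
  step <- map@samplingSpec@step * ifelse(scale > 1L, 1 / scale, 1)
  tickEvery <- max(1L, round(5 / map@samplingSpec@step) * max(1L, scale))
  for (r in seq(1L, h, by = tickEvery))
    img[y0 + r, 1:mar, ] <- 0
  for (c2 in seq(1L, w, by = tickEvery))
    img[1:mar, x0 + c2, ] <- 0
  # legend strip
  lx <- x0 + w + frame + mar
  sq <- max(3L, (H - 2L * mar) %/% (9L * 2L))
  for (i in seq_along(cols)) {
    ys <- mar + (i - 1L) * 2L * sq
    if (ys + sq > H) break
    rgbc <- grDevices::col2rgb(cols[i]) / 255
    for (ch in 1:3)
      img[(ys + 1L):(ys + sq), lx:(lx + legendW - mar), ch] <- rgbc[ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Export a margin plane map as CSV
#'
#' Columns: lattice indices i (along shaft) and j (lateral), world x, y, z,
#' the two signed distances and the zone code.
#'
#' @param map a \linkS4class{MarginPlaneMap}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMapCsv <- function(map, path) {
  lat <- dim(map@zone)
  idx <- expand.grid(i = seq_len(lat[1]), j = seq_len(lat[2]))
  df <- data.frame(i = idx$i, j = idx$j,
                   x = map@points[, 1], y = map@points[, 2],
                   z = map@points[, 3],
                   d_tumor = as.vector(map@dTumor),
                   d_ica = as.vector(map@dIca),
                   zone = as.vector(map@zone))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a pointer pose as JSON
#'
#' @param pose a \linkS4class{PointerPose}.
#' @param path file path.
#' @return \code{readPoseJson} returns the \linkS4class{PointerPose}.
#' @export
writePoseJson <- function(pose, path) {
  jsonlite::write_json(list(tip = pose@tip, shaft_axis = pose@shaftAxis,
                            roll = pose@roll, angulation = pose@angulation,
                            approach = pose@approach, scope = pose@scope,
                            breach_unresolved = pose@breachUnresolved),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePoseJson
#' @export
readPoseJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pointerPose(x$tip, x$shaft_axis, roll = x$roll, angulation = x$angulation,
              approach = x$approach, scope = x$scope,
              breachUnresolved = isTRUE(x$breach_unresolved))
}
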