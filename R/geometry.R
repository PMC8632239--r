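# Analytic surface meshes, mesh measures and primitive voxelization.

.unit <- function(v) v / sqrt(sum(v^2))

#' Construct a triangle mesh
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return a \linkS4class{TriangleMesh}.
#' @export
triangleMesh <- function(vertices, faces) {
  new("TriangleMesh", vertices = as.matrix(vertices),
      faces = matrix(as.integer(as.matrix(faces)), ncol = 3))
}

#' UV-sphere surface mesh
#'
#' @param center sphere center (mm).
#' @param radius sphere radius (mm).
#' @param nTheta segments around the equator.
#' @param nPhi segments pole to pole.
#' @return a closed \linkS4class{TriangleMesh}.
#' @export
sphereMesh <- function(center = c(0, 0, 0), radius = 1, nTheta = 96L, nPhi = 48L) {
  ellipsoidMesh(center, c(radius, radius, radius), nTheta = nTheta, nPhi = nPhi)
}

#' Ellipsoid surface mesh
#'
#' @param center ellipsoid center (mm).
#' @param semiAxes numeric(3) semi-axis lengths (mm).
#' @inheritParams sphereMesh
#' @return a closed \linkS4class{TriangleMesh}.
#' @export
ellipsoidMesh <- function(center = c(0, 0, 0), semiAxes = c(1, 1, 1),
                          nTheta = 96L, nPhi = 48L) {
  nTheta <- as.integer(nTheta); nPhi <- as.integer(nPhi)
  # interior ring vertices (phi strictly between poles) plus two pole vertices
  phi <- seq(0, pi, length.out = nPhi + 1L)[-c(1L, nPhi + 1L)]
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  g <- expand.grid(theta = theta, phi = phi)
  V <- cbind(sin(g$phi) * cos(g$theta), sin(g$phi) * sin(g$theta), cos(g$phi))
  V <- rbind(V, c(0, 0, 1), c(0, 0, -1))
  V <- sweep(sweep(V, 2, semiAxes, "*"), 2, center, "+")
  nRing <- length(phi)
  iTop <- nTheta * nRing + 1L
  iBot <- iTop + 1L
  idx <- function(t, p) (p - 1L) * nTheta + ((t - 1L) %% nTheta) + 1L
  F <- list()
  # pole caps
  F[[1]] <- cbind(iTop, idx(1:nTheta, 1L), idx(2:(nTheta + 1L), 1L))
  F[[2]] <- cbind(iBot, idx(2:(nTheta + 1L), nRing), idx(1:nTheta, nRing))
  # bands
  for (p in seq_len(nRing - 1L)) {
    a <- idx(1:nTheta, p); b <- idx(2:(nTheta + 1L), p)
    c2 <- idx(1:nTheta, p + 1L); d <- idx(2:(nTheta + 1L), p + 1L)
    F[[length(F) + 1L]] <- cbind(a, c2, b)
    F[[length(F) + 1L]] <- cbind(b, c2, d)
  }
  triangleMesh(V, do.call(rbind, F))
}

# Parallel-transport frames along a polyline (n x 3): returns list of unit
# tangents and two normals per point.
.ptFrames <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[1, ] <- .unit(pts[2, ] - pts[1, ])
  if (n > 2)
    for (i in 2:(n - 1)) tg[i, ] <- .unit(pts[i + 1, ] - pts[i - 1, ])
  tg[n, ] <- .unit(pts[n, ] - pts[n - 1, ])
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(0, 1, 0)
  u <- matrix(0, n, 3); w <- matrix(0, n, 3)
  u[1, ] <- .unit(ref - sum(ref * tg[1, ]) * tg[1, ])
  w[1, ] <- .cross3(tg[1, ], u[1, ])
  for (i in 2:n) {
    # rotate previous normal into the new tangent plane
    ui <- u[i - 1, ] - sum(u[i - 1, ] * tg[i, ]) * tg[i, ]
    if (sqrt(sum(ui^2)) < 1e-12) ui <- u[i - 1, ]
    u[i, ] <- .unit(ui)
    w[i, ] <- .cross3(tg[i, ], u[i, ])
  }
  list(tangent = tg, u = u, w = w)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Catmull-Rom resampling of control points (n x 3) to a dense polyline.
.catmullRom <- function(ctrl, nPer = 16L) {
  n <- nrow(ctrl)
  if (n < 3L) {
    t <- seq(0, 1, length.out = max(2L, nPer))
    return(outer(1 - t, ctrl[1, ]) + outer(t, ctrl[n, ]))
  }
  P <- rbind(ctrl[1, ], ctrl, ctrl[n, ]) # clamp ends
  out <- list()
  for (i in 2:(nrow(P) - 2L)) {
    t <- seq(0, 1, length.out = nPer + 1L)[-(nPer + 1L)]
    p0 <- P[i - 1, ]; p1 <- P[i, ]; p2 <- P[i + 1, ]; p3 <- P[i + 2, ]
    tt <- cbind(1, t, t^2, t^3)
    M <- 0.5 * rbind(c(0, 2, 0, 0), c(-1, 0, 1, 0), c(2, -5, 4, -1), c(-1, 3, -3, 1))
    out[[length(out) + 1L]] <- tt %*% M %*% rbind(p0, p1, p2, p3)
  }
  rbind(do.call(rbind, out), ctrl[n, ])
}

#' Swept-tube surface mesh along a polyline
#'
#' The centerline is a clamped piecewise-cubic (Catmull-Rom) curve through the
#' control points; straight runs of control points produce an exact cylinder.
#' Ends are capped with triangle fans, so the mesh is closed.
#'
#' @param controlPoints n x 3 matrix of centerline control points (mm).
#' @param radius tube radius (mm).
#' @param nAround segments around the tube.
#' @param nPer curve samples per control segment.
#' @return a closed \linkS4class{TriangleMesh}.
#' @export
tubeMesh <- function(controlPoints, radius = 2.5, nAround = 48L, nPer = 16L) {
  ctr <- .catmullRom(as.matrix(controlPoints), nPer = nPer)
  fr <- .ptFrames(ctr)
  n <- nrow(ctr)
  ang <- seq(0, 2 * pi, length.out = nAround + 1L)[-(nAround + 1L)]
  V <- matrix(0, n * nAround, 3)
  for (i in seq_len(n)) {
    ring <- ctr[rep(i, nAround), ] +
      radius * (outer(cos(ang), fr$u[i, ]) + outer(sin(ang), fr$w[i, ]))
    V[((i - 1L) * nAround + 1L):(i * nAround), ] <- ring
  }
  iStart <- nrow(V) + 1L
  iEnd <- nrow(V) + 2L
  V <- rbind(V, ctr[1, ], ctr[n, ])
  idx <- function(i, a) (i - 1L) * nAround + ((a - 1L) %% nAround) + 1L
  F <- list()
  for (i in seq_len(n - 1L)) {
    a <- idx(i, 1:nAround); b <- idx(i, 2:(nAround + 1L))
    c2 <- idx(i + 1L, 1:nAround); d <- idx(i + 1L, 2:(nAround + 1L))
    F[[length(F) + 1L]] <- cbind(a, b, c2)
    F[[length(F) + 1L]] <- cbind(b, d, c2)
  }
  F[[length(F) + 1L]] <- cbind(iStart, idx(1L, 2:(nAround + 1L)), idx(1L, 1:nAround))
  F[[length(F) + 1L]] <- cbind(iEnd, idx(n, 1:nAround), idx(n, 2:(nAround + 1L)))
  triangleMesh(V, do.call(rbind, F))
}

#' @rdname NaviMargin-generics
#' @export
setMethod("meshVolume", "TriangleMesh", function(x) {
  V <- x@vertices; F <- x@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c2 <- V[F[, 3], , drop = FALSE]
  # divergence theorem: sum of signed tetrahedron volumes against the origin
  s <- a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) -
       a[, 2] * (b[, 1] * c2[, 3] - b[, 3] * c2[, 1]) +
       a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])
  abs(sum(s)) / 6
})

#' @rdname NaviMargin-generics
#' @export
setMethod("isWatertight", "TriangleMesh", function(x) {
  F <- x@faces
  if (nrow(F) == 0L) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
})

#' Merge triangle meshes into one soup
#'
#' Concatenates vertex and face lists; no boolean union is attempted. Used for
#' multi-component structures (e.g. tumor body plus posterior lobe), whose
#' union surface is a subset of the concatenated component surfaces.
#'
#' @param meshes list of \linkS4class{TriangleMesh}.
#' @return a \linkS4class{TriangleMesh}.
#' @export
mergeMeshes <- function(meshes) {
  off <- 0L
  V <- list(); F <- list()
  for (m in meshes) {
    V[[length(V) + 1L]] <- m@vertices
    F[[length(F) + 1L]] <- m@faces + off
    off <- off + nrow(m@vertices)
  }
  triangleMesh(do.call(rbind, V), do.call(rbind, F))
}

#' Minimal distance between two triangle meshes
#'
#' Minimum over vertex-to-face distances evaluated in both directions; exact
#' up to the chord error of the tessellation.
#'
#' @param meshA,meshB \linkS4class{TriangleMesh} objects.
#' @return distance in mm.
#' @export
meshMinDistance <- function(meshA, meshB) {
  .cpp_mesh_min_dist(meshA@vertices, meshA@faces, meshB@vertices, meshB@faces)
}

#' Minimal distance from points to a mesh surface
#'
#' @param points n x 3 matrix of world points (mm).
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return numeric vector of unsigned distances (mm).
#' @export
pointsToMeshDistance <- function(points, mesh) {
  .cpp_points_to_mesh(as.matrix(points), mesh@vertices, mesh@faces)
}

# ---- voxel grid helpers ----------------------------------------------------

# World coordinates of all voxel centers along one axis.
.axisCoords <- function(spec, axis) {
  spec@origin[axis] + spec@spacing[axis] * (seq_len(spec@dims[axis]) - 1)
}

.emptyMask <- function(spec) {
  new("LabelMask", dims = spec@dims, spacing = spec@spacing,
      origin = spec@origin,
      values = array(FALSE, dim = spec@dims))
}

# Occupancy of an ellipsoid on the voxel-center grid, restricted to its
# bounding box for speed.
.voxelizeEllipsoid <- function(spec, center, semiAxes) {
  m <- .emptyMask(spec)
  xs <- .axisCoords(spec, 1); ys <- .axisCoords(spec, 2); zs <- .axisCoords(spec, 3)
  ix <- which(abs(xs - center[1]) <= semiAxes[1] + spec@spacing[1])
  iy <- which(abs(ys - center[2]) <= semiAxes[2] + spec@spacing[2])
  iz <- which(abs(zs - center[3]) <= semiAxes[3] + spec@spacing[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(m)
  gx <- (xs[ix] - center[1]) / semiAxes[1]
  gy <- (ys[iy] - center[2]) / semiAxes[2]
  gz <- (zs[iz] - center[3]) / semiAxes[3]
  sub <- outer(gx^2, gy^2, "+")
  sub <- outer(sub, gz^2, "+") <= 1
  m@values[ix, iy, iz] <- m@values[ix, iy, iz] | sub
  m
}

.voxelizeSphere <- function(spec, center, radius) {
  .voxelizeEllipsoid(spec, center, rep(radius, 3))
}

# Occupancy of a swept tube: voxel centers within `radius` of the densely
# resampled centerline.
.voxelizeTube <- function(spec, controlPoints, radius, nPer = 16L) {
  ctr <- .catmullRom(as.matrix(controlPoints), nPer = nPer)
  m <- .emptyMask(spec)
  xs <- .axisCoords(spec, 1); ys <- .axisCoords(spec, 2); zs <- .axisCoords(spec, 3)
  pad <- radius + max(spec@spacing)
  ix <- which(xs >= min(ctr[, 1]) - pad & xs <= max(ctr[, 1]) + pad)
  iy <- which(ys >= min(ctr[, 2]) - pad & ys <= max(ctr[, 2]) + pad)
  iz <- which(zs >= min(ctr[, 3]) - pad & zs <= max(ctr[, 3]) + pad)
  if (!length(ix) || !length(iy) || !length(iz)) return(m)
  g <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
  d2 <- .pointsToSegmentsSq(g, ctr)
  sub <- array(d2 <= radius^2, dim = c(length(ix), length(iy), length(iz)))
  m@values[ix, iy, iz] <- m@values[ix, iy, iz] | sub
  m
}

# Squared distance from each point to a polyline given by consecutive vertices.
.pointsToSegmentsSq <- function(pts, poly) {
  n <- nrow(poly)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, (ap %*% ab) / len2)) else 0
    dd <- ap - outer(as.vector(t), ab)
    best <- pmin(best, rowSums(dd^2))
  }
  best
}

# Hollow ellipsoid shell (outer minus inner).
.voxelizeShell <- function(spec, center, outerSemi, innerSemi) {
  outer <- .voxelizeEllipsoid(spec, center, outerSemi)
  inner <- .voxelizeEllipsoid(spec, center, innerSemi)
  outer@values <- outer@values & !inner@values
  outer
}
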