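# Paired-point rigid registration with fiducial registration error gating.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix with det = +1.
#' @param translation numeric(3) in mm.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis rotation axis (will be normalized).
#' @param angleDeg rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  a <- .unit(axis)
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points n x 3 matrix (or numeric(3)) of world points.
#' @return transformed points, same shape.
#' @export
applyTransform <- function(transform, points) {
  p <- points
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, 1)
  out <- sweep(as.matrix(p) %*% t(transform@rotation), 2,
               transform@translation, "+")
  if (vec) out[1, ] else out
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first, then \code{a}.
#'
#' @param a,b \linkS4class{RigidTransform} objects.
#' @return their composition as a \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.vector(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.vector(Rt %*% transform@translation))
}

#' Closed-form paired-point rigid registration
#'
#' Least-squares rigid fit of matched point lists (image divots to tracker
#' divots) by the SVD method, with the standard reflection guard (the
#' smallest singular direction is flipped if the optimum of the orthogonal
#' problem is a reflection). The fiducial registration error (FRE) is the RMS
#' residual over pairs; registrations with FRE at or below \code{threshold}
#' (default 1 mm) are accepted.
#'
#' @param source n x 3 matrix of source points (n >= 3, non-collinear).
#' @param target n x 3 matrix of matched target points.
#' @param threshold acceptance gate on the FRE, mm.
#' @return a \linkS4class{RegistrationResult}.
#' @export
registerPairedPoints <- function(source, target, threshold = 1.0) {
  s <- as.matrix(source); g <- as.matrix(target)
  if (nrow(s) != nrow(g)) stop("source and target must have equal length")
  if (nrow(s) < 3L)
    stop("degenerate configuration: at least 3 point pairs required")
  sc <- colMeans(s); gc <- colMeans(g)
  s0 <- sweep(s, 2, sc); g0 <- sweep(g, 2, gc)
  if (qr(s0)$rank < 2L)
    stop("degenerate configuration: source points are collinear")
  H <- crossprod(s0, g0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t0 <- gc - as.vector(R %*% sc)
  tf <- rigidTransform(R, t0)
  res <- applyTransform(tf, s) - g
  freVal <- sqrt(mean(rowSums(res^2)))
  new("RegistrationResult", transform = tf, fre = freVal,
      threshold = threshold, accepted = freVal <= threshold)
}

#' Register a phantom's fiducials
#'
#' Convenience wrapper: registers the measured (tracked) divots onto the true
#' (image) positions.
#'
#' @param fids a \linkS4class{FiducialSet}.
#' @param threshold FRE acceptance gate, mm.
#' @return a \linkS4class{RegistrationResult}.
#' @export
registerFiducials <- function(fids, threshold = 1.0) {
  registerPairedPoints(fids@measuredPositions, fids@truePositions,
                       threshold = threshold)
}

# ---- persistence -----------------------------------------------------------

#' Read/write fiducial CSV (name,x,y,z)
#'
#' @param path file path.
#' @param fids a \linkS4class{FiducialSet} (for writing).
#' @param which which position set to write ("true" or "measured").
#' @return \code{readFiducialCsv} returns an n x 3 matrix with rownames.
#' @export
readFiducialCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  m
}

#' @rdname readFiducialCsv
#' @export
writeFiducialCsv <- function(fids, path, which = c("true", "measured")) {
  which <- match.arg(which)
  m <- if (which == "true") fids@truePositions else fids@measuredPositions
  df <- data.frame(name = sprintf("F%02d", seq_len(nrow(m))),
                   x = m[, 1], y = m[, 2], z = m[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a rigid transform as JSON (row-major rotation + translation)
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param path file path.
#' @return the path, invisibly; \code{readTransformJson} returns the
#'   \linkS4class{RigidTransform}.
#' @export
writeTransformJson <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.vector(t(transform@rotation)),
                            translation = transform@translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
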