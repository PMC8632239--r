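# NIfTI and STL persistence with explicit grid affines.

.gridAffine <- function(obj) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(obj@spacing)
  aff[1:3, 4] <- obj@origin
  aff
}

#' Write a voxel grid object as NIfTI
#'
#' Masks are written as uint8, distance fields and volumes as float32. The
#' sform affine encodes the RAS world convention (voxel center (0,0,0) at the
#' grid origin).
#'
#' @param x a \linkS4class{LabelMask}, \linkS4class{DistanceField} or
#'   \linkS4class{ScanVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeNiftiGrid <- function(x, path) {
  arr <- if (is.logical(x@values)) array(as.integer(x@values), dim = x@dims)
         else x@values
  im <- RNifti::asNifti(arr)
  aff <- .gridAffine(x)
  RNifti::sform(im) <- structure(aff, code = 2L) # pixdim follows the sform
  RNifti::writeNifti(im, path,
                     datatype = if (is.logical(x@values)) "uint8" else "float")
  invisible(path)
}

#' Read a NIfTI file back into a grid object
#'
#' @param path NIfTI path.
#' @param as one of "mask", "field", "volume".
#' @return the corresponding voxel grid object.
#' @export
readNiftiGrid <- function(path, as = c("mask", "field", "volume")) {
  as <- match.arg(as)
  im <- RNifti::readNifti(path)
  aff <- RNifti::xform(im)
  spacing <- diag(aff[1:3, 1:3])
  origin <- aff[1:3, 4]
  dims <- dim(im)
  arr <- array(as.vector(im), dim = dims)
  switch(as,
    mask = new("LabelMask", dims = as.integer(dims), spacing = spacing,
               origin = origin, values = array(arr > 0.5, dim = dims)),
    field = new("DistanceField", dims = as.integer(dims), spacing = spacing,
                origin = origin, values = arr),
    volume = new("ScanVolume", dims = as.integer(dims), spacing = spacing,
                 origin = origin, values = arr))
}

#' Write a triangle mesh as binary STL (units mm)
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output .stl path.
#' @param header 80-byte header text.
#' @return the path, invisibly.
#' @export
writeSTL <- function(mesh, path, header = "NaviMargin binary STL") {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(formatC(header, width = -80))
  length(hdr) <- 80L
  hdr[is.na(hdr)] <- as.raw(0)
  writeBin(hdr, con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; c2 <- V[F[i, 3], ]
    n <- .cross3(b - a, c2 - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, c2)), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are de-duplicated exactly, so meshes written by
#' \code{\link{writeSTL}} round-trip to a connected surface (up to float32
#' precision).
#'
#' @param path .stl path.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
  rec <- readBin(con, "raw", nf * 50)
  recs <- matrix(rec, nrow = 50)
  tri <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    vals <- readBin(recs[1:48, i], "numeric", 12, size = 4,
                    endian = "little")
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, byrow = TRUE)
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  V <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  triangleMesh(V, F)
}
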