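#' @name NaviMargin-generics
#' @title Generics for grid, mesh and result accessors
#' @description Accessor generics shared across the package's classes.
#' @param x,object an object of the relevant class.
#' @param ... passed to methods.
NULL

#' @rdname NaviMargin-generics
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname NaviMargin-generics
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' @rdname NaviMargin-generics
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("icaMask", function(x) standardGeneric("icaMask"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("boneMask", function(x) standardGeneric("boneMask"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("fiducials", function(x) standardGeneric("fiducials"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("presetOf", function(x) standardGeneric("presetOf"))

#' @rdname NaviMargin-generics
#' @export
setGeneric("fre", function(x) standardGeneric("fre"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("fittedTransform", function(x) standardGeneric("fittedTransform"))

#' @rdname NaviMargin-generics
#' @export
setGeneric("zoneFractions", function(x) standardGeneric("zoneFractions"))
#' @rdname NaviMargin-generics
#' @export
setGeneric("planeFlags", function(x) standardGeneric("planeFlags"))

# ---- simple accessor methods ----------------------------------------------

#' @rdname NaviMargin-generics
setMethod("gridDims", "VoxelGrid", function(x) x@dims)
#' @rdname NaviMargin-generics
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname NaviMargin-generics
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname NaviMargin-generics
setMethod("voxelValues", "VoxelGrid", function(x) x@values)

#' @rdname NaviMargin-generics
setMethod("gridDims", "VolumeSpec", function(x) x@dims)
#' @rdname NaviMargin-generics
setMethod("gridSpacing", "VolumeSpec", function(x) x@spacing)
#' @rdname NaviMargin-generics
setMethod("gridOrigin", "VolumeSpec", function(x) x@origin)

#' @rdname NaviMargin-generics
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname NaviMargin-generics
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname NaviMargin-generics
setMethod("tumorMask", "PhantomModel", function(x) x@masks$tumor)
#' @rdname NaviMargin-generics
setMethod("icaMask", "PhantomModel", function(x) x@masks$ica)
#' @rdname NaviMargin-generics
setMethod("boneMask", "PhantomModel", function(x) x@masks$bone)
#' @rdname NaviMargin-generics
setMethod("fiducials", "PhantomModel", function(x) x@fiducials)
#' @rdname NaviMargin-generics
setMethod("presetOf", "PhantomModel", function(x) x@preset)

#' @rdname NaviMargin-generics
setMethod("fre", "RegistrationResult", function(x) x@fre)
#' @rdname NaviMargin-generics
setMethod("isAccepted", "RegistrationResult", function(x) x@accepted)
#' @rdname NaviMargin-generics
setMethod("fittedTransform", "RegistrationResult", function(x) x@transform)

#' @rdname NaviMargin-generics
setMethod("zoneFractions", "ZoneSummary", function(x) x@fractions)
#' @rdname NaviMargin-generics
setMethod("planeFlags", "ZoneSummary", function(x) x@flags)
#' @rdname NaviMargin-generics
setMethod("zoneFractions", "TrialRecord", function(x) x@summary@fractions)
#' @rdname NaviMargin-generics
setMethod("planeFlags", "TrialRecord", function(x) x@summary@flags)

# ---- show methods ----------------------------------------------------------

setMethod("show", "VolumeSpec", function(object) {
  cat("VolumeSpec:", paste(object@dims, collapse = " x "), "voxels @",
      paste(object@spacing, collapse = "/"), "mm\n")
  cat("  intensities:", paste(names(object@intensities), object@intensities,
                              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PhantomPreset", function(object) {
  cat(sprintf("PhantomPreset %s: T-C clearance %.1f mm (%s)\n",
              object@id, object@tcClearance, object@posteriorExtent))
})

setMethod("show", "PhantomModel", function(object) {
  cat(sprintf("PhantomModel %s (configured T-C clearance %.1f mm)\n",
              object@preset@id, object@preset@tcClearance))
  cat(sprintf("  meshes: tumor %d faces, ICA %d faces, bone %d faces\n",
              nrow(object@tumorMesh@faces), nrow(object@icaMesh@faces),
              nrow(object@boneMesh@faces)))
  if (length(object@masks))
    cat("  masks on", paste(object@spec@dims, collapse = " x "), "grid\n")
})

setMethod("show", "DistanceField", function(object) {
  r <- range(object@values)
  cat(sprintf("DistanceField %s @ %.2g mm: range [%.2f, %.2f] mm\n",
              paste(object@dims, collapse = " x "), object@spacing[1],
              r[1], r[2]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: FRE = %.4f mm (threshold %.2f mm) -> %s\n",
              object@fre, object@threshold,
              if (object@accepted) "accepted" else "REJECTED"))
})

setMethod("show", "MarginPlaneMap", function(object) {
  d <- dim(object@zone)
  cat(sprintf("MarginPlaneMap: %d x %d points (%.0f x %.0f mm window)\n",
              d[1], d[2], object@samplingSpec@length,
              2 * object@samplingSpec@halfWidth))
  print(round(100 * table(factor(object@zone, levels = zoneCodes())) /
                prod(d), 1))
})

setMethod("show", "ZoneSummary", function(object) {
  cat("ZoneSummary over", object@nPoints, "points\n")
  print(round(100 * object@fractions, 1))
  cat("  flags:", paste(names(object@flags)[object@flags], collapse = ", "), "\n")
})

setMethod("show", "TrialRecord", function(object) {
  cat(sprintf("TrialRecord: surgeon %d, %s, %s, %s portion\n",
              object@surgeonId, object@presetId, object@setting,
              object@portion))
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison across settings:",
      paste(object@settings, collapse = ", "), "\n")
  df <- object@zoneStats
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 4) else v)
  print(df, row.names = FALSE)
})

setMethod("show", "GainResult", function(object) {
  cat(sprintf("Guidance gain (guided - unguided, percentage points):\n"))
  cat(sprintf("  clear margin : mean %.1f (range %.1f to %.1f)\n",
              object@meanGain[["clearMargin"]],
              object@rangeGain$clearMargin[1], object@rangeGain$clearMargin[2]))
  cat(sprintf("  carotid spare: mean %.1f (range %.1f to %.1f)\n",
              object@meanGain[["carotidSpared"]],
              object@rangeGain$carotidSpared[1], object@rangeGain$carotidSpared[2]))
})
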