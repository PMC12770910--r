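#' Voxel data accessor
#'
#' @param x A \code{HeadVolume}, \code{LabelMask} or \code{BinaryMask}.
#' @return The underlying 3-D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing accessor
#'
#' @param x An image object.
#' @return Numeric(3) spacing in mm/voxel.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Label map accessor
#'
#' @param x A \code{LabelMask}.
#' @return Named integer vector of class codes.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' Extract a single tissue class as a binary mask
#'
#' @param labels A \code{LabelMask}.
#' @param cls Class name, one of \code{names(labelMap(labels))}.
#' @return A \code{BinaryMask} that is 1 exactly where \code{labels == cls}.
#' @export
setGeneric("binarize", function(labels, cls) standardGeneric("binarize"))

#' Remove voxels anterior to a propagated cut boundary
#'
#' Applies the slice-wise anterior cut: voxels with 0-based anterior index
#' \code{x > adjusted[z]} are set to zero (background); the boundary voxel
#' itself is kept.
#'
#' @param x A \code{BinaryMask}, \code{LabelMask} or \code{HeadVolume}.
#' @param boundary A \code{CutBoundary} with the propagated component filled
#'   (see \code{\link{propagateBoundary}}).
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("cropToBoundary",
           function(x, boundary) standardGeneric("cropToBoundary"))

#' Rigid anterior/posterior tilt about the left-right axis
#'
#' Rotates the volume in the sagittal (X-Z) plane about the grid centre,
#' emulating a small registration error. Label and binary masks use
#' nearest-neighbour resampling; intensity volumes use bilinear resampling.
#' The grid is unchanged.
#'
#' @param x A \code{HeadVolume}, \code{LabelMask} or \code{BinaryMask}.
#' @param degrees Tilt angle; positive pitches the head forward
#'   (anterior-down). Must satisfy \code{abs(degrees) <= 15}.
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("applyTilt", function(x, degrees) standardGeneric("applyTilt"))

#' @rdname voxels
#' @export
setMethod("voxels", "HeadVolume", function(x) x@data)
#' @rdname voxels
#' @export
setMethod("voxels", "LabelMask", function(x) x@data)
#' @rdname voxels
#' @export
setMethod("voxels", "BinaryMask", function(x) x@data)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "HeadVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname labelMap
#' @export
setMethod("labelMap", "LabelMask", function(x) x@labelMap)

#' @export
setMethod("dim", "HeadVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@data))
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))

.showGrid <- function(object, what) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              what, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
}

setMethod("show", "HeadVolume", function(object) {
  .showGrid(object, "HeadVolume")
  r <- range(object@data)
  cat(sprintf("  value range [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "LabelMask", function(object) {
  .showGrid(object, "LabelMask")
  tab <- tabulate(match(as.vector(object@data), object@labelMap),
                  nbins = length(object@labelMap))
  cat("  voxels per class:\n")
  for (i in seq_along(object@labelMap))
    cat(sprintf("    %-16s %d\n", names(object@labelMap)[i], tab[i]))
})

setMethod("show", "BinaryMask", function(object) {
  .showGrid(object, "BinaryMask")
  cat(sprintf("  foreground voxels: %d\n", sum(object@data != 0)))
})

setMethod("show", "CutBoundary", function(object) {
  cat(sprintf("CutBoundary over %d slices", length(object@top)))
  if (length(object@adjusted))
    cat(sprintf("; propagated boundary range [%d, %d]",
                min(object@adjusted), max(object@adjusted)))
  cat("\n")
})

setMethod("show", "ThicknessResult", function(object) {
  cat(sprintf("ThicknessResult: median %.3f mm (central trim kept %d of %d samples)\n",
              object@medianMm, object@nKept, object@nTotal))
  cat(sprintf("  slice band [%d, %d) anchored at z0 = %d\n",
              object@band[1], object@band[2], object@z0))
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("%s = %.4f (95%% CI %.4f-%.4f), n = %d subjects\n",
              object@statistic, object@value,
              object@ciLower, object@ciUpper, object@n))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d grid, brain semi-axes %s mm, wall %.1f mm, seed %d\n",
              object@shape[1], object@shape[2], object@shape[3],
              paste(object@brainSemiAxes, collapse = " x "),
              object@wallMm, object@seed))
})
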