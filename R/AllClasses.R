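#' @import methods
NULL

#' Default tissue label map
#'
#' Integer codes for the five head-tissue classes used throughout the
#' package: background (0), brain (1), skull (2), subcutaneous fat (3) and
#' temporalis-type muscle (4).
#'
#' @return Named integer vector mapping class names to voxel values.
#' @export
defaultLabelMap <- function() {
  c(background = 0L, brain = 1L, skull = 2L,
    subcutaneous_fat = 3L, muscle = 4L)
}

.checkSpacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) ||
      anyNA(spacing) || any(spacing <= 0) || any(!is.finite(spacing)))
    return("'spacing' must be three positive finite numbers (mm/voxel)")
  NULL
}

#' HeadVolume: a 3-D scalar head image
#'
#' A 3-D scalar grid (MRI intensity in arbitrary units, or CT attenuation in
#' Hounsfield units) with voxel spacing, held in the package's canonical
#' orientation: the first array axis increases posterior to anterior, the
#' second right to left, the third inferior to superior.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot spacing Numeric(3), voxel spacing in mm along the three axes.
#' @slot sourceOrientation Orientation string of the file the volume was read
#'   from (e.g. \code{"RAS"}), so writes can restore the original axis order;
#'   \code{NA} for volumes created in memory.
#' @export
setClass("HeadVolume",
  representation(data = "array", spacing = "numeric",
                 sourceOrientation = "character"),
  prototype(sourceOrientation = NA_character_),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("'data' must be a 3-D array")
    .checkSpacing(object@spacing)
  })

#' LabelMask: a 3-D tissue label volume
#'
#' Integer voxel labels over the head-tissue classes of
#' \code{\link{defaultLabelMap}} (or a user-supplied map).
#'
#' @slot data 3-D integer array; every value must be a code in the label map.
#' @slot labelMap Named integer vector mapping class names to voxel codes.
#' @slot spacing Numeric(3) voxel spacing in mm.
#' @slot sourceOrientation Orientation string of the source file, or \code{NA}.
#' @export
setClass("LabelMask",
  representation(data = "array", labelMap = "integer", spacing = "numeric",
                 sourceOrientation = "character"),
  prototype(sourceOrientation = NA_character_),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("'data' must be a 3-D array")
    if (is.null(names(object@labelMap)) || anyDuplicated(object@labelMap) ||
        anyDuplicated(names(object@labelMap)))
      return("'labelMap' must be a named integer vector with unique names and values")
    bad <- setdiff(unique(as.vector(object@data)), object@labelMap)
    if (length(bad))
      return(sprintf("voxel values not in label map: %s",
                     paste(bad, collapse = ", ")))
    .checkSpacing(object@spacing)
  })

#' BinaryMask: a 3-D 0/1 mask
#'
#' @slot data 3-D array with values in \{0, 1\}.
#' @slot spacing Numeric(3) voxel spacing in mm.
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("'data' must be a 3-D array")
    if (!all(object@data %in% c(0, 1)))
      return("mask values must be 0 or 1")
    .checkSpacing(object@spacing)
  })

#' CutBoundary: per-slice anterior cut positions
#'
#' For each axial slice z the most anterior brain voxel index T(z) ("top"),
#' and the propagated boundary T*(z) ("adjusted") obtained as a running
#' maximum from the most inferior slice upward. Indices are 0-based to match
#' the defining recurrence T*(z) = max(T(z), T*(z-1)) with T*(-1) = 0;
#' slices without brain tissue carry top = 0.
#'
#' @slot top Integer vector, one 0-based anterior extreme per slice.
#' @slot adjusted Integer vector of propagated boundaries; empty until
#'   \code{\link{propagateBoundary}} is applied.
#' @export
setClass("CutBoundary",
  representation(top = "integer", adjusted = "integer"),
  prototype(adjusted = integer(0)),
  validity = function(object) {
    if (any(object@top < 0)) return("'top' must be non-negative")
    if (length(object@adjusted)) {
      if (length(object@adjusted) != length(object@top))
        return("'adjusted' must match 'top' in length")
      if (any(diff(object@adjusted) < 0))
        return("'adjusted' must be non-decreasing in z")
      if (any(object@adjusted < object@top))
        return("'adjusted' must be >= 'top' slice-wise")
    }
    NULL
  })

#' ThicknessResult: aggregated skull-thickness estimate
#'
#' @slot medianMm Median thickness (mm) over the centrally trimmed samples.
#' @slot nTotal Number of valid (non-missing) tangent-normal samples pooled.
#' @slot nKept Number of samples inside the central trim band.
#' @slot z0 0-based reference slice (orbital-roof landmark) the band was
#'   anchored to.
#' @slot band Integer(2), 0-based half-open slice band \code{[start, end)}.
#' @slot samples data.frame of individual measurements
#'   (slice, x, y, thickness_mm, kept).
#' @slot perSlice data.frame of per-slice sample counts and degeneracy flags.
#' @export
setClass("ThicknessResult",
  representation(medianMm = "numeric", nTotal = "integer", nKept = "integer",
                 z0 = "integer", band = "integer",
                 samples = "data.frame", perSlice = "data.frame"),
  validity = function(object) {
    if (length(object@band) != 2L) return("'band' must be length 2")
    if (object@nKept > object@nTotal)
      return("kept samples cannot exceed total samples")
    NULL
  })

#' AgreementResult: a chance-corrected agreement statistic with CI
#'
#' @slot statistic Name of the statistic (e.g. \code{"Gwet AC1"}).
#' @slot value Point estimate.
#' @slot ciLower,ciUpper 95\% (or requested level) confidence bounds.
#' @slot n Number of pairwise-complete subjects used.
#' @slot details Named list of intermediate quantities (pa, pe, variance).
#' @export
setClass("AgreementResult",
  representation(statistic = "character", value = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 n = "integer", details = "list"),
  validity = function(object) {
    if (!is.na(object@value) && object@value > 1 + 1e-12)
      return("agreement value cannot exceed 1")
    if (!anyNA(c(object@ciLower, object@ciUpper, object@value)) &&
        (object@ciLower > object@value + 1e-12 ||
         object@ciUpper < object@value - 1e-12))
      return("CI must contain the point estimate")
    NULL
  })

#' PhantomSpec: parameters of a digital head phantom
#'
#' Nested ellipsoidal tissue compartments (brain, skull shell, subcutaneous
#' fat shell, two lateral muscle patches, an anterior face protrusion) with
#' known analytic volumes and skull wall thickness, plus per-class CT
#' attenuation (HU) and T1-like intensity parameters. The seed fully
#' determines the generated volumes.
#'
#' @slot shape Integer(3) grid dimensions (voxels).
#' @slot spacing Numeric(3) spacing in mm.
#' @slot center Numeric(3) head centre in 1-based voxel coordinates.
#' @slot brainSemiAxes Numeric(3) brain ellipsoid semi-axes in mm.
#' @slot wallMm Skull wall thickness in mm (added to each brain semi-axis).
#' @slot fatMm Subcutaneous fat layer thickness in mm.
#' @slot muscleSemiAxes Numeric(3) semi-axes of each lateral muscle patch (mm).
#' @slot faceMm Anterior extent of the face protrusion (mm); 0 disables it.
#' @slot hu Named numeric CT attenuation per class (plus \code{cancellous}).
#' @slot cancellousFrac Fraction of the wall (innermost) given cancellous
#'   attenuation; 0 for a single-density skull.
#' @slot t1Mean,t1Sd Named numeric T1-like intensity mean / noise SD per class.
#' @slot noiseSdHu Gaussian noise SD added to the CT volume (0 = off).
#' @slot seed Integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", center = "numeric",
                 brainSemiAxes = "numeric", wallMm = "numeric",
                 fatMm = "numeric", muscleSemiAxes = "numeric",
                 faceMm = "numeric", hu = "numeric",
                 cancellousFrac = "numeric", t1Mean = "numeric",
                 t1Sd = "numeric", noiseSdHu = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 8))
      return("'shape' must be three dimensions of at least 8 voxels")
    msg <- .checkSpacing(object@spacing)
    if (!is.null(msg)) return(msg)
    if (object@wallMm < 2 * max(object@spacing[1:2]))
      return("skull wall must be at least 2 voxels thick")
    if (object@cancellousFrac < 0 || object@cancellousFrac >= 1)
      return("'cancellousFrac' must be in [0, 1)")
    NULL
  })
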