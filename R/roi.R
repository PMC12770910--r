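#' Per-slice anterior extremes of a brain mask
#'
#' For every axial slice z, finds the most anterior voxel index at which
#' brain tissue is present: T(z) = max\{x : brain(x, y, z) = 1 for some y\},
#' reported 0-based. Slices containing no brain tissue carry T(z) = 0.
#'
#' @param brain A \code{\linkS4class{BinaryMask}} of the brain in canonical
#'   orientation.
#' @return A \code{\linkS4class{CutBoundary}} with the \code{top} component
#'   filled; a warning is issued (and an all-zero boundary returned) when the
#'   mask is empty.
#' @export
topPoints <- function(brain) {
  stopifnot(is(brain, "BinaryMask"))
  d <- dim(brain@data)
  # collapse the lateral axis: anyY[x, z] is 1 if any y has brain tissue
  anyY <- apply(brain@data != 0, c(1, 3), any)
  top <- integer(d[3])
  for (z in seq_len(d[3])) {
    w <- which(anyY[, z])
    top[z] <- if (length(w)) max(w) - 1L else 0L
  }
  if (all(top == 0L) && !any(brain@data != 0))
    warning("brain mask is empty; returning an all-zero cut boundary")
  new("CutBoundary", top = top)
}

#' Propagate the anterior boundary inferior to superior
#'
#' Fills the adjusted boundary T*(z) = max(T(z), T*(z-1)) with T*(-1) = 0,
#' i.e. a running maximum from the most inferior slice upward, so the cutting
#' plane can never move posteriorly in more superior slices.
#'
#' @param boundary A \code{\linkS4class{CutBoundary}} with \code{top} filled.
#' @return The same object with \code{adjusted} completed.
#' @export
propagateBoundary <- function(boundary) {
  stopifnot(is(boundary, "CutBoundary"))
  new("CutBoundary", top = boundary@top,
      adjusted = as.integer(cummax(pmax(boundary@top, 0L))))
}

.cropArray <- function(arr, adjusted) {
  d <- dim(arr)
  if (length(adjusted) != d[3])
    stop("boundary has ", length(adjusted), " slices but the volume has ", d[3])
  # keep voxels with 0-based x <= adjusted[z]; zero the rest
  keepXZ <- outer(seq_len(d[1]) - 1L, adjusted, "<=")   # X x Z
  keep <- aperm(array(keepXZ, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  arr * keep
}

.requireAdjusted <- function(boundary) {
  if (!length(boundary@adjusted))
    stop("boundary has no propagated component; call propagateBoundary() first")
  boundary@adjusted
}

#' @rdname cropToBoundary
#' @export
setMethod("cropToBoundary", "BinaryMask", function(x, boundary) {
  adj <- .requireAdjusted(boundary)
  new("BinaryMask", data = .cropArray(x@data, adj), spacing = x@spacing)
})

#' @rdname cropToBoundary
#' @export
setMethod("cropToBoundary", "LabelMask", function(x, boundary) {
  adj <- .requireAdjusted(boundary)
  out <- .cropArray(x@data, adj)
  new("LabelMask", data = array(as.integer(out), dim = dim(out)),
      labelMap = x@labelMap, spacing = x@spacing,
      sourceOrientation = x@sourceOrientation)
})

#' @rdname cropToBoundary
#' @export
setMethod("cropToBoundary", "HeadVolume", function(x, boundary) {
  adj <- .requireAdjusted(boundary)
  new("HeadVolume", data = .cropArray(x@data, adj), spacing = x@spacing,
      sourceOrientation = x@sourceOrientation)
})

#' Standardize the measurement ROI with a brain-mask-guided anterior cut
#'
#' Composes \code{\link{topPoints}}, \code{\link{propagateBoundary}} and
#' \code{\link{cropToBoundary}}: everything anterior to the propagated
#' per-slice brain boundary is removed from the label mask (and, optionally,
#' the intensity volume), yielding a measurement region that is identical
#' across defacing variants that only remove tissue anterior to that
#' boundary. Brain voxels are never removed.
#'
#' @param labels A \code{\linkS4class{LabelMask}}.
#' @param brain A \code{\linkS4class{BinaryMask}} of the brain, same grid.
#' @param vol Optional \code{\linkS4class{HeadVolume}} to crop alongside.
#' @param onlyBrainSlices If \code{TRUE}, additionally zero out axial slices
#'   that contain no brain voxels (useful to exclude the neck region, where
#'   the propagated boundary is degenerate).
#' @return A list with elements \code{labels}, \code{volume} (or \code{NULL})
#'   and \code{boundary} (the completed \code{\linkS4class{CutBoundary}}).
#' @export
standardizeROI <- function(labels, brain, vol = NULL, onlyBrainSlices = FALSE) {
  stopifnot(is(labels, "LabelMask"), is(brain, "BinaryMask"))
  .sameGeometry(labels, brain, "labels and brain mask")
  cb <- propagateBoundary(topPoints(brain))
  outLabels <- cropToBoundary(labels, cb)
  outVol <- NULL
  if (!is.null(vol)) {
    .sameGeometry(labels, vol, "labels and volume")
    outVol <- cropToBoundary(vol, cb)
  }
  if (onlyBrainSlices) {
    empty <- !apply(brain@data != 0, 3, any)
    if (any(empty)) {
      outLabels@data[, , empty] <- 0L
      if (!is.null(outVol)) outVol@data[, , empty] <- 0
    }
  }
  list(labels = outLabels, volume = outVol, boundary = cb)
}

#' Export a cut boundary for audit
#'
#' @param boundary A \code{\linkS4class{CutBoundary}}.
#' @return A data.frame with 0-based columns \code{z}, \code{top},
#'   \code{adjusted} (the latter \code{NA} when not yet propagated).
#' @export
boundaryTable <- function(boundary) {
  stopifnot(is(boundary, "CutBoundary"))
  data.frame(z = seq_along(boundary@top) - 1L,
             top = boundary@top,
             adjusted = if (length(boundary@adjusted)) boundary@adjusted
                        else NA_integer_)
}

#' Write the boundary audit CSV
#'
#' @param boundary A \code{\linkS4class{CutBoundary}}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeBoundary <- function(boundary, path) {
  utils::write.csv(boundaryTable(boundary), path, row.names = FALSE)
  invisible(path)
}
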