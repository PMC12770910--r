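#' @importFrom RNifti readNifti writeNifti asNifti pixdim orientation
#'   `orientation<-` `qform<-` `pixdim<-`
NULL

# Canonical axis convention: first axis posterior->anterior, second
# right->left, third inferior->superior ("ALS" in RNifti's nomenclature).
.CANONICAL <- "ALS"

.canonicalXform <- function(spacing) {
  # voxel axis 1 -> +y (anterior), axis 2 -> -x (left), axis 3 -> +z (superior)
  m <- matrix(0, 4, 4)
  m[2, 1] <- spacing[1]
  m[1, 2] <- -spacing[2]
  m[3, 3] <- spacing[3]
  m[4, 4] <- 1
  structure(m, code = 2L)
}

.readCanonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3-D volume, got ", nd, "-D: ", path)
  src <- tryCatch(orientation(img), error = function(e) NA_character_)
  if (!is.na(src) && src != .CANONICAL) orientation(img) <- .CANONICAL
  if (is.na(src))
    warning("no qform/sform in '", path, "'; assuming canonical orientation")
  sp <- pixdim(img)[1:3]
  list(data = as.array(img)[, , , drop = TRUE], spacing = sp, source = src)
}

#' Read a head volume from NIfTI
#'
#' Reads a 3-D scalar volume (\code{.nii} or \code{.nii.gz}), reorients it to
#' the package's canonical frame (anterior / left / superior increasing along
#' the three array axes) and records the file's original orientation so
#' \code{\link{writeHeadVolume}} can restore it.
#'
#' @param path Path to a readable NIfTI file.
#' @return A \code{\linkS4class{HeadVolume}}.
#' @export
readHeadVolume <- function(path) {
  r <- .readCanonical(path)
  new("HeadVolume", data = r$data, spacing = r$spacing,
      sourceOrientation = r$source)
}

#' Read a tissue label mask from NIfTI
#'
#' @param path Path to a NIfTI file with integer voxel values.
#' @param labelMap Named integer vector mapping class names to codes; every
#'   value observed in the file must appear in it.
#' @return A \code{\linkS4class{LabelMask}} in canonical orientation.
#' @export
readLabelMask <- function(path, labelMap = defaultLabelMap()) {
  r <- .readCanonical(path)
  v <- r$data
  if (max(abs(v - round(v))) > 1e-6)
    stop("label volume contains non-integer voxel values: ", path)
  v <- array(as.integer(round(v)), dim = dim(v))
  bad <- setdiff(unique(as.vector(v)), labelMap)
  if (length(bad))
    stop("unexpected label value(s) not in label map: ",
         paste(sort(bad), collapse = ", "))
  new("LabelMask", data = v, labelMap = labelMap, spacing = r$spacing,
      sourceOrientation = r$source)
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a NIfTI file with values 0/1 (a tolerance of 1e-6 is
#'   applied for float-stored masks).
#' @return A \code{\linkS4class{BinaryMask}}.
#' @export
readBinaryMask <- function(path) {
  r <- .readCanonical(path)
  v <- round(r$data)
  if (!all(v %in% c(0, 1)) || max(abs(r$data - v)) > 1e-6)
    stop("not a binary mask (values outside {0,1}): ", path)
  new("BinaryMask", data = array(v, dim = dim(v)), spacing = r$spacing)
}

.writeCanonical <- function(data, spacing, path, sourceOrientation = NA_character_,
                            datatype = "auto") {
  img <- asNifti(data)
  pixdim(img) <- spacing
  qform(img) <- .canonicalXform(spacing)
  if (!is.na(sourceOrientation) && sourceOrientation != .CANONICAL)
    orientation(img) <- sourceOrientation
  writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a head volume to NIfTI
#'
#' @param vol A \code{\linkS4class{HeadVolume}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param restoreOrientation If \code{TRUE} (default) and the volume was read
#'   from a file, write in the source file's axis order so a read/write round
#'   trip reproduces the original voxel layout.
#' @return The path, invisibly.
#' @export
writeHeadVolume <- function(vol, path, restoreOrientation = TRUE) {
  src <- if (restoreOrientation) vol@sourceOrientation else NA_character_
  .writeCanonical(vol@data, vol@spacing, path, src)
}

#' Write a label mask to NIfTI
#'
#' @param labels A \code{\linkS4class{LabelMask}}.
#' @param path Output path.
#' @param restoreOrientation As in \code{\link{writeHeadVolume}}.
#' @return The path, invisibly.
#' @export
writeLabelMask <- function(labels, path, restoreOrientation = TRUE) {
  src <- if (restoreOrientation) labels@sourceOrientation else NA_character_
  .writeCanonical(labels@data, labels@spacing, path, src, datatype = "int16")
}

#' Write a binary mask to NIfTI
#'
#' @param mask A \code{\linkS4class{BinaryMask}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBinaryMask <- function(mask, path) {
  .writeCanonical(mask@data, mask@spacing, path, datatype = "uint8")
}

#' @rdname binarize
#' @export
setMethod("binarize", "LabelMask", function(labels, cls) {
  if (!cls %in% names(labels@labelMap))
    stop("unknown class name '", cls, "'; expected one of: ",
         paste(names(labels@labelMap), collapse = ", "))
  code <- labels@labelMap[[cls]]
  new("BinaryMask", data = (labels@data == code) + 0L,
      spacing = labels@spacing)
})

.sameGeometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(what, " differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  if (max(abs(voxelSpacing(a) - voxelSpacing(b))) > 1e-6)
    stop(what, " differ in voxel spacing")
  invisible(TRUE)
}
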