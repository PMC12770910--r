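#' @importFrom stats quantile median rnorm qnorm sd
#' @importFrom utils head tail
NULL

.largestComponent <- function(maskArr) {
  lab <- .labelComponents3d(as.logical(maskArr), dim(maskArr))
  if (max(lab) == 0L) return(array(0L, dim = dim(maskArr)))
  keep <- which.max(tabulate(lab[lab > 0L]))
  array(as.integer(lab == keep), dim = dim(maskArr))
}

#' CT skull mask by Hounsfield-unit thresholding
#'
#' Segments cranial bone from a co-registered CT volume as voxels strictly
#' above an attenuation threshold (default 471 HU), keeping the largest
#' 6-connected component. Higher thresholds emphasize dense cortical bone;
#' lower ones include cancellous bone.
#'
#' @param ct A \code{\linkS4class{HeadVolume}} with voxel values in HU.
#' @param huThreshold Attenuation threshold in HU; default 471.
#' @return A \code{\linkS4class{BinaryMask}}. When no voxel exceeds the
#'   threshold an empty mask is returned with a warning (no valid
#'   segmentation at that threshold).
#' @export
ctSkullMask <- function(ct, huThreshold = 471) {
  stopifnot(is(ct, "HeadVolume"))
  if (huThreshold < -1000)
    stop("'huThreshold' below -1000 HU (air) is not a valid bone threshold")
  raw <- ct@data > huThreshold
  if (!any(raw)) {
    warning("no voxels above ", huThreshold,
            " HU; returning an empty skull mask (no valid segmentation contour)")
    return(new("BinaryMask", data = array(0L, dim = dim(ct@data)),
               spacing = ct@spacing))
  }
  new("BinaryMask", data = .largestComponent(raw), spacing = ct@spacing)
}

#' Select the axial measurement band for thickness estimation
#'
#' The band starts a fixed physical offset (default 10 mm) superior to the
#' orbital-roof reference slice and covers a fixed physical extent (default
#' 16 x 1 mm); with non-unit z spacing the slice count is
#' \code{round(bandMm / spacingZ)}.
#'
#' @param z0 0-based reference slice index (top orbital roof).
#' @param spacingZ Slice spacing in mm.
#' @param offsetMm Offset superior to \code{z0}, in mm; default 10.
#' @param nSlices Number of 1-mm slices the band represents; default 16
#'   (i.e. a 16-mm physical extent).
#' @param dimZ Number of slices in the volume (for the extent check).
#' @return A list with 0-based half-open \code{start}, \code{end} and the
#'   vector \code{z} of 0-based slice indices.
#' @export
selectSlices <- function(z0, spacingZ, offsetMm = 10, nSlices = 16, dimZ) {
  start <- z0 + round(offsetMm / spacingZ)
  count <- round(nSlices * 1.0 / spacingZ)
  if (start < 0 || start + count > dimZ) {
    fit <- max(0, dimZ - start)
    stop("measurement band [", start, ", ", start + count,
         ") exceeds the volume extent (", dimZ, " slices); only ", fit,
         " slice(s) fit above the offset")
  }
  list(start = as.integer(start), end = as.integer(start + count),
       z = as.integer(start + seq_len(count) - 1L))
}

.largestComponent2d <- function(sliceMat) {
  lab <- EBImage::bwlabel(sliceMat != 0)
  if (max(lab) == 0L) return(NULL)
  counts <- tabulate(lab[lab > 0L])
  (lab == which.max(counts)) + 0
}

#' Outer and inner contours of a skull cross-section
#'
#' Extracts the boundary of the largest connected component of a 2-D binary
#' skull slice (outer contour) and the boundary of its largest enclosed
#' cavity (inner contour), as ordered vertex sequences in 1-based voxel
#' coordinates. A slice without an enclosed cavity (a solid blob rather than
#' a ring) is flagged degenerate.
#'
#' @param sliceMat 2-D binary matrix (a single axial slice).
#' @return A list with \code{degenerate} (logical) and, when not degenerate,
#'   \code{outer} and \code{inner} (k x 2 ordered vertex matrices),
#'   \code{component} and \code{cavity} (2-D 0/1 matrices).
#' @export
sliceBoundaries <- function(sliceMat) {
  comp <- .largestComponent2d(sliceMat)
  if (is.null(comp)) return(list(degenerate = TRUE, reason = "empty slice"))
  filled <- EBImage::fillHull(comp)
  cavityAll <- (filled != 0) & (comp == 0)
  if (!any(cavityAll))
    return(list(degenerate = TRUE, reason = "no enclosed cavity"))
  cavity <- .largestComponent2d(cavityAll + 0)
  oc <- EBImage::ocontour(comp)
  ic <- EBImage::ocontour(cavity)
  # ocontour coordinates are 0-based; convert to 1-based voxel indices
  list(degenerate = FALSE,
       outer = oc[[1]] + 1, inner = ic[[1]] + 1,
       component = comp, cavity = cavity)
}

#' Sample points uniformly by arc length along a closed contour
#'
#' Resamples a closed polygonal contour into \code{n} points with equal
#' arc-length spacing, starting at the most anterior vertex (largest first
#' coordinate; ties broken by the smallest lateral coordinate).
#'
#' @param contour k x 2 matrix of ordered contour vertices.
#' @param n Number of sample points; default 100.
#' @return A list with \code{points} (n x 2 coordinates) and
#'   \code{vertexIndex} (nearest original vertex for each sample, used for
#'   tangent estimation).
#' @export
sampleContourPoints <- function(contour, n = 100) {
  m <- nrow(contour)
  if (is.null(m) || m < 4) stop("contour too short to sample")
  start <- which(contour[, 1] == max(contour[, 1]))
  start <- start[which.min(contour[start, 2])]
  idx <- c(start:m, seq_len(start - 1L))
  pts <- contour[idx, , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(m + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  if (total <= 0) stop("degenerate contour with zero length")
  s <- total * (seq_len(n) - 1) / n
  edge <- findInterval(s, cum, rightmost.closed = TRUE)
  edge[edge > m] <- m
  frac <- (s - cum[edge]) / pmax(seg[edge], .Machine$double.eps)
  p <- closed[edge, , drop = FALSE] +
       frac * (closed[edge + 1, , drop = FALSE] - closed[edge, , drop = FALSE])
  nearest <- ifelse(frac < 0.5, edge, edge %% m + 1L)
  list(points = p, vertexIndex = idx[nearest])
}

.contourTangent <- function(contour, i, k = 2L) {
  m <- nrow(contour)
  a <- ((i - 1L - k) %% m) + 1L
  b <- ((i - 1L + k) %% m) + 1L
  t <- contour[b, ] - contour[a, ]
  nrm <- sqrt(sum(t^2))
  if (nrm == 0) return(c(NA_real_, NA_real_))
  t / nrm
}

#' Tangent-normal thickness at one outer-contour point
#'
#' Estimates the local tangent from contour neighbours (central difference
#' over +/- \code{k} vertices), then marches a ray along the inward normal in
#' sub-voxel steps through the binary cross-section. Thickness is the
#' distance (mm) from entering the bone to first exiting into the enclosed
#' cavity. The sample is missing (NA) when the ray leaves the slice, exceeds
#' the maximum length, or exits into anything other than the central cavity
#' (e.g. a sinus-like pocket spanning the wall).
#'
#' @param point Numeric(2), sample position on the outer contour (1-based
#'   voxel coordinates).
#' @param vertexIndex Index of the nearest outer-contour vertex.
#' @param boundaries Output of \code{\link{sliceBoundaries}} for the slice.
#' @param spacingInPlane In-plane voxel spacing in mm (isotropic).
#' @param stepVox Ray-marching step in voxels; default 0.25.
#' @param maxLenMm Maximum ray length in mm; default 50.
#' @param k Tangent half-window in contour vertices; default 2.
#' @return Thickness in mm, or \code{NA_real_} for a missing sample.
#' @export
tangentThickness <- function(point, vertexIndex, boundaries, spacingInPlane,
                             stepVox = 0.25, maxLenMm = 50, k = 2L) {
  if (isTRUE(boundaries$degenerate)) return(NA_real_)
  tg <- .contourTangent(boundaries$outer, vertexIndex, k)
  if (anyNA(tg)) return(NA_real_)
  nrml <- c(-tg[2], tg[1])
  comp <- boundaries$component
  cav <- boundaries$cavity
  centroid <- c(mean(boundaries$inner[, 1]), mean(boundaries$inner[, 2]))
  if (sum((centroid - point) * nrml) < 0) nrml <- -nrml
  d <- dim(comp)
  maxLenVox <- maxLenMm / spacingInPlane
  # start slightly outside the mask so the entry crossing is detected at the
  # pixelated outer surface rather than at the contour pixel centre
  tvals <- seq(-2, maxLenVox, by = stepVox)
  px <- round(point[1] + tvals * nrml[1])
  py <- round(point[2] + tvals * nrml[2])
  inb <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
  inside <- logical(length(tvals))
  inside[inb] <- comp[cbind(px[inb], py[inb])] != 0
  entry <- which(inside)[1]
  # the sampled point sits on the outer boundary: entry must be immediate
  if (is.na(entry) || tvals[entry] > 2) return(NA_real_)
  after <- which(!inside & seq_along(inside) > entry)
  exitIdx <- after[1]
  if (is.na(exitIdx)) return(NA_real_)
  if (!inb[exitIdx]) return(NA_real_)
  if (cav[px[exitIdx], py[exitIdx]] == 0) return(NA_real_)
  (tvals[exitIdx] - tvals[entry]) * spacingInPlane
}

.checkThicknessSpacing <- function(spacing) {
  sxy <- spacing[1:2]
  if (any(sxy < 0.9) || any(sxy > 1.1))
    stop("thickness estimation requires ~1 mm in-plane spacing ",
         "(got ", paste(signif(sxy, 3), collapse = " x "),
         " mm); resample the mask first")
  if (abs(sxy[1] - sxy[2]) > 0.01 * mean(sxy))
    stop("thickness estimation requires isotropic in-plane spacing")
  mean(sxy)
}

#' Median skull thickness over an axial measurement band
#'
#' Measures tangent-normal thickness at \code{nPoints} arc-length-uniform
#' positions on the outer skull contour of every slice in a band starting
#' \code{offsetMm} superior to the reference slice, pools the valid samples,
#' discards values outside the central 95\% (2.5th-97.5th percentiles, linear
#' interpolation), and reports the median of the kept values.
#'
#' @param skull A \code{\linkS4class{BinaryMask}} of the skull (canonical
#'   orientation, ~1 mm in-plane spacing).
#' @param z0 0-based orbital-roof reference slice index.
#' @param nPoints Tangent samples per slice; default 100.
#' @param nSlices Band extent in 1-mm slices; default 16.
#' @param offsetMm Band offset superior to \code{z0}; default 10.
#' @param trim Central fraction of pooled samples kept; default 0.95.
#' @param minValid Minimum number of valid samples required; default 160.
#' @param perSliceTrim If \code{TRUE}, trim within each slice before pooling
#'   instead of trimming the pooled sample set.
#' @return A \code{\linkS4class{ThicknessResult}}.
#' @export
medianSkullThickness <- function(skull, z0, nPoints = 100, nSlices = 16,
                                 offsetMm = 10, trim = 0.95, minValid = 160,
                                 perSliceTrim = FALSE) {
  stopifnot(is(skull, "BinaryMask"))
  sp <- .checkThicknessSpacing(skull@spacing)
  band <- selectSlices(z0, skull@spacing[3], offsetMm, nSlices,
                       dimZ = dim(skull@data)[3])
  rows <- vector("list", length(band$z))
  perSlice <- data.frame(slice = band$z, n_points = 0L, n_valid = 0L,
                         degenerate = FALSE)
  for (i in seq_along(band$z)) {
    z <- band$z[i] + 1L
    bnd <- sliceBoundaries(skull@data[, , z])
    if (isTRUE(bnd$degenerate)) {
      perSlice$degenerate[i] <- TRUE
      next
    }
    smp <- sampleContourPoints(bnd$outer, nPoints)
    th <- vapply(seq_len(nPoints), function(j)
      tangentThickness(smp$points[j, ], smp$vertexIndex[j], bnd, sp),
      numeric(1))
    perSlice$n_points[i] <- nPoints
    perSlice$n_valid[i] <- sum(!is.na(th))
    rows[[i]] <- data.frame(slice = band$z[i],
                            x = smp$points[, 1], y = smp$points[, 2],
                            thickness_mm = th)
  }
  samples <- do.call(rbind, rows)
  if (is.null(samples)) samples <- data.frame(slice = integer(0),
                                              x = numeric(0), y = numeric(0),
                                              thickness_mm = numeric(0))
  valid <- samples$thickness_mm[!is.na(samples$thickness_mm)]
  if (length(valid) < minValid)
    stop("insufficient valid thickness samples (", length(valid), " < ",
         minValid, "); check the skull mask and reference slice")
  alpha <- (1 - trim) / 2
  if (perSliceTrim) {
    keptFlag <- rep(FALSE, nrow(samples))
    for (z in unique(samples$slice)) {
      sel <- samples$slice == z & !is.na(samples$thickness_mm)
      if (!any(sel)) next
      v <- samples$thickness_mm[sel]
      qs <- quantile(v, c(alpha, 1 - alpha), type = 7, names = FALSE)
      keptFlag[sel] <- v >= qs[1] & v <= qs[2]
    }
  } else {
    qs <- quantile(valid, c(alpha, 1 - alpha), type = 7, names = FALSE)
    keptFlag <- !is.na(samples$thickness_mm) &
      samples$thickness_mm >= qs[1] & samples$thickness_mm <= qs[2]
  }
  samples$kept <- keptFlag
  new("ThicknessResult",
      medianMm = median(samples$thickness_mm[keptFlag]),
      nTotal = length(valid), nKept = sum(keptFlag),
      z0 = as.integer(z0), band = c(band$start, band$end),
      samples = samples, perSlice = perSlice)
}

#' Crude orbital-roof fallback heuristic
#'
#' Returns the most inferior slice whose skull cross-section is a closed
#' ring spanning both lateral halves of the skull's extent. This is a rough
#' geometric stand-in for an anatomically detected orbital-roof landmark and
#' is intended for phantoms and quick looks only; supply a true reference
#' slice whenever one is available.
#'
#' @param skull A \code{\linkS4class{BinaryMask}}.
#' @return 0-based slice index, or an error when no slice qualifies.
#' @export
autoReferenceSlice <- function(skull) {
  stopifnot(is(skull, "BinaryMask"))
  d <- dim(skull@data)
  anyXZ <- apply(skull@data != 0, c(2, 3), any)    # lateral x slice occupancy
  yOcc <- which(apply(anyXZ, 1, any))
  if (!length(yOcc)) stop("empty skull mask")
  yMid <- mean(range(yOcc))
  for (z in seq_len(d[3])) {
    slice <- skull@data[, , z]
    if (sum(slice) < 20) next
    bnd <- sliceBoundaries(slice)
    if (isTRUE(bnd$degenerate)) next
    ys <- which(apply(bnd$component != 0, 2, any))
    if (min(ys) < yMid && max(ys) > yMid) return(z - 1L)
  }
  stop("no slice with a closed, laterally spanning skull ring found")
}

#' Compare thickness estimates across tools against a reference
#'
#' Given per-subject median thickness from several tools, reports each tool's
#' mean (SD) across subjects and the mean absolute difference from the
#' reference tool on subjects measured by both.
#'
#' @param measurements data.frame with columns \code{tool}, \code{subject},
#'   \code{thickness_mm}.
#' @param referenceTool Name of the reference tool (e.g. the CT-derived one).
#' @return A data.frame with columns \code{tool}, \code{n},
#'   \code{mean_thickness_mm}, \code{sd_thickness_mm},
#'   \code{mean_abs_diff_mm} (NA for the reference row).
#' @export
compareThickness <- function(measurements, referenceTool) {
  stopifnot(all(c("tool", "subject", "thickness_mm") %in% names(measurements)))
  tools <- unique(measurements$tool)
  if (length(tools) < 2) stop("need at least two tools to compare")
  if (!referenceTool %in% tools)
    stop("reference tool '", referenceTool, "' not present")
  ref <- measurements[measurements$tool == referenceTool, ]
  out <- lapply(tools, function(tl) {
    m <- measurements[measurements$tool == tl, ]
    common <- intersect(m$subject, ref$subject)
    absdiff <- if (tl == referenceTool) NA_real_ else
      mean(abs(m$thickness_mm[match(common, m$subject)] -
               ref$thickness_mm[match(common, ref$subject)]))
    data.frame(tool = tl, n = nrow(m),
               mean_thickness_mm = mean(m$thickness_mm),
               sd_thickness_mm = if (nrow(m) > 1) sd(m$thickness_mm) else NA_real_,
               mean_abs_diff_mm = absdiff)
  })
  do.call(rbind, out)
}
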