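#' Build a digital head phantom specification
#'
#' Phantoms are nested ellipsoidal compartments on a regular grid: a brain
#' ellipsoid, a skull shell of constant nominal wall thickness (each outer
#' semi-axis = brain semi-axis + wall), a subcutaneous fat shell, two lateral
#' ellipsoidal muscle patches just clear of the fat surface (temporalis-like,
#' and analytically exact in volume), and an anterior half-ellipsoid "face"
#' protrusion that gives defacing and anterior cropping something to remove.
#' The head centre sits posterior of the grid centre so the face fits.
#' Phantoms are geometric, not anatomically realistic: their purpose is
#' analytic recoverability of volumes and wall thickness.
#'
#' @param preset \code{"ellipsoid"} (default; brain semi-axes 55 x 50 x 50
#'   mm), \code{"sphere"} (50 mm radius) or \code{"two-density"} (sphere with
#'   the inner half of the skull wall at cancellous attenuation).
#' @param shape Grid dimensions; default 160^3 voxels.
#' @param spacing Voxel spacing in mm; default 1 mm isotropic.
#' @param brainSemiAxes Override the preset's brain semi-axes (mm).
#' @param wallMm Skull wall thickness (mm); default 5.
#' @param fatMm Fat layer thickness (mm); default 4.
#' @param muscleSemiAxes Semi-axes of each muscle patch (mm); default
#'   22 x 8 x 25.
#' @param faceMm Anterior extent of the face protrusion (mm); default 18;
#'   0 disables it.
#' @param hu Named CT attenuation per class; defaults: air -1000, brain 40,
#'   skull (cortical bone) 1000, subcutaneous fat -100, muscle 50,
#'   cancellous bone 450.
#' @param cancellousFrac Inner fraction of the wall given cancellous
#'   attenuation (CT only); the \code{"two-density"} preset sets 0.5.
#' @param t1Mean Named T1-like intensity means per class on a [0, 1] scale
#'   (bone dark, fat bright).
#' @param t1Sd Named per-class Gaussian noise SD for the T1 volume
#'   (default 0 = noiseless, for exact tests).
#' @param noiseSdHu Gaussian noise SD for the CT volume (default 0).
#' @param seed RNG seed; with noise enabled it fully determines the output.
#' @return A \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(preset = c("ellipsoid", "sphere", "two-density"),
                        shape = c(160L, 160L, 160L),
                        spacing = c(1, 1, 1),
                        brainSemiAxes = NULL,
                        wallMm = 5, fatMm = 4,
                        muscleSemiAxes = c(22, 8, 25),
                        faceMm = 18,
                        hu = c(background = -1000, brain = 40, skull = 1000,
                               subcutaneous_fat = -100, muscle = 50,
                               cancellous = 450),
                        cancellousFrac = NULL,
                        t1Mean = c(background = 0.02, brain = 0.55,
                                   skull = 0.15, subcutaneous_fat = 0.95,
                                   muscle = 0.45),
                        t1Sd = c(background = 0, brain = 0, skull = 0,
                                 subcutaneous_fat = 0, muscle = 0),
                        noiseSdHu = 0, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(brainSemiAxes))
    brainSemiAxes <- switch(preset,
                            ellipsoid = c(55, 50, 50),
                            sphere = c(50, 50, 50),
                            `two-density` = c(50, 50, 50))
  if (is.null(cancellousFrac))
    cancellousFrac <- if (preset == "two-density") 0.5 else 0
  shape <- as.integer(shape)
  # head centre shifted posteriorly so the face protrusion fits the grid
  outerX <- brainSemiAxes[1] + wallMm + fatMm
  center <- c((shape[1] + 1) / 2 - (faceMm + 2) / (2 * spacing[1]),
              (shape[2] + 1) / 2, (shape[3] + 1) / 2)
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      center = center, brainSemiAxes = as.numeric(brainSemiAxes),
      wallMm = as.numeric(wallMm), fatMm = as.numeric(fatMm),
      muscleSemiAxes = as.numeric(muscleSemiAxes),
      faceMm = as.numeric(faceMm), hu = hu,
      cancellousFrac = as.numeric(cancellousFrac),
      t1Mean = t1Mean, t1Sd = t1Sd, noiseSdHu = as.numeric(noiseSdHu),
      seed = as.integer(seed))
}

.ellCm3 <- function(semi) 4 / 3 * pi * prod(semi) / 1000

# squared normalized radius of an ellipsoid, built separably
.rho2 <- function(xmm, ymm, zmm, center, semi) {
  x2 <- ((xmm - center[1]) / semi[1])^2
  y2 <- ((ymm - center[2]) / semi[2])^2
  z2 <- ((zmm - center[3]) / semi[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a digital head phantom
#'
#' Voxelizes the compartments of a \code{\linkS4class{PhantomSpec}} into a
#' five-class label mask and paired T1-like and CT-like intensity volumes,
#' and returns an analytic truth record. Identical specs (including seed)
#' produce bit-identical volumes.
#'
#' @param spec A \code{\linkS4class{PhantomSpec}}.
#' @return A list with \code{labels} (\code{\linkS4class{LabelMask}}),
#'   \code{t1} and \code{ct} (\code{\linkS4class{HeadVolume}}s) and
#'   \code{truth}: analytic per-compartment volumes in cm^3 (exact for
#'   brain, skull, muscle and face), voxel counts, the nominal wall
#'   thickness, and \code{z0} (a 0-based reference slice placing the default
#'   thickness band symmetrically about the head's equator).
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape; sp <- spec@spacing; ctr <- spec@center
  ctrMm <- ctr * sp
  xmm <- seq_len(d[1]) * sp[1]
  ymm <- seq_len(d[2]) * sp[2]
  zmm <- seq_len(d[3]) * sp[3]
  aB <- spec@brainSemiAxes
  aS <- aB + spec@wallMm
  aF <- aS + spec@fatMm

  if (ctrMm[1] - aF[1] < sp[1] || any(ctrMm[2:3] - aF[2:3] < sp[2:3]) ||
      any(ctrMm[2:3] + aF[2:3] > c(ymm[d[2]], zmm[d[3]])))
    stop("head compartments exceed the grid; enlarge 'shape' or shrink the axes")

  rhoB <- .rho2(xmm, ymm, zmm, ctrMm, aB)
  rhoS <- .rho2(xmm, ymm, zmm, ctrMm, aS)
  rhoF <- .rho2(xmm, ymm, zmm, ctrMm, aF)

  lab <- array(0L, dim = d)
  lab[rhoF <= 1] <- 3L

  faceCm3 <- 0
  if (spec@faceMm > 0) {
    faceSemi <- c(spec@faceMm, 12, 15)
    faceCtr <- c(ctrMm[1] + aF[1], ctrMm[2], ctrMm[3] - 10)
    if (faceCtr[1] + spec@faceMm > xmm[d[1]])
      stop("face protrusion exceeds the grid anteriorly")
    rhoFace <- .rho2(xmm, ymm, zmm, faceCtr, faceSemi)
    anterior <- outer(outer(xmm > faceCtr[1], rep(TRUE, d[2]), "&"),
                      rep(TRUE, d[3]), "&")
    lab[rhoFace <= 1 & anterior] <- 3L
    faceCm3 <- .ellCm3(faceSemi) / 2
  }

  mS <- spec@muscleSemiAxes
  gap <- max(sp[2])             # 1 voxel clearance keeps muscle volume exact
  myOff <- aF[2] + mS[2] + gap
  muscleCm3 <- 0
  for (side in c(-1, 1)) {
    mCtr <- c(ctrMm[1], ctrMm[2] + side * myOff, ctrMm[3])
    if (mCtr[2] - mS[2] < sp[2] || mCtr[2] + mS[2] > ymm[d[2]])
      stop("muscle patch exceeds the grid laterally")
    rhoM <- .rho2(xmm, ymm, zmm, mCtr, mS)
    lab[rhoM <= 1] <- 4L
    muscleCm3 <- muscleCm3 + .ellCm3(mS)
  }

  lab[rhoS <= 1] <- 2L
  lab[rhoB <= 1] <- 1L

  huLut <- spec@hu[c("background", "brain", "skull", "subcutaneous_fat",
                     "muscle")]
  ct <- array(huLut[lab + 1L], dim = d)
  if (spec@cancellousFrac > 0) {
    aMid <- aB + spec@wallMm * spec@cancellousFrac
    rhoMid <- .rho2(xmm, ymm, zmm, ctrMm, aMid)
    ct[lab == 2L & rhoMid <= 1] <- spec@hu[["cancellous"]]
  }
  t1Lut <- spec@t1Mean[c("background", "brain", "skull", "subcutaneous_fat",
                         "muscle")]
  t1 <- array(t1Lut[lab + 1L], dim = d)

  if (spec@noiseSdHu > 0 || any(spec@t1Sd > 0)) {
    .withSeed(spec@seed, {
      if (spec@noiseSdHu > 0)
        ct <- ct + array(rnorm(prod(d), 0, spec@noiseSdHu), dim = d)
      if (any(spec@t1Sd > 0)) {
        sdLut <- spec@t1Sd[c("background", "brain", "skull",
                             "subcutaneous_fat", "muscle")]
        t1 <- t1 + array(rnorm(prod(d), 0, 1), dim = d) *
              array(sdLut[lab + 1L], dim = d)
      }
    })
  }

  labels <- new("LabelMask", data = lab, labelMap = defaultLabelMap(),
                spacing = sp)
  counts <- vapply(0:4, function(k) sum(lab == k), integer(1))
  names(counts) <- names(defaultLabelMap())
  truth <- list(
    volumes_cm3 = c(brain = .ellCm3(aB),
                    skull = .ellCm3(aS) - .ellCm3(aB),
                    subcutaneous_fat = .ellCm3(aF) - .ellCm3(aS) + faceCm3,
                    muscle = muscleCm3,
                    face = faceCm3),
    voxels = counts,
    wall_mm = spec@wallMm,
    z0 = as.integer(round(ctr[3] - 1 - 18 / sp[3])),
    center = ctr)
  list(labels = labels,
       t1 = new("HeadVolume", data = t1, spacing = sp),
       ct = new("HeadVolume", data = ct, spacing = sp),
       truth = truth)
}

.tiltIndices <- function(d, sp, degrees) {
  th <- degrees * pi / 180
  cx <- (d[1] + 1) / 2; cz <- (d[3] + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), z = seq_len(d[3]))
  dx <- (g$x - cx) * sp[1]; dz <- (g$z - cz) * sp[3]
  list(sx = (cos(th) * dx + sin(th) * dz) / sp[1] + cx,
       sz = (-sin(th) * dx + cos(th) * dz) / sp[3] + cz)
}

.expandXZ <- function(mat, d) {
  # replicate an (X x Z) matrix across the lateral axis -> X x Y x Z array
  aperm(array(mat, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
}

.tiltNN <- function(arr, sp, degrees) {
  d <- dim(arr)
  m <- .tiltIndices(d, sp, degrees)
  rx <- round(m$sx); rz <- round(m$sz)
  ok <- rx >= 1 & rx <= d[1] & rz >= 1 & rz <= d[3]
  rx[!ok] <- 1L; rz[!ok] <- 1L
  base <- matrix(rx + (rz - 1) * d[1] * d[2], nrow = d[1])
  baseArr <- .expandXZ(base, d)
  okArr <- .expandXZ(matrix(ok, nrow = d[1]), d)
  yoff <- array(rep(rep((seq_len(d[2]) - 1L) * d[1], each = d[1]), d[3]),
                dim = d)
  out <- array(arr[baseArr + yoff], dim = d)
  out[!okArr] <- 0
  out
}

.tiltLinear <- function(arr, sp, degrees) {
  d <- dim(arr)
  m <- .tiltIndices(d, sp, degrees)
  x0 <- floor(m$sx); z0 <- floor(m$sz)
  fx <- m$sx - x0; fz <- m$sz - z0
  yoff <- array(rep(rep((seq_len(d[2]) - 1L) * d[1], each = d[1]), d[3]),
                dim = d)
  out <- array(0, dim = d)
  for (cxi in 0:1) for (czi in 0:1) {
    xi <- x0 + cxi; zi <- z0 + czi
    w <- (if (cxi) fx else 1 - fx) * (if (czi) fz else 1 - fz)
    ok <- xi >= 1 & xi <= d[1] & zi >= 1 & zi <= d[3]
    xi[!ok] <- 1L; zi[!ok] <- 1L
    w[!ok] <- 0
    base <- matrix(xi + (zi - 1) * d[1] * d[2], nrow = d[1])
    wm <- matrix(w, nrow = d[1])
    out <- out + .expandXZ(wm, d) * array(arr[.expandXZ(base, d) + yoff],
                                          dim = d)
  }
  out
}

.checkTilt <- function(degrees) {
  if (!is.finite(degrees) || abs(degrees) > 15)
    stop("tilt angle must be finite and within +/-15 degrees")
}

#' @rdname applyTilt
#' @export
setMethod("applyTilt", "HeadVolume", function(x, degrees) {
  .checkTilt(degrees)
  if (degrees == 0) return(x)
  new("HeadVolume", data = .tiltLinear(x@data, x@spacing, degrees),
      spacing = x@spacing, sourceOrientation = x@sourceOrientation)
})

#' @rdname applyTilt
#' @export
setMethod("applyTilt", "LabelMask", function(x, degrees) {
  .checkTilt(degrees)
  if (degrees == 0) return(x)
  out <- .tiltNN(x@data, x@spacing, degrees)
  new("LabelMask", data = array(as.integer(out), dim = dim(out)),
      labelMap = x@labelMap, spacing = x@spacing,
      sourceOrientation = x@sourceOrientation)
})

#' @rdname applyTilt
#' @export
setMethod("applyTilt", "BinaryMask", function(x, degrees) {
  .checkTilt(degrees)
  if (degrees == 0) return(x)
  out <- .tiltNN(x@data, x@spacing, degrees)
  new("BinaryMask", data = array(as.integer(out), dim = dim(out)),
      spacing = x@spacing)
})

#' Intensity augmentations for robustness testing
#'
#' Applies one of the standard robustness transforms voxelwise, after
#' min-max normalizing the volume to [0, 1] (disable renormalization with
#' \code{normalize = FALSE} when chaining transforms): gamma adjustment
#' (\code{"gamma_0.7"}, \code{"gamma_1.5"}, or any \code{"gamma_<g>"}),
#' brightness offsets (\code{"brightness_+0.2"}, \code{"brightness_-0.2"};
#' values are not clipped, so opposite offsets invert exactly), and
#' intensity rescaling to [0, 1.2] (\code{"scale_0_1.2"}).
#'
#' @param vol A \code{\linkS4class{HeadVolume}}.
#' @param kind Transform name (see above).
#' @param normalize Min-max normalize to [0, 1] first; default \code{TRUE}.
#' @return A transformed \code{\linkS4class{HeadVolume}}; labels paired with
#'   the volume are unaffected by intensity transforms.
#' @export
applyIntensityAugmentation <- function(vol, kind, normalize = TRUE) {
  stopifnot(is(vol, "HeadVolume"))
  v <- vol@data
  if (normalize) {
    r <- range(v)
    v <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else v * 0
  }
  out <-
    if (grepl("^gamma_", kind)) {
      g <- suppressWarnings(as.numeric(sub("^gamma_", "", kind)))
      if (!is.finite(g) || g <= 0) stop("unknown augmentation kind: ", kind)
      v^g
    } else if (grepl("^brightness_", kind)) {
      b <- suppressWarnings(as.numeric(sub("^brightness_", "", kind)))
      if (!is.finite(b)) stop("unknown augmentation kind: ", kind)
      v + b
    } else if (kind == "scale_0_1.2") {
      v * 1.2
    } else stop("unknown augmentation kind: ", kind)
  new("HeadVolume", data = out, spacing = vol@spacing,
      sourceOrientation = vol@sourceOrientation)
}

#' Simulate defacing of a head volume or mask
#'
#' Zeroes an anterior region that lies strictly anterior to the propagated
#' brain boundary of the intact volume (plus a safety margin), emulating the
#' variety of facial-anonymization algorithms applied to public MRI
#' datasets. Styles: \code{"plane"} removes everything anterior to a single
#' sagittal plane at the global boundary maximum; \code{"wedge"} follows the
#' per-slice propagated boundary on brain-bearing slices only;
#' \code{"aggressive"} follows the boundary on every slice, including
#' inferior slices without brain (where nearly the whole slice goes). With
#' \code{marginMm >= 0} no brain voxel is ever touched, and the standardized
#' ROI of the defaced output is voxel-identical to the intact one.
#'
#' @param x A \code{\linkS4class{HeadVolume}}, \code{\linkS4class{LabelMask}}
#'   or \code{\linkS4class{BinaryMask}} to deface.
#' @param brain \code{\linkS4class{BinaryMask}} of the brain on the same grid.
#' @param style One of \code{"plane"}, \code{"wedge"}, \code{"aggressive"}.
#' @param marginMm Extra anterior clearance in mm; must be >= 0 (a negative
#'   margin could cut brain tissue and is rejected).
#' @return A list with \code{defaced} (same class as \code{x}) and
#'   \code{removed} (a \code{\linkS4class{BinaryMask}} of the zeroed region).
#' @export
simulateDefacing <- function(x, brain,
                             style = c("plane", "wedge", "aggressive"),
                             marginMm = 0) {
  style <- match.arg(style)
  stopifnot(is(brain, "BinaryMask"))
  .sameGeometry(x, brain, "input and brain mask")
  if (marginMm < 0)
    stop("'marginMm' must be >= 0: a negative margin could cut brain tissue")
  cb <- propagateBoundary(suppressWarnings(topPoints(brain)))
  d <- dim(brain@data)
  mVox <- round(marginMm / brain@spacing[1])
  hasBrain <- apply(brain@data != 0, 3, any)
  cut <- switch(style,
    plane = rep(max(cb@adjusted) + mVox, d[3]),
    wedge = ifelse(hasBrain, cb@adjusted + mVox, d[1]),   # untouched slices
    aggressive = cb@adjusted + mVox)
  removedXZ <- outer(seq_len(d[1]) - 1L, cut, ">")
  removed <- .expandXZ(removedXZ + 0L, d)
  arr <- voxels(x)
  arr[removed == 1L] <- 0
  defaced <-
    if (is(x, "HeadVolume"))
      new("HeadVolume", data = arr, spacing = x@spacing,
          sourceOrientation = x@sourceOrientation)
    else if (is(x, "LabelMask"))
      new("LabelMask", data = array(as.integer(arr), dim = d),
          labelMap = x@labelMap, spacing = x@spacing,
          sourceOrientation = x@sourceOrientation)
    else new("BinaryMask", data = array(as.integer(arr), dim = d),
             spacing = x@spacing)
  list(defaced = defaced,
       removed = new("BinaryMask", data = removed, spacing = brain@spacing))
}
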