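#' Dice similarity coefficient
#'
#' Volumetric overlap 2|A n B| / (|A| + |B|) between two binary masks of the
#' same shape. Two empty masks are defined as perfect agreement on absence
#' (Dice 1) and flagged via \code{attr(., "bothEmpty")}, so per-class batch
#' reports do not propagate NaN for classes absent from both segmentations.
#'
#' @param a,b \code{\linkS4class{BinaryMask}} objects (or plain 0/1 arrays)
#'   of identical shape.
#' @return Numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "BinaryMask")) a@data else a
  bv <- if (is(b, "BinaryMask")) b@data else b
  if (!identical(dim(av), dim(bv))) stop("masks differ in shape")
  na <- sum(av != 0); nb <- sum(bv != 0)
  if (na + nb == 0) return(structure(1, bothEmpty = TRUE))
  2 * sum(av != 0 & bv != 0) / (na + nb)
}

.surfaceVoxels <- function(m) {
  # mask voxels with at least one 6-neighbour (or volume face) of background
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  f <- m != 0
  shift <- function(arr, ax, by) {
    out <- array(FALSE, dim = d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift(f, ax, by)
  f & !interior
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Robust Hausdorff variant: the 95th percentile of the pooled symmetric
#' surface-to-surface distance distribution between two masks, in mm.
#' Surfaces are mask voxels with a background face-neighbour (volume faces
#' count as background); distances are Euclidean and spacing-aware, computed
#' with an exact separable distance transform.
#'
#' @param a,b Non-empty \code{\linkS4class{BinaryMask}} objects with the same
#'   shape and spacing.
#' @param percentile Percentile of the pooled distances; default 0.95.
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, percentile = 0.95) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  .sameGeometry(a, b, "masks")
  if (!any(a@data != 0) || !any(b@data != 0))
    stop("HD95 is undefined for an empty mask")
  sa <- .surfaceVoxels(a@data)
  sb <- .surfaceVoxels(b@data)
  sp <- a@spacing
  d <- dim(a@data)
  dToB <- sqrt(.edt3d(as.logical(sb), d, sp))
  dToA <- sqrt(.edt3d(as.logical(sa), d, sp))
  pooled <- c(dToB[sa], dToA[sb])
  quantile(pooled, percentile, type = 7, names = FALSE)
}

#' Bland-Altman agreement of paired measurements
#'
#' Mean difference (bias) and 95\% limits of agreement
#' bias +/- 1.96 * SD(differences) between two paired measurement series.
#'
#' @param x,y Numeric vectors of equal length (>= 3); differences are
#'   \code{y - x}.
#' @return A list with \code{bias}, \code{sd}, \code{loaLow}, \code{loaHigh},
#'   \code{n} and the vector of \code{differences}.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("paired measurements differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd = s,
       loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       n = length(d), differences = d)
}

#' Gwet's AC1 chance-corrected inter-rater agreement
#'
#' AC1 = (pa - pe) / (1 - pe), where pa is the observed proportion of
#' agreement between the two raters and the chance-agreement probability is
#' pe = (1/(Q-1)) * sum_q pi_q (1 - pi_q), with pi_q the mean of the two
#' raters' marginal proportions for category q. Unlike Cohen's kappa, AC1 is
#' robust to prevalence imbalance. The confidence interval uses Gwet's
#' subject-level linearized variance estimator with a normal approximation,
#' truncated above at 1. Only subjects rated by both raters contribute.
#'
#' @param ratings A subjects x raters matrix or data.frame of categorical
#'   ratings (factor, character or integer); \code{NA} marks a missing
#'   rating.
#' @param raters Length-2 vector of column names or indices selecting the
#'   rater pair; default the first two columns.
#' @param categories Optional vector fixing the category set Q; defaults to
#'   the union of categories observed in the two columns.
#' @param ciLevel Confidence level; default 0.95.
#' @return An \code{\linkS4class{AgreementResult}}.
#' @export
gwetAC1 <- function(ratings, raters = c(1, 2), categories = NULL,
                    ciLevel = 0.95) {
  ratings <- as.data.frame(ratings)
  if (length(raters) != 2) stop("exactly two raters must be selected")
  r1 <- as.character(ratings[[raters[1]]])
  r2 <- as.character(ratings[[raters[2]]])
  ok <- !is.na(r1) & !is.na(r2)
  if (all(!ok)) stop("a rater has no usable ratings")
  r1 <- r1[ok]; r2 <- r2[ok]
  n <- length(r1)
  if (n < 2) stop("need at least 2 subjects rated by both raters")
  cats <- if (is.null(categories)) sort(unique(c(r1, r2)))
          else as.character(categories)
  if (!all(c(r1, r2) %in% cats)) stop("ratings outside the category set")
  Q <- length(cats)
  if (Q < 2)
    stop("only one category present; supply 'categories' to fix the set")
  m1 <- outer(r1, cats, "==") + 0   # n x Q indicators
  m2 <- outer(r2, cats, "==") + 0
  piq <- (colMeans(m1) + colMeans(m2)) / 2
  pa <- mean(r1 == r2)
  pe <- sum(piq * (1 - piq)) / (Q - 1)
  ac1 <- (pa - pe) / (1 - pe)
  # Gwet (2008) linearization: per-subject pe and agreement indicators
  ai <- (r1 == r2) + 0
  piIq <- (m1 + m2) / 2
  pei <- as.vector(piIq %*% (1 - piq)) / (Q - 1)
  ac1i <- (ai - pe) / (1 - pe)
  ac1star <- ac1i - 2 * (1 - ac1) * (pei - pe) / (1 - pe)
  v <- sum((ac1star - ac1)^2) / (n * (n - 1))
  z <- qnorm(1 - (1 - ciLevel) / 2)
  half <- z * sqrt(max(v, 0))
  new("AgreementResult", statistic = "Gwet AC1", value = ac1,
      ciLower = ac1 - half, ciUpper = min(1, ac1 + half),
      n = as.integer(n),
      details = list(pa = pa, pe = pe, variance = v, categories = cats))
}

#' Per-class Dice and HD95 between two label masks
#'
#' Convenience batch comparison used by the command-line interface.
#'
#' @param pred,ref \code{\linkS4class{LabelMask}} objects on the same grid.
#' @param classes Class names to compare; default all non-background classes.
#' @return A data.frame with columns \code{class}, \code{dice},
#'   \code{hd95_mm} (HD95 is \code{NA} when either mask is empty for a
#'   class).
#' @export
compareMasks <- function(pred, ref, classes = NULL) {
  stopifnot(is(pred, "LabelMask"), is(ref, "LabelMask"))
  .sameGeometry(pred, ref, "label masks")
  if (is.null(classes))
    classes <- setdiff(names(pred@labelMap), "background")
  out <- lapply(classes, function(cl) {
    pa <- binarize(pred, cl); ra <- binarize(ref, cl)
    h <- if (any(pa@data != 0) && any(ra@data != 0)) hd95(pa, ra) else NA_real_
    data.frame(class = cl, dice = as.numeric(diceCoefficient(pa, ra)),
               hd95_mm = h)
  })
  do.call(rbind, out)
}
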