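#' Per-class tissue volumes
#'
#' Counts voxels of every non-background class and converts to cm^3 using the
#' voxel spacing (volume = count * sx*sy*sz / 1000). Classes absent from the
#' volume report zero. Optionally the standardized brain-mask-guided ROI is
#' applied first.
#'
#' @param labels A \code{\linkS4class{LabelMask}}.
#' @param brain Optional \code{\linkS4class{BinaryMask}}; required when
#'   \code{roiMode = "standardized"}.
#' @param roiMode \code{"whole"} (default) or \code{"standardized"} (apply
#'   \code{\link{standardizeROI}} before counting).
#' @return A data.frame with columns \code{class}, \code{voxels},
#'   \code{volume_cm3}, \code{roi_mode}.
#' @export
tissueVolumes <- function(labels, brain = NULL,
                          roiMode = c("whole", "standardized")) {
  roiMode <- match.arg(roiMode)
  stopifnot(is(labels, "LabelMask"))
  if (roiMode == "standardized") {
    if (is.null(brain))
      stop("'brain' mask is required for the standardized ROI")
    labels <- standardizeROI(labels, brain)$labels
  }
  lm <- labels@labelMap
  classes <- names(lm)[names(lm) != "background"]
  counts <- vapply(classes,
                   function(cl) sum(labels@data == lm[[cl]]),
                   integer(1))
  data.frame(class = classes,
             voxels = unname(counts),
             volume_cm3 = unname(counts) * prod(labels@spacing) / 1000,
             roi_mode = roiMode,
             row.names = NULL)
}

#' Percent change between two volume reports
#'
#' Signed per-class percent change 100 * (test - ref) / ref and absolute
#' difference in cm^3. A class with zero reference and zero test volume is
#' reported as 0\% change; zero reference with positive test volume is
#' undefined and flagged.
#'
#' @param test,reference Volume reports from \code{\link{tissueVolumes}}
#'   (must cover the same classes).
#' @return A data.frame with columns \code{class}, \code{reference_cm3},
#'   \code{test_cm3}, \code{diff_cm3}, \code{pct_change}, \code{defined}.
#' @export
percentChange <- function(test, reference) {
  if (!setequal(test$class, reference$class))
    stop("volume reports cover different classes")
  reference <- reference[match(test$class, reference$class), ]
  d <- test$volume_cm3 - reference$volume_cm3
  pct <- ifelse(reference$volume_cm3 > 0,
                100 * d / reference$volume_cm3,
                ifelse(test$volume_cm3 == 0, 0, NA_real_))
  data.frame(class = test$class,
             reference_cm3 = reference$volume_cm3,
             test_cm3 = test$volume_cm3,
             diff_cm3 = d,
             pct_change = pct,
             defined = !is.na(pct),
             row.names = NULL)
}
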