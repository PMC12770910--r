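test_that("the measurement band starts 10 mm above the reference slice", {
  b <- selectSlices(z0 = 50, spacingZ = 1, dimZ = 200)
  expect_identical(c(b$start, b$end), c(60L, 76L))
  expect_identical(length(b$z), 16L)
  # non-unit z spacing: the band covers 16 mm of physical extent
  b2 <- selectSlices(z0 = 50, spacingZ = 0.95, dimZ = 200)
  expect_identical(length(b2$z), as.integer(round(16 / 0.95)))
  expect_gte(length(b2$z) * 0.95, 16 - 0.95)
  # reference slice near the top of the volume is an extent error
  expect_error(selectSlices(z0 = 50, spacingZ = 1, dimZ = 70), "extent")
})

test_that("slice boundaries recover annulus contours and flag solid blobs", {
  sl <- annulusSlice(100, rOuter = 40, rInner = 35)
  b <- sliceBoundaries(sl)
  expect_false(b$degenerate)
  cx <- cy <- (100 + 1) / 2
  rOut <- sqrt((b$outer[, 1] - cx)^2 + (b$outer[, 2] - cy)^2)
  rIn <- sqrt((b$inner[, 1] - cx)^2 + (b$inner[, 2] - cy)^2)
  expect_lt(max(abs(rOut - 40)), 1)
  expect_lt(max(abs(rIn - 35)), 1)
  # solid disk has no enclosed cavity
  disk <- annulusSlice(60, rOuter = 20, rInner = 0)
  expect_true(sliceBoundaries(disk)$degenerate)
  expect_true(sliceBoundaries(matrix(0L, 20, 20))$degenerate)
})

test_that("contour sampling is uniform in arc length and starts anteriorly", {
  sl <- annulusSlice(120, rOuter = 45, rInner = 40)
  b <- sliceBoundaries(sl)
  smp <- sampleContourPoints(b$outer, n = 100)
  p <- smp$points
  # first sample is the most anterior contour vertex
  expect_equal(p[1, 1], max(b$outer[, 1]))
  # independent oracle: locate every sample on the polygon by point-to-segment
  # projection and read off its cumulative arc-length position
  poly <- b$outer
  m <- nrow(poly)
  closed <- rbind(poly, poly[1, ])
  seg <- closed[-1, , drop = FALSE] - closed[-(m + 1), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  arcPos <- function(pt) {
    rel <- sweep(closed[-(m + 1), , drop = FALSE], 2, pt, "-")
    tproj <- pmin(pmax(-rowSums(rel * seg) / pmax(len^2, 1e-12), 0), 1)
    foot <- closed[-(m + 1), , drop = FALSE] + tproj * seg
    dist2 <- rowSums(sweep(foot, 2, pt, "-")^2)
    i <- which.min(dist2)
    cum[i] + tproj[i] * len[i]
  }
  pos <- vapply(seq_len(100), function(j) arcPos(p[j, ]), numeric(1))
  total <- cum[m + 1]
  gaps <- diff(c(pos, pos[1] + total)) %% total
  # arc-length gaps are uniform at total/n within interpolation tolerance
  expect_lt(max(abs(gaps - total / 100)) / (total / 100), 0.01)

  # axis-aligned square, n = 4: samples sit a quarter-perimeter apart
  side <- 10
  sq <- rbind(cbind(1:(side + 1), 1),
              cbind(side + 1, 2:(side + 1)),
              cbind(side:1, side + 1),
              cbind(1, side:2))
  smp4 <- sampleContourPoints(sq, n = 4)
  d4 <- sqrt(rowSums((smp4$points[c(2:4, 1), ] - smp4$points)^2))
  expect_equal(d4, rep(side, 4), tolerance = 1e-8)
})

test_that("tangent-normal thickness recovers the annulus wall within a voxel", {
  sl <- annulusSlice(120, rOuter = 20 / 1 + 0, rInner = 15)  # 5 mm wall at 1 mm voxels
  b <- sliceBoundaries(sl)
  smp <- sampleContourPoints(b$outer, n = 50)
  th <- vapply(1:50, function(j)
    tangentThickness(smp$points[j, ], smp$vertexIndex[j], b, 1), numeric(1))
  expect_true(all(!is.na(th)))
  expect_true(all(abs(th - 5) <= 1))
})

test_that("rays exiting into an enclosed pocket are missing samples", {
  n <- 120; cx <- cy <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  ang <- atan2(g$y - cy, g$x - cx)
  sl <- matrix(as.integer(r <= 40 & r >= 30), n, n)
  # carve an enclosed air pocket inside the wall on the anterior side
  pocket <- r <= 38.5 & r >= 31.5 & abs(ang) < 0.2
  sl[matrix(pocket, n, n)] <- 0L
  b <- sliceBoundaries(sl)
  expect_false(b$degenerate)
  smp <- sampleContourPoints(b$outer, n = 100)
  th <- vapply(1:100, function(j)
    tangentThickness(smp$points[j, ], smp$vertexIndex[j], b, 1), numeric(1))
  angs <- atan2(smp$points[, 2] - cy, smp$points[, 1] - cx)
  inPocket <- abs(angs) < 0.15
  expect_true(any(inPocket))
  expect_true(all(is.na(th[inPocket])))     # pocket rays are missing
  expect_true(mean(!is.na(th[!inPocket])) > 0.9)
})

test_that("median thickness aggregates the central 95% of pooled samples", {
  ph <- smallPhantom()
  skull <- binarize(ph$labels, "skull")
  res <- medianSkullThickness(skull, ph$truth$z0)
  expect_s4_class(res, "ThicknessResult")
  expect_lt(abs(res@medianMm - ph$truth$wall_mm), 1)
  # trimming keeps at least 95% minus percentile edge effects
  expect_gte(res@nKept, 0.95 * res@nTotal - 2)
  # near-constant data: trimming does not move the median by more than a voxel
  valid <- res@samples$thickness_mm[!is.na(res@samples$thickness_mm)]
  expect_lt(abs(res@medianMm - median(valid)), 1)
  # per-slice trimming is a supported alternative with a similar answer
  resPS <- medianSkullThickness(skull, ph$truth$z0, perSliceTrim = TRUE)
  expect_lt(abs(resPS@medianMm - res@medianMm), 1)
  # audit bookkeeping
  expect_identical(res@band, c(ph$truth$z0 + 10L, ph$truth$z0 + 26L))
  expect_identical(nrow(res@perSlice), 16L)
})

test_that("degenerate or insufficient inputs raise clear thickness errors", {
  # solid cylinder: every slice is degenerate, so no samples accumulate
  arr <- array(0L, dim = c(60, 60, 40))
  arr[20:40, 20:40, ] <- 1L
  expect_error(medianSkullThickness(asBinary(arr), z0 = 0), "insufficient")
  # non ~1 mm in-plane spacing is rejected
  ph <- smallPhantom()
  skull <- binarize(ph$labels, "skull")
  coarse <- new("BinaryMask", data = voxels(skull), spacing = c(2, 2, 1))
  expect_error(medianSkullThickness(coarse, ph$truth$z0), "1 mm")
})

test_that("CT thresholding recovers phantom bone exactly and sweeps monotonically", {
  ph <- smallPhantom()
  mask <- ctSkullMask(ph$ct, 471)
  expect_identical(voxels(mask), (voxels(ph$labels) == 2L) + 0L)
  expect_error(ctSkullMask(ph$ct, -1500), "-1000")
  # threshold above all bone attenuation: empty mask with a warning
  expect_warning(empty <- ctSkullMask(ph$ct, 1500), "empty")
  expect_identical(sum(voxels(empty)), 0L)
  # two-density skull: mask volume non-increasing over the threshold sweep
  ph2 <- makePhantom(smallPhantomSpec(cancellousFrac = 0.5))
  vols <- vapply(c(300, 400, 500, 800),
                 function(hu) sum(voxels(ctSkullMask(ph2$ct, hu))), numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_lt(vols[3], vols[2])     # cancellous bone drops out above 450 HU
})

test_that("thickness comparison tables report means and absolute differences", {
  df <- data.frame(tool = rep(c("ct", "mri"), each = 2),
                   subject = rep(c("s1", "s2"), 2),
                   thickness_mm = c(5.60, 6.00, 5.46, 6.20))
  tab <- compareThickness(df, "ct")
  expect_equal(tab$mean_abs_diff_mm[tab$tool == "mri"], mean(c(0.14, 0.20)))
  expect_true(is.na(tab$mean_abs_diff_mm[tab$tool == "ct"]))
  same <- data.frame(tool = rep(c("ct", "copy"), each = 2),
                     subject = rep(c("s1", "s2"), 2),
                     thickness_mm = c(5, 6, 5, 6))
  expect_equal(compareThickness(same, "ct")$mean_abs_diff_mm[2], 0)
  expect_error(compareThickness(df, "grace"), "not present")
  expect_error(compareThickness(df[df$tool == "ct", ], "ct"), "two tools")
})

test_that("the CT-derived and label-derived skull masks give matching thickness", {
  ph <- smallPhantom()
  thLabel <- medianSkullThickness(binarize(ph$labels, "skull"), ph$truth$z0)
  thCT <- medianSkullThickness(ctSkullMask(ph$ct, 471), ph$truth$z0)
  expect_lte(abs(thLabel@medianMm - thCT@medianMm), 1)
})

test_that("the fallback reference-slice heuristic lands below the equator", {
  ph <- smallPhantom()
  skull <- binarize(ph$labels, "skull")
  z0 <- autoReferenceSlice(skull)
  expect_lt(z0, ph$truth$center[3])
  expect_error(autoReferenceSlice(asBinary(array(0L, c(8, 8, 8)))), "empty")
})
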