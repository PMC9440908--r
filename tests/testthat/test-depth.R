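test_that("median filter smooths speckle and preserves constants", {
  v <- array(0.3, c(12, 12, 12))
  expect_equal(medianFilter3D(v), v)
  v[6, 6, 6] <- 5        # isolated hot voxel vanishes
  expect_equal(medianFilter3D(v)[6, 6, 6], 0.3)
})

test_that("a noiseless flat surface yields monotone columns and exact recovery", {
  vol <- simulateStructuralVolume(c(40, 40), nz = 60, noiseSd = 0,
                                  speckle = FALSE,
                                  surfaceFn = function(x, y) 10)
  expect_equal(vol$surfaceUm, matrix(10, 40, 40))
  # monotone non-decreasing z profile in every column
  mono <- apply(vol$volume, c(1, 2), function(p) all(diff(p) >= -1e-12))
  expect_true(all(mono))
  sm <- detectSurface(vol$volume, zStepUm = 1)
  expect_lte(max(abs(sm@z - 10), na.rm = TRUE), 1)
})

test_that("a tilted plane is recovered within one z-step at default noise", {
  plane <- function(x, y) 8 + 0.15 * x + 0.1 * y
  vol <- simulateStructuralVolume(c(60, 60), nz = 60, surfaceFn = plane,
                                  seed = 2)
  truth <- vol$surfaceUm
  sm <- detectSurface(vol$volume, zStepUm = 1)
  # compare per-column estimate to the mean true surface in that column
  colTruth <- matrix(NA_real_, nrow(sm@z), ncol(sm@z))
  for (i in seq_len(nrow(sm@z))) for (j in seq_len(ncol(sm@z))) {
    xs <- ((i - 1) * 10 + 1):min(i * 10, 60)
    ys <- ((j - 1) * 10 + 1):min(j * 10, 60)
    colTruth[i, j] <- mean(truth[xs, ys])
  }
  err <- abs(sm@z - colTruth)
  expect_lte(mean(err, na.rm = TRUE), 1)
})

test_that("surface detection is z-translation-equivariant (noiseless)", {
  v1 <- simulateStructuralVolume(c(30, 30), nz = 60, noiseSd = 0,
                                 speckle = FALSE,
                                 surfaceFn = function(x, y) 12)
  v2 <- simulateStructuralVolume(c(30, 30), nz = 60, noiseSd = 0,
                                 speckle = FALSE,
                                 surfaceFn = function(x, y) 20)
  s1 <- detectSurface(v1$volume, zStepUm = 1, clahe = FALSE)
  s2 <- detectSurface(v2$volume, zStepUm = 1, clahe = FALSE)
  expect_equal(s2@z - s1@z, matrix(8, nrow(s1@z), ncol(s1@z)),
               tolerance = 1.01)
})

test_that("degenerate volumes are rejected", {
  expect_error(detectSurface(array(0.2, c(20, 20, 30))), "surface error")
  expect_error(simulateStructuralVolume(nz = 12, surfaceFn = function(x, y) 11),
               "configuration error")
  expect_error(detectSurface(array(0.2, c(20, 20, 5))), "10 z-slices")
})

test_that("ROI depth is plane z minus surface z with 14 um plane spacing", {
  z <- matrix(10, 3, 3)
  sm <- new("SurfaceMap", z = z, quality = matrix(1, 3, 3), zStepUm = 1,
            colPx = 10)
  roi <- data.frame(cell_id = c("a", "b", "c"),
                    x_px = c(5, 15, 25), y_px = c(5, 15, 25),
                    plane_index = c(0L, 1L, 2L))
  out <- assignDepth(roi, sm, planeZ0Um = 30)
  expect_equal(out$depth_um, c(20, 34, 48))   # offsets 0, 14, 28
  # above-surface ROI: negative depth plus warning
  expect_warning(out2 <- assignDepth(data.frame(cell_id = "d", x_px = 5,
                                                y_px = 5, plane_index = 0L),
                                     sm, planeZ0Um = 5), "above")
  expect_equal(out2$depth_um, -5)
  expect_equal(out2$depth_flag, "negative")
  # missing surface column: depth missing, flagged
  z2 <- z; z2[1, 1] <- NA
  sm2 <- new("SurfaceMap", z = z2, quality = matrix(1, 3, 3), zStepUm = 1,
             colPx = 10)
  out3 <- assignDepth(roi[1, ], sm2, planeZ0Um = 30)
  expect_true(is.na(out3$depth_um))
  expect_equal(out3$depth_flag, "missing_surface")
})

test_that("end-to-end depth recovery on a synthetic volume stays within 1 um", {
  plane <- function(x, y) 9 + 0.1 * x
  vol <- simulateStructuralVolume(c(50, 50), nz = 60, surfaceFn = plane,
                                  seed = 4)
  sm <- detectSurface(vol$volume, zStepUm = 1)
  set.seed(5)
  roi <- data.frame(cell_id = sprintf("r%02d", 1:40),
                    x_px = runif(40, 1, 49), y_px = runif(40, 1, 49),
                    plane_index = sample(0:2, 40, TRUE))
  out <- assignDepth(roi, sm, planeZ0Um = 30)
  trueDepth <- 30 + roi$plane_index * 14 - vol$surfaceUm[
    cbind(pmax(1, round(roi$x_px)), pmax(1, round(roi$y_px)))]
  expect_lte(mean(abs(out$depth_um - trueDepth), na.rm = TRUE), 1.5)
})
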