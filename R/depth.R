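#' 3-D median filter
#'
#' Cube-neighbourhood median smoothing of a structural volume, with the
#' neighbourhood clipped at the boundary.
#'
#' @param volume 3-D numeric array (x, y, z).
#' @param radius neighbourhood radius in voxels (1 = 3x3x3).
#' @return filtered array of the same shape.
#' @export
medianFilter3D <- function(volume, radius = 1L) {
  stopifnot(length(dim(volume)) == 3L, radius >= 0)
  if (radius == 0L) return(volume)
  .median3d_cpp(as.numeric(volume), as.integer(dim(volume)),
                as.integer(radius))
}

#' Detect the dorsal grey-matter surface in a structural volume
#'
#' The curved tissue surface must be located before cell depths can be
#' computed. The volume (acquired from above: low z = above the tissue,
#' high z = deep) is smoothed with a 3-D median filter, contrast-enhanced
#' slice-wise with CLAHE, and XY-downsampled into columns of
#' `columnXY` x `columnXY` pixels. For each column the mean-intensity z
#' profile rises asymptotically as the tissue comes into focus; the
#' surface is taken as the first z at which the profile exceeds 50% of the
#' column's plateau, where the plateau is the mean of the deepest quartile
#' of slices. Columns whose plateau-to-background contrast (quality) is
#' below `minQuality` carry no usable surface and are marked missing.
#'
#' @param volume 3-D numeric array (x, y, z), z from above the surface
#'   downward.
#' @param zStepUm z step in micrometres.
#' @param medianRadius radius for [medianFilter3D()].
#' @param claheTilePx approximate CLAHE tile size in pixels.
#' @param claheLimit CLAHE contrast limit (passed to [EBImage::clahe()]).
#' @param columnXY XY size of each downsampling column, pixels.
#' @param minQuality minimum plateau-to-background contrast (on the
#'   volume's normalized 0-1 intensity scale) for a column estimate.
#' @param clahe apply CLAHE (set `FALSE` to skip contrast enhancement).
#' @return a [SurfaceMap-class].
#' @export
detectSurface <- function(volume, zStepUm = 1, medianRadius = 1L,
                          claheTilePx = 32, claheLimit = 2,
                          columnXY = 10L, minQuality = 0.05,
                          clahe = TRUE) {
  stopifnot(length(dim(volume)) == 3L)
  nz <- dim(volume)[3]
  if (nz < 10L) stop("volume must have at least 10 z-slices")
  v <- medianFilter3D(volume, medianRadius)
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  if (clahe && diff(rng) > 0) {
    nxTiles <- max(1L, round(dim(v)[1] / claheTilePx))
    nyTiles <- max(1L, round(dim(v)[2] / claheTilePx))
    for (k in seq_len(nz)) {
      if (diff(range(v[, , k])) <= 0) next   # constant slice: nothing to equalize
      v[, , k] <- EBImage::clahe(EBImage::Image(v[, , k]),
                                 nx = nxTiles, ny = nyTiles,
                                 limit = claheLimit, keep.range = TRUE)
    }
  }
  nxCol <- ceiling(dim(v)[1] / columnXY)
  nyCol <- ceiling(dim(v)[2] / columnXY)
  zMat <- qMat <- matrix(NA_real_, nxCol, nyCol)
  qIdx <- max(1L, floor(nz * 3 / 4))
  for (i in seq_len(nxCol)) {
    xs <- ((i - 1L) * columnXY + 1L):min(i * columnXY, dim(v)[1])
    for (j in seq_len(nyCol)) {
      ys <- ((j - 1L) * columnXY + 1L):min(j * columnXY, dim(v)[2])
      prof <- apply(v[xs, ys, , drop = FALSE], 3L, mean)
      plateau <- mean(prof[qIdx:nz])
      background <- mean(prof[seq_len(max(1L, floor(nz / 4)))])
      quality <- plateau - background
      qMat[i, j] <- quality
      if (!is.finite(quality) || quality < minQuality) next
      cross <- which(prof > 0.5 * plateau)
      if (length(cross)) zMat[i, j] <- (cross[1] - 1L) * zStepUm
    }
  }
  if (all(is.na(zMat)))
    stop("surface error: no column had usable contrast")
  new("SurfaceMap", z = zMat, quality = qMat, zStepUm = zStepUm,
      colPx = as.numeric(columnXY))
}

#' Assign dorso-ventral depth to ROIs
#'
#' Each imaging plane sits at a fixed absolute z (plane 0 at `planeZ0Um`,
#' subsequent planes `planeSpacingUm` = 14 um apart). A cell's depth below
#' the dorsal surface is the absolute z of its plane minus the surface z
#' at its XY column. Cells above the estimated surface get a negative
#' depth and a warning flag; cells over columns without a surface estimate
#' get a missing depth.
#'
#' @param roi data.frame/DataFrame with `x_px`, `y_px`, `plane_index`
#'   (0-based).
#' @param surface a [SurfaceMap-class].
#' @param planeZ0Um absolute z (um, volume frame) of plane 0.
#' @param planeSpacingUm spacing between planes (um).
#' @return the ROI table with columns `depth_um` and `depth_flag`
#'   (`"ok"`, `"negative"`, `"missing_surface"`).
#' @export
assignDepth <- function(roi, surface, planeZ0Um = 0,
                        planeSpacingUm = 14) {
  roi <- as.data.frame(roi)
  stopifnot(all(c("x_px", "y_px", "plane_index") %in% names(roi)))
  ci <- pmin(nrow(surface@z), floor(roi$x_px / surface@colPx) + 1L)
  cj <- pmin(ncol(surface@z), floor(roi$y_px / surface@colPx) + 1L)
  ci <- pmax(1L, ci); cj <- pmax(1L, cj)
  zsurf <- surface@z[cbind(ci, cj)]
  planeZ <- planeZ0Um + roi$plane_index * planeSpacingUm
  depth <- planeZ - zsurf
  flag <- ifelse(is.na(zsurf), "missing_surface",
                 ifelse(depth < 0, "negative", "ok"))
  if (any(flag == "negative"))
    warning(sum(flag == "negative"), " ROI(s) lie above the estimated surface")
  roi$depth_um <- depth
  roi$depth_flag <- flag
  roi
}
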