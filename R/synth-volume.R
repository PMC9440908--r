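#' Simulate a structural volume with a known tissue surface
#'
#' Builds a 3-D stack emulating a high-contrast structural acquisition of
#' the dorsal horn: dark above the tissue, a sigmoidal intensity rise at
#' the surface, and a bright plateau below, optionally speckled with
#' cell-body blobs. The true surface map is returned for recovery tests.
#'
#' @param xyShape c(nx, ny) in pixels.
#' @param nz number of z slices.
#' @param zStepUm z step in micrometres.
#' @param surfaceFn function (x_px, y_px) -> surface z in um; may be
#'   vectorized via `outer`. Default: flat surface at 10 um.
#' @param noiseSd additive Gaussian noise SD (intensity units; plateau is
#'   ~0.5).
#' @param speckle add bright cell-body blobs below the surface.
#' @param background,plateau intensity levels above/below the surface.
#' @param riseWidthUm width of the sigmoidal rise.
#' @param seed random seed.
#' @return list with `volume` (nx x ny x nz array), `surfaceUm` (nx x ny
#'   true surface map) and `zStepUm`.
#' @export
simulateStructuralVolume <- function(xyShape = c(64, 64), nz = 70,
                                     zStepUm = 1,
                                     surfaceFn = function(x, y) 10,
                                     noiseSd = 0.02, speckle = TRUE,
                                     background = 0.05, plateau = 0.5,
                                     riseWidthUm = 0.8, seed = 1) {
  nx <- xyShape[1]; ny <- xyShape[2]
  surf <- outer(seq_len(nx), seq_len(ny), Vectorize(surfaceFn))
  zMax <- nz * zStepUm
  if (any(surf < 2 * zStepUm) || any(surf > zMax * 0.7))
    stop("configuration error: z range too thin to contain the surface")
  set.seed(seed)
  zUm <- (seq_len(nz) - 1L) * zStepUm
  vol <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz))
    vol[, , k] <- background + (plateau - background) *
      stats::plogis((zUm[k] - surf) / riseWidthUm)
  if (speckle) {
    nBlob <- round(nx * ny * nz / 3000)
    bx <- stats::runif(nBlob, 1, nx)
    by <- stats::runif(nBlob, 1, ny)
    bz <- stats::runif(nBlob, 0, zMax)
    for (b in seq_len(nBlob)) {
      if (bz[b] < surf[round(bx[b]), round(by[b])] + 4) next
      xs <- max(1, round(bx[b]) - 3):min(nx, round(bx[b]) + 3)
      ys <- max(1, round(by[b]) - 3):min(ny, round(by[b]) + 3)
      zs <- max(1, round(bz[b] / zStepUm) - 2):min(nz, round(bz[b] / zStepUm) + 2)
      for (k in zs) {
        d2 <- outer((xs - bx[b])^2, (ys - by[b])^2, `+`) +
          (zUm[k] - bz[b])^2 / zStepUm^2
        vol[xs, ys, k] <- vol[xs, ys, k] + 0.35 * exp(-d2 / (2 * 1.5^2))
      }
    }
  }
  if (noiseSd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, noiseSd), dim(vol))
  vol <- pmax(vol, 0)
  list(volume = vol, surfaceUm = surf, zStepUm = zStepUm)
}
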