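#' Vector-based modality tuning of one cell
#'
#' The three modality amplitudes (maximum response amplitude across trials,
#' e.g. heat / mechanical / cold, or brush / LT / HT for the mechanical
#' sub-modalities) are first normalized to their per-cell mean, then placed
#' as vectors at the three basis angles (90, 210 and 330 degrees
#' counter-clockwise from the positive x-axis, 120 degrees apart), and
#' summed. The angle of the sum is the cell's preferred modality direction
#' and its length the tuning strength: an equally tri-modal cell sums to
#' the zero vector, a single-modality cell points exactly along its basis
#' angle. Normalizing by the mean makes the result invariant to uniform
#' scaling of all three amplitudes.
#'
#' @param amplitudes numeric length 3, non-negative, in the order of
#'   `basisAngles`.
#' @param basisAngles numeric length 3, degrees CCW from +x, pairwise 120
#'   degrees apart.
#' @return list with `angle_deg` in [0, 360), `magnitude` (1.0 = one unit
#'   vector), `components` (the three vectors as a 3x2 matrix) and
#'   `excluded = FALSE`; or, for all-zero amplitudes (cells with no
#'   responses are excluded from tuning analysis), `excluded = TRUE` with
#'   `NA` angle and magnitude.
#' @examples
#' tuningVector(c(1, 0, 0))$angle_deg     # 90: pure first-modality cell
#' tuningVector(c(1, 1, 1))$magnitude     # 0: untuned
#' @export
tuningVector <- function(amplitudes,
                         basisAngles = c(heat = 90, mech = 210, cold = 330)) {
  stopifnot(length(amplitudes) == 3L, length(basisAngles) == 3L)
  if (any(amplitudes < 0 | !is.finite(amplitudes)))
    stop("amplitudes must be finite and non-negative")
  if (all(amplitudes == 0))
    return(list(angle_deg = NA_real_, magnitude = NA_real_,
                components = NULL, excluded = TRUE))
  norm <- amplitudes / mean(amplitudes)
  # cospi/sinpi are exact at multiples of 90 degrees
  comp <- cbind(x = norm * cospi(basisAngles / 180),
                y = norm * sinpi(basisAngles / 180))
  v <- colSums(comp)
  mag <- sqrt(sum(v^2))
  ang <- if (mag == 0) 0 else (atan2(v["y"], v["x"]) * 180 / pi) %% 360
  ang <- round(ang, 9) %% 360   # absorb atan2 round-off at exact angles
  list(angle_deg = unname(ang), magnitude = mag, components = comp,
       excluded = FALSE)
}

#' Standardize circular angles to signed degrees-from-axis
#'
#' Maps each angle to the signed smallest rotation from a reference axis,
#' in (-180, 180]. Angles differing by full turns are equivalent: +1 and
#' -359 both standardize to +1 against axis 0. Required before any linear
#' statistic is applied to angular data.
#'
#' @param angles numeric vector of angles in degrees.
#' @param referenceAngle axis to standardize against, degrees.
#' @return signed degrees from the axis, in (-180, 180].
#' @examples
#' standardizeAngles(c(1, -359), 0)   # both +1
#' @export
standardizeAngles <- function(angles, referenceAngle = 0) {
  stopifnot(all(is.finite(angles)))
  d <- (angles - referenceAngle) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Modality preference score
#'
#' `(X_i - X_avg) / X_max` per modality: the deviation of each modality's
#' amplitude from the cell's average, scaled by its maximum amplitude.
#' Positive values mark preferred modalities. For three modalities the
#' score is bounded above by 2/3.
#'
#' @param amplitudes numeric vector of per-modality amplitudes.
#' @return numeric vector of scores (same names); all-`NA` with a
#'   `"degenerate"` attribute when every amplitude is zero.
#' @examples
#' preferenceScore(c(2, 1, 0))   # 0.5 0 -0.5
#' @export
preferenceScore <- function(amplitudes) {
  if (max(amplitudes) <= 0) {
    out <- rep(NA_real_, length(amplitudes))
    names(out) <- names(amplitudes)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (amplitudes - mean(amplitudes)) / max(amplitudes)
}

#' Per-cell tuning table for a block
#'
#' Computes [tuningVector()] for every cell from a family-response table,
#' using the maximum peak amplitude across all trials of each modality.
#' `modalities` selects and orders the three families mapped onto the basis
#' angles: the cardinal set is heat/mechanical/cold (mechanical = the
#' maximum over all mechanical families), the mechanical sub-modality set
#' brush/static_LT/static_HT.
#'
#' @param famResp family-response table from [assignFamilyResponse()].
#' @param block `"pre"` or `"post"`.
#' @param modalities `"cardinal"` or `"mechanical"`.
#' @param config a [CicadaConfig-class].
#' @return data.frame `cell_id`, `block`, the three amplitudes,
#'   `angle_deg`, `magnitude`, `excluded`.
#' @export
tuningTable <- function(famResp, block = "pre",
                        modalities = c("cardinal", "mechanical"),
                        config = cicadaConfig()) {
  modalities <- match.arg(modalities)
  fr <- famResp[famResp$block == block, , drop = FALSE]
  cells <- unique(fr$cell_id)
  ampOf <- function(cell, fams) {
    g <- fr[fr$cell_id == cell & fr$family %in% fams, , drop = FALSE]
    if (nrow(g) == 0L) 0 else max(g$max_peak, 0)
  }
  rows <- lapply(cells, function(cl) {
    a <- if (modalities == "cardinal")
      c(ampOf(cl, "heat"),
        ampOf(cl, c("brush", "airpuff", "static_LT", "static_HT")),
        ampOf(cl, "cold"))
    else
      c(ampOf(cl, "brush"), ampOf(cl, "static_LT"), ampOf(cl, "static_HT"))
    a <- pmax(a, 0)
    tv <- tuningVector(a, config@basisAngles)
    data.frame(cell_id = cl, block = block, amp1 = a[1], amp2 = a[2],
               amp3 = a[3], angle_deg = tv$angle_deg,
               magnitude = tv$magnitude, excluded = tv$excluded,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  names(out)[3:5] <- if (modalities == "cardinal")
    c("amp_heat", "amp_mech", "amp_cold") else
      c("amp_brush", "amp_lt", "amp_ht")
  out
}
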