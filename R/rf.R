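#' Receptive-field size from per-trial responder grids
#'
#' The skin is probed with a von Frey filament at 16 sites in a 4x4 grid,
#' twice per filament and block. The receptive-field size is the number of
#' responsive sites averaged across trials, giving a possible size of 0 to
#' 16.
#'
#' @param grids a list of per-trial 4x4 logical matrices, or a 4x4xT array.
#' @return list of class `ReceptiveField` with `size`, `per_trial` counts,
#'   `site_sum` (4x4 matrix of per-site response counts) and `n_trials`.
#' @examples
#' g <- matrix(FALSE, 4, 4); g[1, 1:4] <- TRUE
#' rfSize(list(g, g))$size   # 4
#' @export
rfSize <- function(grids) {
  if (is.array(grids) && length(dim(grids)) == 3L)
    grids <- lapply(seq_len(dim(grids)[3]), function(i) grids[, , i])
  if (!length(grids)) stop("at least one trial grid is required")
  for (g in grids)
    if (!identical(dim(g), c(4L, 4L)))
      stop("shape error: receptive-field grids must be 4x4")
  counts <- vapply(grids, function(g) sum(g, na.rm = TRUE), numeric(1))
  sums <- Reduce(`+`, lapply(grids, function(g) {
    g[is.na(g)] <- FALSE; g + 0
  }))
  out <- list(size = mean(counts), per_trial = counts, site_sum = sums,
              n_trials = length(grids))
  class(out) <- "ReceptiveField"
  out
}

#' @export
print.ReceptiveField <- function(x, ...) {
  cat("ReceptiveField: size", x$size, "sites over", x$n_trials, "trials\n")
  invisible(x)
}

#' Convert a receptive-field size to estimated skin area
#'
#' The 16 grid sites span a 225 mm^2 region spaced ~3.75 mm apart, so each
#' responsive site represents about 3.75 mm^2 of skin: a cell responding at
#' 4 sites has an estimated receptive field of 15 mm^2.
#'
#' @param size responsive-site count (0-16, possibly fractional).
#' @param perSiteAreaMm2 skin area per site (mm^2).
#' @return area in mm^2.
#' @examples
#' rfArea(4)    # 15
#' @export
rfArea <- function(size, perSiteAreaMm2 = 3.75) {
  stopifnot(all(size >= 0))
  size * perSiteAreaMm2
}

#' Receptive-field table from response calls
#'
#' Builds per-trial 4x4 responder grids for each cell from the static
#' filament calls and summarizes them with [rfSize()] and [rfArea()].
#'
#' @param calls data.frame from [detectResponses()].
#' @param family `"static_LT"` or `"static_HT"`.
#' @param block `"pre"` or `"post"`.
#' @param config a [CicadaConfig-class].
#' @return data.frame `cell_id`, `family`, `block`, `size`, `area_mm2`.
#' @export
rfTable <- function(calls, family = "static_LT", block = "pre",
                    config = cicadaConfig()) {
  g <- calls[calls$family == family & calls$block == block, , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(cell_id = character(), family = character(),
                      block = character(), size = numeric(),
                      area_mm2 = numeric()))
  out <- do.call(rbind, lapply(split(g, g$cell_id), function(gc) {
    grids <- lapply(sort(unique(gc$trial_index)), function(tr) {
      m <- matrix(FALSE, 4, 4)
      t <- gc[gc$trial_index == tr, ]
      m[cbind(t$grid_row + 1L, t$grid_col + 1L)] <- t$responder
      m
    })
    rf <- rfSize(grids)
    data.frame(cell_id = gc$cell_id[1], family = family, block = block,
               size = rf$size,
               area_mm2 = rfArea(rf$size, config@perSiteAreaMm2),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Exact 1-D Wasserstein (earth mover's) distance between samples
#'
#' Integral of the absolute difference of the two empirical CDFs; exact for
#' finite samples and robust at small n.
#'
#' @param a,b numeric samples.
#' @return non-negative distance in the units of the inputs.
#' @export
wasserstein1 <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  grid <- sort(unique(c(a, b)))
  if (length(grid) < 2L) return(0)
  Fa <- stats::ecdf(a)(grid[-length(grid)])
  Fb <- stats::ecdf(b)(grid[-length(grid)])
  sum(abs(Fa - Fb) * diff(grid))
}

#' Infer the capsaicin injection locus from responder positions
#'
#' The dorsal horn is somatotopically organized along its medio-lateral
#' axis, so cells responding to stimulation of one skin column occupy a
#' characteristic medio-lateral band. This operation compares the
#' medio-lateral distribution of capsaicin responders to reference
#' distributions (positions of cells responding to the HT filament at each
#' of the 4 grid columns) using the exact 1-D Wasserstein distance, and
#' returns the best-matching column as the inferred injection locus. The
#' spread is the set of columns within 1.5x the minimum distance, and
#' confidence is the relative margin between the two closest references.
#'
#' @param responderPositions medio-lateral positions of capsaicin
#'   responders.
#' @param referencePositions list, one numeric vector per grid column
#'   (named or in column order 0..3).
#' @param minResponders minimum responders required for an estimate.
#' @param marginThreshold relative margin below which the estimate is
#'   flagged low-confidence.
#' @return list with `locus` (0-based column, `NA` when low-confidence
#'   with too few responders), `spread`, `distances`, `margin`,
#'   `low_confidence`.
#' @export
inferInjectionLocus <- function(responderPositions, referencePositions,
                                minResponders = 5L, marginThreshold = 0.1) {
  stopifnot(length(referencePositions) >= 1L)
  cols <- if (!is.null(names(referencePositions)))
    as.integer(names(referencePositions)) else
      seq_along(referencePositions) - 1L
  if (length(responderPositions) < minResponders)
    return(list(locus = NA_integer_, spread = integer(0),
                distances = stats::setNames(rep(NA_real_, length(cols)), cols),
                margin = NA_real_, low_confidence = TRUE))
  d <- vapply(referencePositions, wasserstein1, numeric(1),
              a = responderPositions)
  names(d) <- cols
  ord <- order(d)
  margin <- if (length(d) > 1L)
    (d[ord[2]] - d[ord[1]]) / max(d[ord[2]], .Machine$double.eps) else 1
  list(locus = cols[ord[1]],
       spread = sort(cols[d <= 1.5 * d[ord[1]]]),
       distances = d, margin = unname(margin),
       low_confidence = unname(margin) < marginThreshold)
}
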