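#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   `rowData<-` colData
NULL

.STIM_FAMILIES   <- c("brush", "airpuff", "static_LT", "static_HT",
                      "heat", "cold")
.GRID_FAMILIES   <- c("static_LT", "static_HT")
.LIGAND_FAMILIES <- c("SP", "OXT", "GRP", "Oxo", "taltirelin", "NMB",
                      "CCK", "NKB")
.EVENT_KINDS     <- c("stimulus", "ligand", "injection")

#' Raw fluorescence traces for a population recording
#'
#' `TraceSet` holds the cells-by-frames raw fluorescence matrix of a
#' multiphoton population recording, together with the frame rate and any
#' per-cell ROI annotation (in-plane position, imaging plane, projection
#' neuron flag, depth). It extends
#' \linkS4class{SummarizedExperiment}: the single assay `"fluor"` is the
#' fluorescence matrix, `rowData` carries the ROI table and `metadata`
#' carries `frame_rate_hz`.
#'
#' `NA` frames are permitted and represent masked intervals (e.g. the blind
#' spot while the shutter is closed during an intradermal injection); all
#' non-missing values must be finite and non-negative.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!"fluor" %in% names(assays(object)))
    msg <- c(msg, "assay 'fluor' is required")
  else {
    f <- assay(object, "fluor")
    v <- f[!is.na(f)]
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
      msg <- c(msg, "non-missing fluorescence values must be finite and >= 0")
  }
  fr <- metadata(object)$frame_rate_hz
  if (is.null(fr) || !is.numeric(fr) || length(fr) != 1L || !is.finite(fr) ||
      fr <= 0)
    msg <- c(msg, "metadata frame_rate_hz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a TraceSet
#'
#' @param fluor numeric matrix of raw fluorescence, cells in rows and frames
#'   in columns. Row names, if present, are taken as cell identifiers.
#' @param cellIds character vector of cell identifiers (defaults to the row
#'   names of `fluor`, else `cell_1 ... cell_n`).
#' @param frameRate acquisition rate in frames per second (Hz). The imaging
#'   protocol scans each plane at 1 Hz, the default.
#' @param roi optional per-cell annotation `data.frame`/`DataFrame` with
#'   columns such as `x_px`, `y_px`, `plane_index`, `is_spbn`; stored in
#'   `rowData`.
#' @return a [TraceSet-class] object.
#' @export
TraceSet <- function(fluor, cellIds = NULL, frameRate = 1.0, roi = NULL) {
  fluor <- as.matrix(fluor)
  storage.mode(fluor) <- "double"
  if (is.null(cellIds))
    cellIds <- if (!is.null(rownames(fluor))) rownames(fluor) else
      paste0("cell_", seq_len(nrow(fluor)))
  if (length(cellIds) != nrow(fluor))
    stop("length(cellIds) must equal nrow(fluor)")
  if (anyDuplicated(cellIds)) stop("cell identifiers must be unique")
  rownames(fluor) <- cellIds
  rd <- if (is.null(roi)) DataFrame(row.names = cellIds) else {
    roi <- DataFrame(roi)
    if ("cell_id" %in% colnames(roi)) {
      if (!setequal(roi$cell_id, cellIds))
        stop("roi cell_id set does not match trace cell identifiers")
      roi <- roi[match(cellIds, roi$cell_id), , drop = FALSE]
      roi$cell_id <- NULL
    } else if (nrow(roi) != length(cellIds))
      stop("roi table must have one row per cell")
    rownames(roi) <- cellIds
    roi
  }
  se <- SummarizedExperiment(
    assays = SimpleList(fluor = fluor), rowData = rd,
    metadata = list(frame_rate_hz = as.numeric(frameRate)))
  new("TraceSet", se)
}

#' Baseline-corrected traces with QC annotation
#'
#' `DffSet` is the product of [preprocessTraces()]: assays `"dff"`
#' (fractional fluorescence change, 1.0 = 100%) and `"baseline"` (the
#' rolling-percentile baseline, same units as the raw fluorescence), with
#' per-cell quality-control columns `qc_keep` and `qc_reason` in `rowData`.
#'
#' @export
setClass("DffSet", contains = "SummarizedExperiment")

setValidity("DffSet", function(object) {
  msg <- character()
  if (!all(c("dff", "baseline") %in% names(assays(object))))
    msg <- c(msg, "assays 'dff' and 'baseline' are required")
  else {
    b <- assay(object, "baseline")
    d <- assay(object, "dff")
    bad <- !is.na(d) & (is.na(b) | b <= 0)
    if (any(bad))
      msg <- c(msg, "baseline must be positive wherever dff is defined")
  }
  if (!"qc_keep" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'qc_keep' is required")
  if (length(msg)) msg else TRUE
})

#' Typed stimulus/ligand/injection event timeline
#'
#' Ordered record of everything delivered during an experiment: cutaneous
#' stimuli (brush, airpuff, static low/high-threshold von Frey at a 4x4
#' grid site, heat and cold ramps), an optional intradermal capsaicin
#' injection, and the end-of-experiment Gq-GPCR agonist (CICADA ligand)
#' series. Grid coordinates are 0-based `(row, col)` and present exactly
#' for the static filament families.
#'
#' @slot events a `DataFrame` with columns `kind`, `family`, `onset_s`,
#'   `duration_s`, `grid_row`, `grid_col`, `trial_index`, `block`.
#' @export
setClass("EventTimeline", representation(events = "DataFrame"))

.EVENT_COLS <- c("kind", "family", "onset_s", "duration_s",
                 "grid_row", "grid_col", "trial_index", "block")

setValidity("EventTimeline", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(.EVENT_COLS %in% colnames(ev)))
    return(paste("missing event columns:",
                 paste(setdiff(.EVENT_COLS, colnames(ev)), collapse = ", ")))
  if (nrow(ev) == 0L) return(TRUE)
  if (!all(ev$kind %in% .EVENT_KINDS))
    msg <- c(msg, "unknown event kind")
  ok_fam <- ev$family %in% c(.STIM_FAMILIES, .LIGAND_FAMILIES, "capsaicin")
  if (!all(ok_fam))
    msg <- c(msg, paste("unknown family:",
                        paste(unique(ev$family[!ok_fam]), collapse = ", ")))
  if (is.unsorted(ev$onset_s)) msg <- c(msg, "event onsets must be non-decreasing")
  grid_fam <- ev$family %in% .GRID_FAMILIES
  has_grid <- !is.na(ev$grid_row) & !is.na(ev$grid_col)
  if (any(grid_fam & !has_grid))
    msg <- c(msg, "static filament events require grid_row and grid_col")
  if (any(!grid_fam & has_grid))
    msg <- c(msg, "grid coordinates are only allowed on static filament events")
  if (any(has_grid & (ev$grid_row < 0 | ev$grid_row > 3 |
                      ev$grid_col < 0 | ev$grid_col > 3)))
    msg <- c(msg, "grid coordinates must lie in 0..3")
  if (any(ev$trial_index < 0)) msg <- c(msg, "trial_index must be >= 0")
  if (!all(ev$block %in% c("pre", "post", "ligand")))
    msg <- c(msg, "block must be one of pre/post/ligand")
  if (length(msg)) msg else TRUE
})

#' Construct an EventTimeline
#'
#' @param events data.frame/DataFrame of events; missing optional columns
#'   (`grid_row`, `grid_col`, `duration_s`, `trial_index`, `block`) are
#'   filled with defaults. Rows are sorted by onset.
#' @return an [EventTimeline-class] object.
#' @export
EventTimeline <- function(events = NULL) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    ev <- DataFrame(kind = character(), family = character(),
                    onset_s = numeric(), duration_s = numeric(),
                    grid_row = integer(), grid_col = integer(),
                    trial_index = integer(), block = character())
    return(new("EventTimeline", events = ev))
  }
  ev <- DataFrame(events)
  if (!"kind" %in% colnames(ev))
    ev$kind <- ifelse(ev$family %in% .LIGAND_FAMILIES, "ligand",
                      ifelse(ev$family == "capsaicin", "injection", "stimulus"))
  if (!"duration_s" %in% colnames(ev)) ev$duration_s <- 1
  if (!"grid_row" %in% colnames(ev)) ev$grid_row <- NA_integer_
  if (!"grid_col" %in% colnames(ev)) ev$grid_col <- NA_integer_
  if (!"trial_index" %in% colnames(ev)) ev$trial_index <- 0L
  if (!"block" %in% colnames(ev)) ev$block <- "pre"
  ev$grid_row <- as.integer(ev$grid_row)
  ev$grid_col <- as.integer(ev$grid_col)
  ev$trial_index <- as.integer(ev$trial_index)
  ev <- ev[order(ev$onset_s), .EVENT_COLS]
  rownames(ev) <- NULL
  new("EventTimeline", events = ev)
}

#' Ground truth of a synthetic experiment
#'
#' Records every generative parameter of a simulated recording so that
#' downstream stages can be tested for parameter recovery: per-cell response
#' amplitudes, receptive-field membership per block, ligand receptor
#' profile, sensitization effects, and the true peak amplitude injected at
#' every (cell, event) pair.
#'
#' @slot cells per-cell generative parameters (`DataFrame`).
#' @slot eventAmps cells x events matrix of true injected peak amplitudes
#'   (dF/F units); 0 means the cell does not respond to that event.
#' @slot rf list per cell with integer site indices (1..16, row-major) of
#'   the true receptive field in the `pre` and `post` blocks.
#' @slot meta list of generator settings (kernel parameters, blind interval,
#'   injection site, seed).
#' @export
setClass("GroundTruth", representation(
  cells = "DataFrame", eventAmps = "matrix", rf = "list", meta = "list"))

#' Estimated tissue-surface map of a structural volume
#'
#' Per-column (10x10-pixel by default) estimates of the z position of the
#' dorsal grey-matter surface, in micrometres from the top of the volume,
#' with a plateau-to-background contrast quality score per column.
#'
#' @slot z matrix of surface z estimates (um); `NA` where the column had no
#'   usable contrast.
#' @slot quality matrix of contrast scores, same shape as `z`.
#' @slot zStepUm z step of the source volume in um.
#' @slot colPx XY size in pixels of each column.
#' @export
setClass("SurfaceMap", representation(
  z = "matrix", quality = "matrix", zStepUm = "numeric", colPx = "numeric"))

setValidity("SurfaceMap", function(object) {
  if (!identical(dim(object@z), dim(object@quality)))
    return("z and quality must have identical dimensions")
  if (object@zStepUm <= 0) return("zStepUm must be positive")
  TRUE
})

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet:", nrow(object), "cells x", ncol(object), "frames @",
      metadata(object)$frame_rate_hz, "Hz\n")
  if (ncol(rowData(object)))
    cat("  ROI columns:", paste(colnames(rowData(object)), collapse = ", "),
        "\n")
})

setMethod("show", "DffSet", function(object) {
  keep <- sum(rowData(object)$qc_keep)
  cat("DffSet:", nrow(object), "cells x", ncol(object), "frames;",
      keep, "passed drift QC\n")
})

setMethod("show", "EventTimeline", function(object) {
  ev <- object@events
  cat("EventTimeline:", nrow(ev), "events")
  if (nrow(ev))
    cat(" spanning [", min(ev$onset_s), ",", max(ev$onset_s + ev$duration_s),
        "] s;", length(unique(ev$family)), "families")
  cat("\n")
})

setMethod("show", "SurfaceMap", function(object) {
  cat("SurfaceMap:", nrow(object@z), "x", ncol(object@z), "columns (",
      object@colPx, "px each ), z step", object@zStepUm, "um;",
      sum(is.na(object@z)), "missing\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cells), "cells,", ncol(object@eventAmps),
      "events\n")
})
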