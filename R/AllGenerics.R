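#' Accessors for CicadaDH classes
#'
#' `fluor()` returns the raw fluorescence matrix of a [TraceSet-class];
#' `dff()` and `baselineFluor()` the dF/F and baseline matrices of a
#' [DffSet-class]; `frameRate()` the frame rate in Hz; `cellIds()` the cell
#' identifiers; `events()` the event table of an [EventTimeline-class] as a
#' `DataFrame`; `qcKeep()` the per-cell drift-QC verdict.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fluor", function(x) standardGeneric("fluor"))
#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
#' @rdname accessors
#' @export
setGeneric("baselineFluor", function(x) standardGeneric("baselineFluor"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("qcKeep", function(x) standardGeneric("qcKeep"))

#' @rdname accessors
#' @export
setMethod("fluor", "TraceSet", function(x) assay(x, "fluor"))
#' @rdname accessors
#' @export
setMethod("dff", "DffSet", function(x) assay(x, "dff"))
#' @rdname accessors
#' @export
setMethod("baselineFluor", "DffSet", function(x) assay(x, "baseline"))
#' @rdname accessors
#' @export
setMethod("frameRate", "SummarizedExperiment",
          function(x) metadata(x)$frame_rate_hz)
#' @rdname accessors
#' @export
setMethod("cellIds", "SummarizedExperiment", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("events", "EventTimeline", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("qcKeep", "DffSet", function(x) {
  k <- rowData(x)$qc_keep
  names(k) <- rownames(x)
  k
})

#' Number of events in a timeline
#' @param x an [EventTimeline-class].
#' @return integer count.
#' @export
nEvents <- function(x) nrow(events(x))

#' Subset a timeline by family, block or kind
#'
#' @param x an [EventTimeline-class].
#' @param family,block,kind optional character vectors to keep.
#' @return an [EventTimeline-class] with the matching events.
#' @export
filterEvents <- function(x, family = NULL, block = NULL, kind = NULL) {
  ev <- events(x)
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(family)) keep <- keep & ev$family %in% family
  if (!is.null(block))  keep <- keep & ev$block %in% block
  if (!is.null(kind))   keep <- keep & ev$kind %in% kind
  EventTimeline(ev[keep, , drop = FALSE])
}
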