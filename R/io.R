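#' Read raw traces from a wide CSV
#'
#' Expects a header `cell_id,f0,f1,...` with one row per cell. Ragged rows
#' raise a format error; non-numeric cells raise a parse error naming the
#' offending cell and frame.
#'
#' @param path CSV file.
#' @param frameRate frames per second (the container stores no rate).
#' @param roi optional ROI table to attach (see [TraceSet()]).
#' @return a [TraceSet-class].
#' @export
readTraces <- function(path, frameRate = 1.0, roi = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!"cell_id" %in% names(raw) || ncol(raw) < 2L)
    stop("format error: expected header cell_id,f0,f1,...")
  ids <- raw$cell_id
  mat <- as.matrix(raw[setdiff(names(raw), "cell_id")])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  bad <- which(is.na(num) & !(is.na(mat) | mat %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error: non-numeric value for cell '", ids[bad[1, 1]],
         "' at frame ", bad[1, 2], " (row ", bad[1, 1] + 1L, ")")
  empty <- which(is.na(mat) | mat == "", arr.ind = TRUE)
  if (nrow(empty) && !all(mat[empty] %in% "NA"))
    stop("parse error: missing value for cell '", ids[empty[1, 1]],
         "' at frame ", empty[1, 2], " (row ", empty[1, 1] + 1L, ")")
  TraceSet(num, cellIds = ids, frameRate = frameRate, roi = roi)
}

#' Write raw traces to a wide CSV
#'
#' Inverse of [readTraces()]: full-precision round trip.
#'
#' @param traces a [TraceSet-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path) {
  f <- fluor(traces)
  df <- data.frame(cell_id = rownames(f),
                   format(f, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("cell_id", paste0("f", seq_len(ncol(f)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event timeline from JSON
#'
#' Expects a JSON array of event objects (`family`, `onset_s`, and
#' optionally `kind`, `duration_s`, `grid_row`, `grid_col`, `trial_index`,
#' `block`). Schema violations (unknown family, grid coordinates on a
#' non-static event, missing grid on a static event) are rejected by the
#' timeline validity checks.
#'
#' @param path JSON file.
#' @return an [EventTimeline-class].
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(arr) == 0L) return(EventTimeline())
  if (!is.data.frame(arr)) stop("schema error: expected a JSON array of event objects")
  tryCatch(EventTimeline(arr),
           error = function(e) stop("schema error: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write an event timeline to JSON
#' @param timeline an [EventTimeline-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(timeline, path) {
  df <- as.data.frame(events(timeline))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an ROI table from CSV
#' @param path CSV with columns `cell_id`, `x_px`, `y_px`, `plane_index`,
#'   `is_spbn` and optionally `depth_um`.
#' @return a `DataFrame`.
#' @export
readRoiTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("cell_id", "x_px", "y_px", "plane_index", "is_spbn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: ROI table lacks column(s) ",
         paste(miss, collapse = ", "))
  DataFrame(df)
}

#' Write pipeline results to an output directory
#'
#' Writes the standard result tables (`responses.csv`, `tuning.csv`,
#' `rf.csv`, `clusters.csv`) and a machine-readable `report.json` carrying
#' the configuration echo, the package version, the seed and the summary
#' sections of the results. Returns a manifest of the files written with
#' their MD5 checksums; identical inputs produce identical checksums.
#'
#' @param results a pipeline result list (see [runPipeline()]); must
#'   contain `responses`, `tuning`, `rf`, `clusters` data.frames (possibly
#'   empty) and a `report` list.
#' @param outDir output directory (created if needed).
#' @return data.frame manifest with `file` and `md5`.
#' @export
writeReport <- function(results, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("I/O error: cannot write to directory ", outDir)
  tables <- c("responses", "tuning", "rf", "clusters")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(outDir, paste0(tb, ".csv"))
    df <- results[[tb]]
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "report.json")
  jsonlite::write_json(results$report, p, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
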