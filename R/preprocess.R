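#' @useDynLib CicadaDH, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Rolling-percentile baseline of a fluorescence trace
#'
#' For every frame, the baseline is a low percentile (30th by default) of
#' the raw fluorescence in a window of `windowS` seconds centered on that
#' frame. Windows shrink at the recording edges rather than padding, so no
#' data are fabricated at the start or end of a multi-hour recording. A low
#' percentile tracks slow photobleaching and focal drift while staying
#' below stimulus-evoked transients, which occupy a minority of frames.
#' Percentiles interpolate linearly between order statistics
#' (`stats::quantile` type 7); `NA` frames (masked intervals) are excluded
#' from the window.
#'
#' @param trace numeric vector, raw fluorescence of one cell.
#' @param windowS window width in seconds (default 300 = 5 min).
#' @param percentile percentile in (0, 100) (default 30).
#' @param frameRate frames per second.
#' @return numeric vector of the same length: the baseline F_b.
#' @export
rollingBaseline <- function(trace, windowS = 300, percentile = 30,
                            frameRate = 1.0) {
  if (windowS <= 0) stop("configuration error: windowS must be positive")
  if (percentile <= 0 || percentile >= 100)
    stop("configuration error: percentile must be in (0, 100)")
  if (length(trace) < 2L) stop("trace must have at least 2 frames")
  half <- floor(round(windowS * frameRate) / 2)
  .run_percentile_cpp(as.numeric(trace), as.integer(half), percentile / 100)
}

#' Fractional fluorescence change
#'
#' Element-wise `(F - F_b) / F_b`, the dF/F transform against a
#' pre-computed baseline. 1.0 corresponds to a 100% increase over baseline.
#'
#' @param trace raw fluorescence vector F.
#' @param baseline baseline vector F_b, strictly positive wherever `trace`
#'   is non-missing.
#' @return dF/F vector; `NA` where `trace` is `NA`.
#' @export
computeDff <- function(trace, baseline) {
  if (length(trace) != length(baseline))
    stop("trace and baseline lengths differ")
  bad <- which(!is.na(trace) & (is.na(baseline) | baseline <= 0))
  if (length(bad))
    stop("numeric error: baseline is not positive at frame ", bad[1])
  (trace - baseline) / baseline
}

#' Drift quality control on a raw trace
#'
#' The recording is cut into consecutive bins (5 min by default) and the
#' median raw fluorescence of each bin is computed. Under the default
#' `"ratio"` rule a cell is discarded when the spread of binned medians
#' exceeds the drift limit: `max/min - 1 > limit` (limit 2.0, i.e. a >200%
#' increase from the dimmest to the brightest epoch), a signature of
#' physical drift or Ca2+ dysregulation. The `"first_bin"` rule instead
#' discards when any bin deviates from the first bin by more than the
#' limit.
#'
#' @param trace raw fluorescence vector.
#' @param binS bin width in seconds.
#' @param limit allowed fractional drift.
#' @param frameRate frames per second.
#' @param mode `"ratio"` or `"first_bin"`.
#' @return list with `keep` (logical) and `reason` (character; records the
#'   offending ratio when discarded).
#' @export
driftQC <- function(trace, binS = 300, limit = 2.0, frameRate = 1.0,
                    mode = c("ratio", "first_bin")) {
  mode <- match.arg(mode)
  if (binS <= 0 || limit <= 0) stop("configuration error: binS and limit must be positive")
  binFrames <- max(1L, round(binS * frameRate))
  n <- length(trace)
  if (n < 2L * binFrames) stop("trace must span at least 2 drift bins")
  bin <- (seq_len(n) - 1L) %/% binFrames
  # drop a trailing fragment shorter than half a bin to keep medians stable
  full <- bin < (n %/% binFrames) | (n %% binFrames) >= binFrames / 2
  med <- tapply(trace[full], bin[full], stats::median, na.rm = TRUE)
  med <- med[!is.na(med)]
  if (any(med <= 0)) stop("numeric error: non-positive binned median fluorescence")
  if (mode == "ratio") {
    ratio <- max(med) / min(med)
    if (ratio - 1 > limit)
      list(keep = FALSE,
           reason = sprintf("drift %.0f%% exceeds %.0f%% (max/min binned median %.2f)",
                            100 * (ratio - 1), 100 * limit, ratio))
    else list(keep = TRUE, reason = "ok")
  } else {
    dev <- max(abs(med / med[1] - 1))
    if (dev > limit)
      list(keep = FALSE,
           reason = sprintf("drift %.0f%% from first bin exceeds %.0f%%",
                            100 * dev, 100 * limit))
    else list(keep = TRUE, reason = "ok")
  }
}

#' Baseline, dF/F and drift QC for a whole recording
#'
#' Applies [rollingBaseline()], [computeDff()] and [driftQC()] to every
#' cell of a [TraceSet-class].
#'
#' @param traces a [TraceSet-class].
#' @param config a [CicadaConfig-class].
#' @return a [DffSet-class] with assays `dff` and `baseline` and rowData
#'   columns `qc_keep`, `qc_reason`.
#' @export
preprocessTraces <- function(traces, config = cicadaConfig()) {
  f <- fluor(traces)
  fr <- frameRate(traces)
  base <- t(apply(f, 1L, rollingBaseline, windowS = config@baselineWindowS,
                  percentile = config@baselinePercentile, frameRate = fr))
  d <- (f - base) / base
  d[is.na(base) | base <= 0] <- NA_real_  # undefined where no baseline exists
  qc <- apply(f, 1L, function(tr)
    driftQC(tr, binS = config@driftBinS, limit = config@driftLimit,
            frameRate = fr, mode = config@driftMode))
  rd <- rowData(traces)
  rd$qc_keep <- vapply(qc, `[[`, logical(1), "keep")
  rd$qc_reason <- vapply(qc, `[[`, character(1), "reason")
  dimnames(base) <- dimnames(d) <- dimnames(f)
  se <- SummarizedExperiment(
    assays = SimpleList(dff = d, baseline = base), rowData = rd,
    metadata = list(frame_rate_hz = fr, config = configAsList(config)))
  new("DffSet", se)
}
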