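# Frame arithmetic: time t seconds -> 1-based frame index round(t * fr) + 1;
# all windows are half-open [t0, t1).
.windowFrames <- function(t0, t1, frameRate, nFrames = NULL, clip = FALSE) {
  i0 <- round(t0 * frameRate) + 1L
  i1 <- round(t1 * frameRate)          # last frame strictly before t1
  if (clip && !is.null(nFrames)) {
    i0 <- max(1L, i0)
    i1 <- min(nFrames, i1)
  }
  if (!is.null(nFrames) && !clip && (i0 < 1L || i1 > nFrames))
    stop("range error: window [", t0, ", ", t1, ") s lies outside the recording")
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

.rowMaxNA <- function(m) {
  p <- apply(m, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  as.numeric(p)
}

.rowSdNA <- function(m) {
  apply(m, 1L, stats::sd, na.rm = TRUE)
}

#' Stimulus-evoked response call for one cell and one event
#'
#' A cell is a responder to an event when the peak dF/F inside the response
#' window exceeds both the absolute amplitude threshold (1.25 dF/F, i.e.
#' 125%) and `sigmaMult` (6) times the SD of the dF/F trace in the
#' `noiseWindowS` (30 s) immediately preceding the event. Frames listed in
#' `maskFrames` (typically the response windows of other events, which
#' contain real signal) are excluded from the noise estimate; if fewer than
#' 3 noise frames survive masking the full pre-event window is used.
#'
#' @param dffTrace dF/F vector for one cell.
#' @param onsetS event onset in seconds.
#' @param windowS response window length (s).
#' @param noiseWindowS pre-event noise window length (s).
#' @param ampThreshold amplitude threshold (dF/F).
#' @param sigmaMult noise multiplier.
#' @param frameRate frames per second.
#' @param maskFrames optional integer frames to exclude from the noise SD.
#' @return list with `peak_amp`, `noise_sigma`, `responder`.
#' @export
detectResponse <- function(dffTrace, onsetS, windowS = 5, noiseWindowS = 30,
                           ampThreshold = 1.25, sigmaMult = 6,
                           frameRate = 1.0, maskFrames = NULL) {
  n <- length(dffTrace)
  rf <- .windowFrames(onsetS, onsetS + windowS, frameRate, n)
  nf <- .windowFrames(onsetS - noiseWindowS, onsetS, frameRate, n)
  if (!is.null(maskFrames)) {
    kept <- setdiff(nf, maskFrames)
    if (length(kept) >= 3L) nf <- kept
  }
  peak <- if (all(is.na(dffTrace[rf]))) NA_real_ else max(dffTrace[rf], na.rm = TRUE)
  sigma <- stats::sd(dffTrace[nf], na.rm = TRUE)
  list(peak_amp = peak, noise_sigma = sigma,
       responder = isTRUE(peak > ampThreshold && peak > sigmaMult * sigma))
}

#' Ligand-evoked response call
#'
#' Identical amplitude and sigma criteria to [detectResponse()] but with a
#' wide response window (120 s by default) to accommodate the slower and
#' more variable onset of bath-applied GPCR-agonist responses.
#'
#' @inheritParams detectResponse
#' @export
detectLigandResponse <- function(dffTrace, onsetS, windowS = 120,
                                 noiseWindowS = 30, ampThreshold = 1.25,
                                 sigmaMult = 6, frameRate = 1.0,
                                 maskFrames = NULL) {
  detectResponse(dffTrace, onsetS, windowS = windowS,
                 noiseWindowS = noiseWindowS, ampThreshold = ampThreshold,
                 sigmaMult = sigmaMult, frameRate = frameRate,
                 maskFrames = maskFrames)
}

#' Response calls for every cell and every event of a recording
#'
#' Vectorized application of the responder rule across a [DffSet-class] and
#' an [EventTimeline-class]. Stimulus events use the short response window,
#' ligand events the 120 s window. The noise SD for each event is computed
#' on pre-event frames outside every event's response window. Cells that
#' failed drift QC are skipped.
#'
#' @param dffset a [DffSet-class].
#' @param timeline an [EventTimeline-class].
#' @param config a [CicadaConfig-class].
#' @return data.frame with one row per (kept cell, non-injection event):
#'   `cell_id`, `event_index`, `kind`, `family`, `block`, `trial_index`,
#'   `grid_row`, `grid_col`, `onset_s`, `peak_amp`, `noise_sigma`,
#'   `responder`.
#' @export
detectResponses <- function(dffset, timeline, config = cicadaConfig()) {
  ev <- as.data.frame(events(timeline))
  ev$event_index <- seq_len(nrow(ev))
  ev <- ev[ev$kind != "injection", , drop = FALSE]
  d <- dff(dffset)[qcKeep(dffset), , drop = FALSE]
  if (nrow(ev) == 0L || nrow(d) == 0L)
    return(data.frame(cell_id = character(), event_index = integer(),
                      kind = character(), family = character(),
                      block = character(), trial_index = integer(),
                      grid_row = integer(), grid_col = integer(),
                      onset_s = numeric(), peak_amp = numeric(),
                      noise_sigma = numeric(), responder = logical()))
  fr <- frameRate(dffset)
  n <- ncol(d)
  win <- ifelse(ev$kind == "ligand", config@ligandWindowS,
                config@responseWindowS)
  # global mask of frames inside any response window (they contain signal)
  mask <- sort(unique(unlist(mapply(
    function(o, w) .windowFrames(o, o + w, fr, n, clip = TRUE),
    ev$onset_s, win, SIMPLIFY = FALSE))))
  out <- vector("list", nrow(ev))
  for (j in seq_len(nrow(ev))) {
    rf <- .windowFrames(ev$onset_s[j], ev$onset_s[j] + win[j], fr, n)
    nf <- .windowFrames(ev$onset_s[j] - config@noiseWindowS, ev$onset_s[j],
                        fr, n)
    kept <- setdiff(nf, mask)
    if (length(kept) >= 3L) nf <- kept
    peak <- .rowMaxNA(d[, rf, drop = FALSE])
    sigma <- .rowSdNA(d[, nf, drop = FALSE])
    out[[j]] <- data.frame(
      cell_id = rownames(d), event_index = ev$event_index[j],
      kind = ev$kind[j], family = ev$family[j], block = ev$block[j],
      trial_index = ev$trial_index[j], grid_row = ev$grid_row[j],
      grid_col = ev$grid_col[j], onset_s = ev$onset_s[j],
      peak_amp = peak, noise_sigma = sigma,
      responder = !is.na(peak) & peak > config@ampThreshold &
        peak > config@sigmaMult * sigma,
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Family-level responder assignment
#'
#' Collapses per-trial calls to one verdict per (cell, family, block):
#' brush and airpuff require at least 2 of 3 applications; heat, cold and
#' the static filament families require at least 1 (their individual
#' applications differ in ramp parameters or skin site, so trials are not
#' equivalent repetitions).
#'
#' @param calls the data.frame from [detectResponses()].
#' @return data.frame with `cell_id`, `family`, `block`, `n_trials`,
#'   `n_responses`, `max_peak`, `responder`.
#' @export
assignFamilyResponse <- function(calls) {
  calls <- calls[calls$family %in% .STIM_FAMILIES, , drop = FALSE]
  if (nrow(calls) == 0L) stop("assignment error: no stimulus-family trials present")
  key <- interaction(calls$cell_id, calls$family, calls$block, drop = TRUE)
  agg <- do.call(rbind, lapply(split(calls, key), function(g) {
    need2 <- g$family[1] %in% c("brush", "airpuff")
    data.frame(cell_id = g$cell_id[1], family = g$family[1],
               block = g$block[1], n_trials = nrow(g),
               n_responses = sum(g$responder),
               max_peak = max(g$peak_amp, na.rm = TRUE),
               responder = sum(g$responder) >= if (need2) 2L else 1L,
               row.names = NULL)
  }))
  rownames(agg) <- NULL
  agg[order(agg$cell_id, agg$family, agg$block), ]
}

#' Capsaicin responder classification
#'
#' A cell responds to the capsaicin injection when its mean dF/F over a
#' 2-minute window after the injection exceeds `factor` (1.5, i.e. 150%)
#' times the mean over the 2-minute window before it. Both windows exclude
#' the blind interval around the injection (imaging is interrupted while
#' the needle is placed): the pre window ends at `injection - blindS` and
#' the post window starts at `injection + blindS`. Cells whose pre-window
#' mean is at or below a small floor (1e-6) cannot yield a meaningful
#' ratio and are flagged indeterminate, not responders.
#'
#' @param dffset a [DffSet-class] (or a numeric matrix of dF/F).
#' @param injectionS injection time in seconds.
#' @param config a [CicadaConfig-class].
#' @return data.frame with `cell_id`, `pre_mean`, `post_mean`, `ratio`,
#'   `responder`, `indeterminate`.
#' @export
capsaicinResponder <- function(dffset, injectionS, config = cicadaConfig()) {
  d <- if (is.matrix(dffset)) dffset else dff(dffset)[qcKeep(dffset), , drop = FALSE]
  fr <- if (is.matrix(dffset)) 1.0 else frameRate(dffset)
  W <- config@capsaicinWindowS
  b <- config@capsaicinBlindS
  n <- ncol(d)
  preF <- .windowFrames(injectionS - b - W, injectionS - b, fr, n)
  postF <- .windowFrames(injectionS + b, injectionS + b + W, fr, n)
  pre <- rowMeans(d[, preF, drop = FALSE], na.rm = TRUE)
  post <- rowMeans(d[, postF, drop = FALSE], na.rm = TRUE)
  indet <- !is.finite(pre) | pre <= 1e-6
  ratio <- ifelse(indet, NA_real_, post / pre)
  data.frame(cell_id = rownames(d), pre_mean = pre, post_mean = post,
             ratio = ratio,
             responder = !indet & !is.na(ratio) & ratio > config@capsaicinFactor,
             indeterminate = indet, row.names = NULL)
}
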