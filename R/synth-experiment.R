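#' Fluorescence impulse-response kernel
#'
#' Difference-of-exponentials stand-in for slow genetically encoded
#' calcium-indicator kinetics, sampled at the frame grid and normalized so
#' that the sampled maximum is exactly 1: an event of amplitude A then
#' produces a sampled peak of exactly A dF/F. The continuous-time argmax
#' is `log(decay/rise) / (1/rise - 1/decay)`.
#'
#' @param riseTauS rise time constant (s).
#' @param decayTauS decay time constant (s).
#' @param frameRate frames per second.
#' @return numeric vector of kernel samples at frame offsets 0, 1, ...
#'   until the tail falls below 1e-4 of the peak.
#' @export
calciumKernel <- function(riseTauS = 0.2, decayTauS = 1.5, frameRate = 1.0) {
  stopifnot(riseTauS > 0, decayTauS > riseTauS)
  tMax <- -decayTauS * log(1e-4)
  tt <- seq(0, tMax, by = 1 / frameRate)
  k <- exp(-tt / decayTauS) - exp(-tt / riseTauS)
  k / max(k)
}

#' Kernel parameters of the generator
#'
#' @param riseTauS,decayTauS stimulus-kernel time constants (s).
#' @param ligandRiseTauS,ligandDecayTauS ligand-kernel time constants (s),
#'   slower to mimic bath-application pharmacokinetics.
#' @param capsaicinDecayTauS decay (s) of the sustained capsaicin surge.
#' @param ligandLatencyMaxS per-(cell, ligand) uniform onset latency bound
#'   (s), modelling drug-penetration variability.
#' @param noiseSd additive Gaussian noise SD in dF/F units.
#' @param bleachFraction fluorescence fraction lost per hour to
#'   photobleaching (multiplicative exponential on raw F).
#' @param baselineF resting raw fluorescence (arbitrary units).
#' @param spontRateHz per-cell Poisson rate of spontaneous transients.
#' @param spontAmpRange amplitude range of spontaneous transients (dF/F).
#' @param oscAmp peak amplitude (dF/F) of slow rhythmic "up-state" bursts
#'   of ongoing activity (half-wave-rectified squared sinusoid, so the cell
#'   is quiet half the time and bursts smoothly in between). Dorsal-horn
#'   networks show slow rhythmic population activity; this skewed ongoing
#'   drive leaves the low-percentile baseline at the quiet level while
#'   giving every cell the stable positive activity floor that ratio-based
#'   measures such as the capsaicin-responder rule implicitly assume.
#' @param oscPeriodRange per-cell uniform range (s) of the burst period.
#' @return validated list of class `KernelParams`.
#' @export
kernelParams <- function(riseTauS = 0.2, decayTauS = 1.5,
                         ligandRiseTauS = 10, ligandDecayTauS = 40,
                         capsaicinDecayTauS = 180, ligandLatencyMaxS = 60,
                         noiseSd = 0.05, bleachFraction = 0.10,
                         baselineF = 100, spontRateHz = 0.05,
                         spontAmpRange = c(0.03, 0.09),
                         oscAmp = 0.15, oscPeriodRange = c(20, 40)) {
  stopifnot(riseTauS > 0, decayTauS > 0, ligandRiseTauS > 0,
            ligandDecayTauS > 0, noiseSd >= 0,
            bleachFraction >= 0, bleachFraction < 1, baselineF > 0,
            spontRateHz >= 0, oscAmp >= 0)
  structure(as.list(environment()), class = "KernelParams")
}

# true injected peak amplitude for every (cell, event); 0 = no response
.eventAmplitudes <- function(cells, ev, rfList) {
  n <- nrow(cells)
  amps <- matrix(0, n, nrow(ev))
  for (j in seq_len(nrow(ev))) {
    fam <- ev$family[j]
    blk <- ev$block[j]
    a <- switch(fam,
      brush = cells$amp_brush,
      airpuff = cells$amp_airpuff,
      heat = cells$amp_heat,
      cold = cells$amp_cold,
      static_LT = {
        site <- 4L * ev$grid_row[j] + ev$grid_col[j] + 1L
        inRF <- vapply(seq_len(n), function(i)
          site %in% (if (blk == "post") rfList[[i]]$post else
                       rfList[[i]]$pre), logical(1))
        gain <- if (blk == "post") cells$lt_gain else rep(1, n)
        cells$amp_lt * gain * inRF
      },
      static_HT = {
        site <- 4L * ev$grid_row[j] + ev$grid_col[j] + 1L
        inRF <- vapply(seq_len(n), function(i)
          site %in% rfList[[i]]$pre, logical(1))
        cells$amp_ht * inRF
      },
      capsaicin = cells$cap_amp,
      cells$ligands[, fam]   # one of the 8 CICADA ligands
    )
    amps[, j] <- a
  }
  rownames(amps) <- cells$cell_id
  amps
}

#' Simulate a full synthetic experiment with known ground truth
#'
#' Generates raw fluorescence traces for a cell population under a
#' stimulation protocol:
#' `F(t) = baselineF * (1 + dFF_true(t) + noise(t)) * bleach(t)`, where
#' `dFF_true` is the sum over events of the cell's true amplitude times
#' the sampled indicator kernel (slow kernel plus onset latency for
#' ligands, sustained slow-decay surge for directly capsaicin-driven
#' cells, plus low-rate spontaneous transients), `noise` is white Gaussian
#' in dF/F units and `bleach` is a multiplicative exponential decay.
#' Static filament events drive a cell only when the probed site lies
#' inside its (possibly expanded, post block) receptive field;
#' post-block low-threshold amplitudes carry the cell's `lt_gain`.
#' An approximately 60 s blind interval around the capsaicin injection is
#' masked as `NA` frames, emulating the imaging interruption.
#'
#' The ROI table places cells somatotopically: the medio-lateral (x)
#' position is anti-correlated with the receptive-field column (distal
#' skin maps medially), so locus inference has real structure to recover.
#'
#' @param nCells number of cells (>= 1).
#' @param protocol result of [buildProtocol()] (or a compatible list).
#' @param cells per-cell parameters from [cellPopulation()]; generated
#'   with `seed` when `NULL`.
#' @param kernel a [kernelParams()] list.
#' @param frameRate frames per second.
#' @param seed random seed for the trace noise (and the population when
#'   `cells` is `NULL`).
#' @return list with `traces` ([TraceSet-class]), `timeline`
#'   ([EventTimeline-class]), `roi` (`DataFrame`), `truth`
#'   ([GroundTruth-class]) and `injection_s`.
#' @export
simulateExperiment <- function(nCells = 100, protocol = buildProtocol(),
                               cells = NULL, kernel = kernelParams(),
                               frameRate = 1.0, seed = 1) {
  stopifnot(nCells >= 1)
  if (is.null(cells)) cells <- cellPopulation(nCells, seed = seed)
  nCells <- nrow(cells)
  ev <- as.data.frame(events(protocol$timeline))
  nFrames <- ceiling(protocol$duration_s * frameRate)
  if (max(ev$onset_s + ev$duration_s) > nFrames / frameRate)
    stop("configuration error: protocol is longer than the recording")
  set.seed(seed + 1L)
  rfList <- lapply(seq_len(nCells), function(i) list(
    pre = .rfSites(cells$rf_row[i], cells$rf_col[i], cells$rf_radius[i]),
    post = .rfSitesPost(cells$rf_row[i], cells$rf_col[i],
                        cells$rf_radius[i], cells$rf_expansion[i])))
  amps <- .eventAmplitudes(cells, ev, rfList)

  kStim <- calciumKernel(kernel$riseTauS, kernel$decayTauS, frameRate)
  kLig <- calciumKernel(kernel$ligandRiseTauS, kernel$ligandDecayTauS,
                        frameRate)
  kCap <- calciumKernel(kernel$ligandRiseTauS, kernel$capsaicinDecayTauS,
                        frameRate)
  addKernel <- function(trace, frame0, amp, kern) {
    if (amp <= 0 || frame0 > length(trace)) return(trace)
    idx <- frame0:min(length(trace), frame0 + length(kern) - 1L)
    trace[idx] <- trace[idx] + amp * kern[seq_along(idx)]
    trace
  }
  dffTrue <- matrix(0, nCells, nFrames)
  for (i in seq_len(nCells)) {
    tr <- numeric(nFrames)
    for (j in seq_len(nrow(ev))) {
      a <- amps[i, j]
      if (a <= 0) next
      lat <- 0
      kern <- kStim
      if (ev$kind[j] == "ligand") {
        kern <- kLig
        lat <- stats::runif(1, 0, kernel$ligandLatencyMaxS)
      } else if (ev$kind[j] == "injection") kern <- kCap
      f0 <- round((ev$onset_s[j] + lat) * frameRate) + 1L
      tr <- addKernel(tr, f0, a, kern)
    }
    nSp <- stats::rpois(1, kernel$spontRateHz * nFrames / frameRate)
    if (nSp > 0) {
      spOn <- stats::runif(nSp, 0, nFrames / frameRate)
      spAmp <- stats::runif(nSp, kernel$spontAmpRange[1],
                            kernel$spontAmpRange[2])
      for (s in seq_len(nSp))
        tr <- addKernel(tr, round(spOn[s] * frameRate) + 1L, spAmp[s], kStim)
    }
    if (kernel$oscAmp > 0) {
      period <- stats::runif(1, kernel$oscPeriodRange[1],
                             kernel$oscPeriodRange[2])
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(nFrames) - 1L) / frameRate
      tr <- tr + kernel$oscAmp *
        pmax(0, sin(2 * pi * tt / period + phase))^2
    }
    dffTrue[i, ] <- tr
  }
  noise <- matrix(stats::rnorm(nCells * nFrames, 0, kernel$noiseSd),
                  nCells, nFrames)
  tSec <- (seq_len(nFrames) - 1L) / frameRate
  bleach <- exp(log(1 - kernel$bleachFraction) * tSec / 3600)
  f <- kernel$baselineF * pmax(0, 1 + dffTrue + noise) *
    matrix(bleach, nCells, nFrames, byrow = TRUE)

  blind <- c(NA_real_, NA_real_)
  if (!is.na(protocol$injection_s)) {
    blind <- protocol$injection_s + c(-30, 30)
    bf <- .windowFrames(blind[1], blind[2], frameRate, nFrames, clip = TRUE)
    f[, bf] <- NA_real_
  }

  xNoise <- stats::rnorm(nCells, 0, 25)
  roi <- DataFrame(
    cell_id = cells$cell_id,
    x_px = pmin(511, pmax(1, 60 + (3 - cells$rf_col) * 120 + xNoise)),
    y_px = stats::runif(nCells, 1, 213),
    plane_index = pmin(2L, pmax(0L, as.integer(cells$depth_um %/% 20))),
    is_spbn = cells$is_spbn)
  traces <- TraceSet(f, cellIds = cells$cell_id, frameRate = frameRate,
                     roi = roi)
  truth <- new("GroundTruth", cells = cells, eventAmps = amps, rf = rfList,
               meta = list(kernel = kernel, blind_s = blind,
                           injection_s = protocol$injection_s, seed = seed,
                           frame_rate_hz = frameRate))
  list(traces = traces, timeline = protocol$timeline, roi = roi,
       truth = truth, injection_s = protocol$injection_s)
}

#' Noisy responder annotations from ground truth
#'
#' Emulates a manually annotated ground-truth set: for every (cell,
#' stimulus event) pair the true responder state (injected amplitude > 0)
#' is taken and flipped with probability `labelNoiseRate`, modelling
#' annotator error.
#'
#' @param truth a [GroundTruth-class].
#' @param timeline the matching [EventTimeline-class].
#' @param labelNoiseRate flip probability in [0, 1).
#' @param seed random seed.
#' @param kinds event kinds to annotate.
#' @return data.frame `cell_id`, `event_index`, `true_responder`, `label`.
#' @export
simulateAnnotations <- function(truth, timeline, labelNoiseRate = 0,
                                seed = 1, kinds = "stimulus") {
  stopifnot(labelNoiseRate >= 0, labelNoiseRate < 1)
  ev <- as.data.frame(events(timeline))
  keep <- which(ev$kind %in% kinds)
  amps <- truth@eventAmps[, keep, drop = FALSE]
  out <- data.frame(
    cell_id = rep(rownames(amps), times = length(keep)),
    event_index = rep(keep, each = nrow(amps)),
    true_responder = as.vector(amps > 0))
  set.seed(seed)
  flip <- stats::runif(nrow(out)) < labelNoiseRate
  out$label <- xor(out$true_responder, flip)
  out
}
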