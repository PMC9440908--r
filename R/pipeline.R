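#' Classify projection neurons into WDR / HT / LT functional types
#'
#' Spinoparabrachial projection neurons are conventionally divided by
#' their mechanical response profile. Using the pre-capsaicin
#' family-response table: a cell responsive to both a low-threshold
#' mechanical stimulus (brush or the 0.16 g filament) and the
#' high-threshold 2.0 g filament, whose HT peak is at least `wdrRatio`
#' times its best LT-class peak (i.e. it encodes intensity in its
#' amplitude), is wide-dynamic-range (WDR); a cell responsive to HT but
#' not to LT-class stimuli is HT; a cell responsive only to LT-class
#' stimuli is LT; anything else (e.g. thermal-only, or HT+LT without
#' amplitude coding) is unclassified.
#'
#' @param famResp family-response table from [assignFamilyResponse()]
#'   (pre block rows are used).
#' @param cellId cell to classify.
#' @param wdrRatio HT/LT peak ratio required for WDR.
#' @return one of `"WDR"`, `"HT"`, `"LT"`, `"unclassified"`.
#' @export
classifySpbn <- function(famResp, cellId, wdrRatio = 1.2) {
  fr <- famResp[famResp$cell_id == cellId & famResp$block == "pre", ]
  if (nrow(fr) == 0L) return("unclassified")
  respOf <- function(fams) {
    g <- fr[fr$family %in% fams, ]
    nrow(g) > 0L && any(g$responder)
  }
  peakOf <- function(fams) {
    g <- fr[fr$family %in% fams & fr$responder, ]
    if (nrow(g) == 0L) 0 else max(g$max_peak)
  }
  ltClass <- respOf(c("brush", "static_LT"))
  ht <- respOf("static_HT")
  if (ltClass && ht) {
    if (peakOf("static_HT") >= wdrRatio * peakOf(c("brush", "static_LT")))
      "WDR" else "unclassified"
  } else if (ht) "HT"
  else if (ltClass) "LT"
  else "unclassified"
}

#' Pre/post-capsaicin sensitization deltas
#'
#' Compares the pre- and post-capsaicin blocks analysed under one
#' configuration: per stimulus family the change in percent responders;
#' per cell the low-threshold receptive-field size change and fold-change
#' (fold only where the pre size is positive) and the mechanical tuning
#' shift toward the low-threshold basis axis (degrees of standardized
#' angle moved toward 210; positive = toward LT); aggregates by CICADA
#' cluster when labels are supplied.
#'
#' @param famResp family-response table covering both blocks.
#' @param rfPre,rfPost receptive-field tables ([rfTable()]) for the LT
#'   filament in each block.
#' @param tunPre,tunPost mechanical sub-modality tuning tables
#'   ([tuningTable()]) for each block.
#' @param clusters optional named cluster labels for aggregation.
#' @param config a [CicadaConfig-class].
#' @return list of class `SensitizationReport` with `family_deltas`,
#'   `cell_deltas`, `cluster_deltas` (when labels given).
#' @export
prePostDeltas <- function(famResp, rfPre, rfPost, tunPre, tunPost,
                          clusters = NULL, config = cicadaConfig()) {
  cellsPre <- unique(famResp$cell_id[famResp$block == "pre"])
  cellsPost <- unique(famResp$cell_id[famResp$block == "post"])
  if (!setequal(cellsPre, cellsPost))
    stop("alignment error: cell sets differ between blocks; missing: ",
         paste(head(c(setdiff(cellsPre, cellsPost),
                      setdiff(cellsPost, cellsPre)), 5), collapse = ", "))
  fams <- sort(unique(famResp$family))
  famDeltas <- do.call(rbind, lapply(fams, function(fm) {
    pre <- famResp[famResp$family == fm & famResp$block == "pre", ]
    post <- famResp[famResp$family == fm & famResp$block == "post", ]
    data.frame(family = fm,
               pct_pre = 100 * mean(pre$responder),
               pct_post = 100 * mean(post$responder),
               delta_pct = 100 * (mean(post$responder) - mean(pre$responder)))
  }))

  ids <- sort(cellsPre)
  rfs <- merge(rfPre[c("cell_id", "size")], rfPost[c("cell_id", "size")],
               by = "cell_id", all = TRUE, suffixes = c("_pre", "_post"))
  tun <- merge(tunPre[c("cell_id", "angle_deg", "excluded")],
               tunPost[c("cell_id", "angle_deg")],
               by = "cell_id", all = TRUE, suffixes = c("_pre", "_post"))
  cellDeltas <- data.frame(cell_id = ids)
  cellDeltas <- merge(cellDeltas, rfs, by = "cell_id", all.x = TRUE)
  cellDeltas <- merge(cellDeltas, tun, by = "cell_id", all.x = TRUE)
  cellDeltas$rf_delta <- cellDeltas$size_post - cellDeltas$size_pre
  cellDeltas$rf_fold <- ifelse(
    !is.na(cellDeltas$size_pre) & cellDeltas$size_pre > 0,
    cellDeltas$size_post / cellDeltas$size_pre, NA_real_)
  ltAxis <- config@basisAngles["mech"]
  stdPre <- ifelse(is.na(cellDeltas$angle_deg_pre), NA_real_,
                   standardizeAngles(ifelse(is.na(cellDeltas$angle_deg_pre),
                                            0, cellDeltas$angle_deg_pre),
                                     ltAxis))
  stdPost <- ifelse(is.na(cellDeltas$angle_deg_post), NA_real_,
                    standardizeAngles(ifelse(is.na(cellDeltas$angle_deg_post),
                                             0, cellDeltas$angle_deg_post),
                                      ltAxis))
  cellDeltas$std_angle_pre <- stdPre
  cellDeltas$std_angle_post <- stdPost
  cellDeltas$shift_toward_lt <- abs(stdPre) - abs(stdPost)

  out <- list(family_deltas = famDeltas, cell_deltas = cellDeltas)
  if (!is.null(clusters)) {
    cellDeltas$cluster <- clusters[cellDeltas$cell_id]
    ltResp <- famResp[famResp$family == "static_LT", ]
    out$cluster_deltas <- do.call(rbind, lapply(
      sort(unique(stats::na.omit(cellDeltas$cluster))), function(cl) {
        ids_cl <- cellDeltas$cell_id[!is.na(cellDeltas$cluster) &
                                       cellDeltas$cluster == cl]
        lr <- ltResp[ltResp$cell_id %in% ids_cl, ]
        g <- cellDeltas[cellDeltas$cell_id %in% ids_cl, ]
        data.frame(
          cluster = cl, n = length(ids_cl),
          delta_pct_lt = 100 * (mean(lr$responder[lr$block == "post"]) -
                                  mean(lr$responder[lr$block == "pre"])),
          mean_rf_fold = mean(g$rf_fold, na.rm = TRUE),
          mean_shift_toward_lt = mean(g$shift_toward_lt, na.rm = TRUE))
      }))
  }
  class(out) <- "SensitizationReport"
  out
}

#' @export
print.SensitizationReport <- function(x, ...) {
  cat("SensitizationReport:", nrow(x$cell_deltas), "cells\n")
  print(x$family_deltas, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on either a supplied experiment or a freshly
#' simulated one: preprocessing (rolling baseline, dF/F, drift QC),
#' responder detection for stimuli and ligands, family assignment,
#' capsaicin-responder classification, tuning vectors and receptive
#' fields per block, CICADA profile normalization and clustering,
#' optional depth assignment from a structural volume, and pre/post
#' sensitization deltas. Cells with no pre-capsaicin responses are
#' excluded from tuning analysis. All artifacts are written to `outDir`
#' when given.
#'
#' @param config a [CicadaConfig-class]; its `seed` drives simulation and
#'   clustering.
#' @param traces,timeline optional [TraceSet-class] and
#'   [EventTimeline-class]; when `NULL` a synthetic experiment is
#'   generated with `nCells`.
#' @param injectionS injection time (s); taken from the simulation when
#'   generating.
#' @param nCells cells to simulate when no traces are given.
#' @param volume optional structural volume list
#'   ([simulateStructuralVolume()] output or a compatible list with
#'   `volume` and `zStepUm`) for depth assignment.
#' @param planeZ0Um absolute z of imaging plane 0 in the volume frame.
#' @param outDir optional output directory for [writeReport()].
#' @return list with all stage outputs (`dffset`, `responses`, `famResp`,
#'   `capsaicin`, `tuning`, `rf`, `clusters`, `clusterSummary`, `deltas`,
#'   `report`, and `truth` when simulated).
#' @export
runPipeline <- function(config = cicadaConfig(), traces = NULL,
                        timeline = NULL, injectionS = NULL, nCells = 100,
                        volume = NULL, planeZ0Um = 20, outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  roi <- NULL
  if (is.null(traces)) {
    sim <- stage("simulate",
                 simulateExperiment(nCells = nCells, seed = config@seed))
    traces <- sim$traces
    timeline <- sim$timeline
    injectionS <- sim$injection_s
    truth <- sim$truth
    roi <- sim$roi
  } else if (is.null(timeline))
    stop("pipeline stage 'input' failed: timeline is required with traces")
  dffset <- stage("preprocess", preprocessTraces(traces, config))
  responses <- stage("detect", detectResponses(dffset, timeline, config))
  famResp <- stage("assign", assignFamilyResponse(responses))

  haveInjection <- !is.null(injectionS) && !is.na(injectionS)
  capsaicin <- if (haveInjection)
    stage("capsaicin", capsaicinResponder(dffset, injectionS, config)) else NULL

  # cells with at least one pre-block family response enter tuning analysis
  preResp <- famResp[famResp$block == "pre" & famResp$responder, ]
  tunedCells <- unique(preResp$cell_id)
  tuneBlocks <- c("pre", if (haveInjection) "post")
  tuning <- do.call(rbind, unlist(lapply(tuneBlocks, function(b) {
    lapply(c("cardinal", "mechanical"), function(m) {
      tt <- tuningTable(famResp[famResp$cell_id %in% tunedCells, ], b, m,
                        config)
      if (nrow(tt)) cbind(modalities = m, tt[c(
        "cell_id", "block", "angle_deg", "magnitude", "excluded")])
    })
  }), recursive = FALSE))
  rf <- do.call(rbind, unlist(lapply(tuneBlocks, function(b)
    lapply(c("static_LT", "static_HT"), function(fm)
      rfTable(responses, fm, b, config))), recursive = FALSE))

  clusters <- clusterSum <- NULL
  profs <- NULL
  if (any(responses$kind == "ligand")) {
    profs <- stage("cicada", cicadaProfiles(responses, config))
    respProfs <- profs[profs$any_responder, , drop = FALSE]
    if (nrow(respProfs) >= config@k) {
      m <- as.matrix(respProfs[paste0("norm_", .LIGAND_FAMILIES)])
      rownames(m) <- respProfs$cell_id
      depths <- NULL
      if (!is.null(truth)) {
        depths <- truth@cells$depth_um
        names(depths) <- truth@cells$cell_id
      }
      cl <- stage("cluster",
                  clusterProfiles(m, k = config@k, seed = config@seed,
                                  nInit = config@nInit, depths = depths))
      clusters <- data.frame(cell_id = names(cl$labels),
                             cluster = unname(cl$labels))
      clusterSum <- clusterSummary(cl$labels, m, depths, famResp)
    }
  }

  depthTable <- NULL
  if (!is.null(volume)) {
    surface <- stage("depth", detectSurface(volume$volume,
                                            zStepUm = volume$zStepUm))
    roiIn <- if (!is.null(roi)) roi else rowData(traces)
    depthTable <- stage("depth", assignDepth(
      roiIn, surface, planeZ0Um = planeZ0Um,
      planeSpacingUm = config@planeSpacingUm))
  }

  deltas <- NULL
  if (haveInjection) {
    clVec <- NULL
    if (!is.null(clusters)) {
      clVec <- clusters$cluster
      names(clVec) <- clusters$cell_id
    }
    deltas <- stage("deltas", prePostDeltas(
      famResp,
      rfTable(responses, "static_LT", "pre", config),
      rfTable(responses, "static_LT", "post", config),
      tuningTable(famResp[famResp$cell_id %in% tunedCells, ], "pre",
                  "mechanical", config),
      tuningTable(famResp[famResp$cell_id %in% tunedCells, ], "post",
                  "mechanical", config),
      clusters = clVec, config = config))
  }

  report <- list(
    software = list(package = "CicadaDH",
                    version = as.character(utils::packageVersion("CicadaDH"))),
    config = configAsList(config),
    seed = config@seed,
    n_cells = nrow(traces),
    n_cells_kept = sum(qcKeep(dffset)),
    n_events = nEvents(timeline),
    injection_s = if (haveInjection) injectionS else NULL,
    family_deltas = if (!is.null(deltas)) deltas$family_deltas else NULL,
    capsaicin_responder_pct = if (!is.null(capsaicin))
      100 * mean(capsaicin$responder, na.rm = TRUE) else NULL,
    cluster_summary = clusterSum)

  results <- list(dffset = dffset, responses = responses, famResp = famResp,
                  capsaicin = capsaicin, tuning = tuning, rf = rf,
                  clusters = clusters, clusterSummary = clusterSum,
                  profiles = profs, depth = depthTable, deltas = deltas,
                  truth = truth, report = report)
  if (!is.null(outDir))
    results$manifest <- stage("write", writeReport(results, outDir))
  results
}
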