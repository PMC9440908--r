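#' Analysis configuration
#'
#' All tunable constants of the pipeline live in a single validated S4
#' object. Defaults reproduce the published analysis settings: a 300 s
#' rolling window with the 30th percentile for dF/F baselining, the >200%
#' binned-median drift cut, the 1.25 dF/F + 6 sigma responder rule with a
#' 5 s stimulus window (120 s for bath-applied ligands) and a 30 s noise
#' window, the 150% capsaicin-responder factor on 2-minute averages with a
#' 30 s blind interval, the 120 degree-separated modality basis, the
#' ~3.75 mm 4x4 stimulation grid (3.75 mm^2 per responsive site as the area
#' conversion), and k = 7 for pharmacological clustering.
#'
#' @slot baselineWindowS width (s) of the centered rolling-baseline window.
#' @slot baselinePercentile percentile (0-100) used as baseline.
#' @slot driftBinS bin width (s) for the drift QC medians.
#' @slot driftLimit allowed fractional drift (2.0 means a 200% increase).
#' @slot driftMode `"ratio"` (max/min binned median) or `"first_bin"`
#'   (deviation from the first bin).
#' @slot ampThreshold responder peak amplitude threshold (dF/F).
#' @slot sigmaMult responder noise multiplier (peak must exceed
#'   `sigmaMult` x pre-event SD).
#' @slot responseWindowS response window (s) after a cutaneous stimulus.
#' @slot ligandWindowS response window (s) after a ligand application.
#' @slot noiseWindowS pre-event window (s) for the noise SD.
#' @slot capsaicinFactor post/pre activity ratio defining a capsaicin
#'   responder (1.5 = 150% of pre-injection level).
#' @slot capsaicinWindowS averaging window (s) on each side of injection.
#' @slot capsaicinBlindS half-width (s) of the masked interval around the
#'   injection.
#' @slot basisAngles named numeric, degrees counter-clockwise from +x for
#'   the three modality basis vectors; must be pairwise 120 degrees apart.
#' @slot perSiteAreaMm2 skin area (mm^2) represented by one grid site.
#' @slot k number of pharmacological clusters.
#' @slot nInit random restarts for k-means.
#' @slot specificityWeight weight on specificity in threshold calibration.
#' @slot wdrRatio HT/LT peak ratio above which a projection neuron counts
#'   as wide-dynamic-range.
#' @slot normMode `"paper"` for (X - Xmin)/Xmax ligand-profile
#'   normalization, `"minmax"` for the conventional (X - Xmin)/(Xmax - Xmin).
#' @slot planeSpacingUm axial spacing (um) between imaging planes.
#' @slot fovUm,fovPx field of view in um and pixels (x, y).
#' @slot seed master random seed; every stochastic step derives from it.
#' @export
setClass("CicadaConfig", representation(
  baselineWindowS = "numeric", baselinePercentile = "numeric",
  driftBinS = "numeric", driftLimit = "numeric", driftMode = "character",
  ampThreshold = "numeric", sigmaMult = "numeric",
  responseWindowS = "numeric", ligandWindowS = "numeric",
  noiseWindowS = "numeric",
  capsaicinFactor = "numeric", capsaicinWindowS = "numeric",
  capsaicinBlindS = "numeric",
  basisAngles = "numeric", perSiteAreaMm2 = "numeric",
  k = "numeric", nInit = "numeric", specificityWeight = "numeric",
  wdrRatio = "numeric", normMode = "character",
  planeSpacingUm = "numeric", fovUm = "numeric", fovPx = "numeric",
  seed = "numeric"))

setValidity("CicadaConfig", function(object) {
  msg <- character()
  pos <- c("baselineWindowS", "driftBinS", "driftLimit", "ampThreshold",
           "sigmaMult", "responseWindowS", "ligandWindowS", "noiseWindowS",
           "capsaicinFactor", "capsaicinWindowS", "perSiteAreaMm2", "k",
           "nInit", "specificityWeight", "wdrRatio", "planeSpacingUm")
  for (s in pos)
    if (slot(object, s) <= 0)
      msg <- c(msg, paste0(s, " must be strictly positive"))
  if (object@baselinePercentile <= 0 || object@baselinePercentile >= 100)
    msg <- c(msg, "baselinePercentile must be in (0, 100)")
  if (object@capsaicinBlindS < 0)
    msg <- c(msg, "capsaicinBlindS must be >= 0")
  ba <- sort(object@basisAngles %% 360)
  if (length(ba) != 3L ||
      max(abs(diff(c(ba, ba[1] + 360)) - 120)) > 1e-9)
    msg <- c(msg, "basisAngles must be three angles pairwise 120 deg apart")
  if (!object@driftMode %in% c("ratio", "first_bin"))
    msg <- c(msg, "driftMode must be 'ratio' or 'first_bin'")
  if (!object@normMode %in% c("paper", "minmax"))
    msg <- c(msg, "normMode must be 'paper' or 'minmax'")
  if (length(msg)) msg else TRUE
})

#' Build an analysis configuration
#'
#' @param ... named overrides for any [CicadaConfig-class] slot.
#' @return a validated [CicadaConfig-class].
#' @examples
#' cfg <- cicadaConfig(seed = 42)
#' cfg@ampThreshold
#' @export
cicadaConfig <- function(...) {
  defaults <- list(
    baselineWindowS = 300, baselinePercentile = 30,
    driftBinS = 300, driftLimit = 2.0, driftMode = "ratio",
    ampThreshold = 1.25, sigmaMult = 6,
    responseWindowS = 5, ligandWindowS = 120, noiseWindowS = 30,
    capsaicinFactor = 1.5, capsaicinWindowS = 120, capsaicinBlindS = 30,
    basisAngles = c(heat = 90, mech = 210, cold = 330),
    perSiteAreaMm2 = 3.75,
    k = 7, nInit = 25, specificityWeight = 1.25,
    wdrRatio = 1.2, normMode = "paper",
    planeSpacingUm = 14, fovUm = c(528.2, 220.8), fovPx = c(512, 214),
    seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  defaults[names(ov)] <- ov
  do.call(new, c(list("CicadaConfig"), defaults))
}

#' In-plane pixel size of the imaging configuration
#'
#' Divides the field-of-view extent by the pixel count along the same axis.
#' With the default geometry (528.2 um across 512 pixels) this is
#' 1.03 um/pixel.
#'
#' @param config a [CicadaConfig-class].
#' @param axis 1 for x, 2 for y.
#' @param digits rounding applied to the reported value (2, matching the
#'   precision the geometry is usually quoted at); use `NULL` for the raw
#'   quotient.
#' @return pixel size in micrometres per pixel.
#' @examples
#' pixelSizeUm(cicadaConfig())  # 1.03
#' @export
pixelSizeUm <- function(config = cicadaConfig(), axis = 1L, digits = 2) {
  p <- config@fovUm[axis] / config@fovPx[axis]
  if (is.null(digits)) p else round(p, digits)
}

#' Serialize a configuration to a plain list (for the JSON report)
#' @param config a [CicadaConfig-class].
#' @return named list of all slots.
#' @export
configAsList <- function(config) {
  sn <- slotNames("CicadaConfig")
  stats::setNames(lapply(sn, function(s) slot(config, s)), sn)
}

setMethod("show", "CicadaConfig", function(object) {
  cat("CicadaConfig: responder >", object@ampThreshold, "dF/F & >",
      object@sigmaMult, "sigma; windows", object@responseWindowS, "/",
      object@ligandWindowS, "s; baseline", object@baselinePercentile,
      "th pct over", object@baselineWindowS, "s; k =", object@k,
      "; seed =", object@seed, "\n")
})
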