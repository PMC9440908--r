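#' Default excitatory-neuron archetypes for the generator
#'
#' Seven generative archetypes loosely shaped like the pharmacologically
#' defined excitatory populations of the superficial dorsal horn: each has
#' a signature response to one or two of the 8 CICADA ligands, a
#' characteristic depth band (ordered shallow to deep), modality response
#' amplitudes (dF/F peak units), and sensitization parameters. `lt_gain`
#' multiplies the static low-threshold amplitude in the post-capsaicin
#' block (values > 1 model capsaicin-induced low-threshold gain, i.e.
#' mechanical allodynia); `rf_expansion` is the intended fold-change in
#' receptive-field site count after capsaicin.
#'
#' @return a `DataFrame`, one row per archetype, with sampling probability
#'   `prob`.
#' @export
defaultArchetypes <- function() {
  lig <- matrix(0, 7, 8,
                dimnames = list(NULL, .LIGAND_FAMILIES))
  lig[1, c("NKB", "SP")] <- c(2.2, 1.2)   # Ex1-like, TACR3/1
  lig[2, "SP"] <- 2.4                     # Ex2-like, TACR1
  lig[3, c("GRP", "NMB")] <- c(2.2, 1.8)  # Ex3-like, GRPR/NMBR
  lig[4, "CCK"] <- 2.4                    # Ex4-like, CCKBR
  lig[5, "taltirelin"] <- 2.4             # Ex5-like, TRHR
  lig[6, "Oxo"] <- 2.4                    # Ex6-like, CHRM3
  lig[7, "OXT"] <- 2.4                    # Ex7-like, OXTR
  df <- DataFrame(
    archetype = paste0("A", 1:7),
    prob      = c(0.16, 0.16, 0.16, 0.05, 0.16, 0.16, 0.15),
    depth_um  = c(8, 15, 22, 30, 38, 46, 54),
    amp_heat  = c(2.0, 2.2, 1.8, 0.0, 0.0, 1.6, 0.0),
    amp_cold  = c(1.8, 0.0, 0.0, 2.0, 0.0, 0.0, 0.0),
    amp_brush = c(2.0, 1.6, 0.0, 0.0, 1.8, 0.0, 2.0),
    amp_airpuff = c(1.6, 0.0, 0.0, 0.0, 1.5, 0.0, 1.6),
    amp_lt    = c(0.8, 0.9, 1.6, 0.0, 1.8, 1.6, 1.8),
    amp_ht    = c(2.2, 2.0, 2.0, 1.8, 2.0, 2.0, 1.6),
    lt_gain   = c(2.5, 2.0, 1.0, 1.0, 1.0, 1.5, 1.0),
    rf_expansion = c(2.0, 1.0, 1.0, 1.0, 1.0, 4.0, 1.0),
    spbn_prob = c(0.06, 0.04, 0.02, 0.0, 0.0, 0.0, 0.0))
  df$ligands <- lig
  df
}

#' Draw a synthetic cell population
#'
#' Samples `n` cells from an archetype table: each cell inherits its
#' archetype's modality and ligand amplitudes (with multiplicative
#' log-normal jitter), a receptive-field disc centre (archetype-agnostic,
#' uniform over the inner stimulation grid) and radius, a depth around the
#' archetype's band, and the archetype's sensitization parameters. A cell
#' is directly capsaicin-sensitive when its receptive-field column lies
#' close to the injected skin column.
#'
#' @param n number of cells.
#' @param archetypes archetype table ([defaultArchetypes()] or a custom
#'   `DataFrame` of the same shape).
#' @param seed random seed.
#' @param ampJitterSd SD of the log-normal amplitude jitter.
#' @param rfRadius mean receptive-field disc radius in grid units.
#' @param capsaicinCol skin grid column (0-3) of the capsaicin injection.
#' @param capsaicinReach maximum |rf column - injected column| for direct
#'   capsaicin sensitivity.
#' @param capsaicinAmp sustained surge amplitude (dF/F) of directly
#'   capsaicin-driven cells.
#' @return a `DataFrame` of per-cell generative parameters.
#' @export
cellPopulation <- function(n, archetypes = defaultArchetypes(), seed = 1,
                           ampJitterSd = 0.12, rfRadius = 0.9,
                           capsaicinCol = 1, capsaicinReach = 0.4,
                           capsaicinAmp = 0.6) {
  stopifnot(n >= 1)
  set.seed(seed)
  idx <- sample.int(nrow(archetypes), n, replace = TRUE,
                    prob = archetypes$prob)
  jit <- function(base) base * exp(stats::rnorm(n, 0, ampJitterSd))
  amps <- c("amp_heat", "amp_cold", "amp_brush", "amp_airpuff",
            "amp_lt", "amp_ht")
  cells <- DataFrame(cell_id = sprintf("cell_%04d", seq_len(n)),
                     archetype = archetypes$archetype[idx])
  for (a in amps) cells[[a]] <- jit(archetypes[[a]][idx])
  ligBase <- archetypes$ligands[idx, , drop = FALSE]
  ligJit <- ligBase * exp(matrix(stats::rnorm(n * 8, 0, ampJitterSd), n, 8))
  colnames(ligJit) <- .LIGAND_FAMILIES
  cells$ligands <- ligJit
  cells$rf_row <- stats::runif(n, 0.75, 2.25)
  cells$rf_col <- stats::runif(n, 0.75, 2.25)
  cells$rf_radius <- stats::runif(n, rfRadius * 0.85, rfRadius * 1.15)
  cells$depth_um <- pmax(1, archetypes$depth_um[idx] + stats::rnorm(n, 0, 4))
  cells$is_spbn <- stats::runif(n) < archetypes$spbn_prob[idx]
  cells$lt_gain <- archetypes$lt_gain[idx]
  cells$rf_expansion <- archetypes$rf_expansion[idx]
  cells$capsaicin_direct <- abs(cells$rf_col - capsaicinCol) <= capsaicinReach
  cells$cap_amp <- ifelse(cells$capsaicin_direct, capsaicinAmp, 0)
  cells
}

# Receptive-field membership on the 4x4 grid.
# Sites are indexed 1..16 row-major: site = 4*row + col + 1 (0-based coords).
.rfSites <- function(row, col, radius) {
  g <- expand.grid(r = 0:3, c = 0:3)
  d <- sqrt((g$r - row)^2 + (g$c - col)^2)
  which(d <= radius + 1e-9)
}

# Post-capsaicin receptive field: grow the disc outward by distance rank
# until round(expansion * pre-count) sites (capped at 16) are members, so
# the planted expansion IS the fold-change in site count.
.rfSitesPost <- function(row, col, radius, expansion) {
  pre <- .rfSites(row, col, radius)
  target <- min(16L, round(expansion * length(pre)))
  if (target <= length(pre)) return(pre)
  g <- expand.grid(r = 0:3, c = 0:3)
  d <- sqrt((g$r - row)^2 + (g$c - col)^2)
  sort(order(d)[seq_len(target)])
}
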