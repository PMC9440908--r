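#' Build the standard stimulation protocol as an event timeline
#'
#' Emits the full session structure: a pre-capsaicin testing block (brush
#' x3 and airpuff x3 at 60 s spacing, two heat and two cold ramps, then
#' 2 trials x 16 sites of static LT and HT filament mapping at 15 s
#' spacing, sites in deterministic row-major order), an optional
#' intradermal capsaicin injection followed after a rest by an identical
#' post block, and an optional end-of-session ligand block in which the 8
#' CICADA agonists are applied serially under TTX.
#'
#' @param capsaicin include the injection and post block.
#' @param ligands include the CICADA ligand block.
#' @param settleS quiet time (s) before the first stimulus.
#' @param postDelayS rest (s) between injection and the post block. The
#'   full experimental schedule tests repeatedly for ~90 min after
#'   injection and analyses the middle block; the generator emits a single
#'   post block after this shorter rest to stay desk-scale.
#' @param gridGapS spacing (s) between grid-site stimulations.
#' @param ligandGapS spacing (s) between ligand applications (must exceed
#'   the 120 s response window plus the 30 s noise window).
#' @return list with `timeline` (an [EventTimeline-class]), `injection_s`
#'   (`NA` when `capsaicin = FALSE`) and `duration_s`.
#' @export
buildProtocol <- function(capsaicin = TRUE, ligands = TRUE, settleS = 60,
                          postDelayS = 300, gridGapS = 15,
                          ligandGapS = 180) {
  rows <- list()
  t <- settleS
  addBlock <- function(t, block) {
    add <- function(fam, nrep, gap, dur, t) {
      for (i in seq_len(nrep)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = "stimulus", family = fam, onset_s = t, duration_s = dur,
          grid_row = NA_integer_, grid_col = NA_integer_,
          trial_index = i - 1L, block = block)
        t <- t + gap
      }
      t + 15 - gap + dur   # short pause after each family
    }
    t <- add("brush", 3L, 60, 2, t)
    t <- add("airpuff", 3L, 60, 1, t)
    t <- add("heat", 2L, 60, 10, t)
    t <- add("cold", 2L, 60, 10, t)
    for (fam in c("static_LT", "static_HT")) {
      for (trial in 0:1) {
        for (r in 0:3) for (cc in 0:3) {
          rows[[length(rows) + 1L]] <<- data.frame(
            kind = "stimulus", family = fam, onset_s = t, duration_s = 1,
            grid_row = r, grid_col = cc, trial_index = trial, block = block)
          t <- t + gridGapS
        }
      }
      t <- t + 15
    }
    t
  }
  t <- addBlock(t, "pre")
  injection <- NA_real_
  if (capsaicin) {
    injection <- t + 240
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "injection", family = "capsaicin", onset_s = injection,
      duration_s = 5, grid_row = NA_integer_, grid_col = NA_integer_,
      trial_index = 0L, block = "pre")
    t <- addBlock(injection + postDelayS, "post")
  }
  if (ligands) {
    t <- t + 60
    for (i in seq_along(.LIGAND_FAMILIES)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "ligand", family = .LIGAND_FAMILIES[i], onset_s = t,
        duration_s = 30, grid_row = NA_integer_, grid_col = NA_integer_,
        trial_index = 0L, block = "ligand")
      t <- t + ligandGapS
    }
  }
  list(timeline = EventTimeline(do.call(rbind, rows)),
       injection_s = injection, duration_s = t + 60)
}
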