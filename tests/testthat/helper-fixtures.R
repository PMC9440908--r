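# Shared fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

# A mid-sized synthetic experiment with the default population, preprocessed
# and detected; used by several test files.
fixExperiment <- function() {
  if (is.null(.fixtures$exp)) {
    sim <- simulateExperiment(nCells = 50, seed = 101)
    cfg <- cicadaConfig(seed = 101)
    dffset <- preprocessTraces(sim$traces, cfg)
    resp <- detectResponses(dffset, sim$timeline, cfg)
    .fixtures$exp <- list(sim = sim, cfg = cfg, dffset = dffset, resp = resp,
                          fam = assignFamilyResponse(resp))
  }
  .fixtures$exp
}

# A 200-cell single-archetype population carrying the 4-fold
# receptive-field expansion, analysed through the pipeline (memoised).
fixRfExpansion <- function() {
  if (is.null(.fixtures$rfx)) {
    arch <- defaultArchetypes()[6, ]
    arch$prob <- 1
    arch$rf_expansion <- 4
    arch$lt_gain <- 1
    cells <- cellPopulation(200, archetypes = arch, seed = 202)
    sim <- simulateExperiment(cells = cells, seed = 202)
    cfg <- cicadaConfig(seed = 202)
    dffset <- preprocessTraces(sim$traces, cfg)
    resp <- detectResponses(dffset, sim$timeline, cfg)
    .fixtures$rfx <- list(sim = sim, cfg = cfg, resp = resp, cells = cells)
  }
  .fixtures$rfx
}

# Tiny deterministic trace helpers.
constantTrace <- function(n = 600, level = 100) rep(level, n)

# event timeline with a single stimulus for unit tests
oneEventTimeline <- function(family = "brush", onset = 60, block = "pre") {
  EventTimeline(data.frame(kind = "stimulus", family = family,
                           onset_s = onset, duration_s = 1,
                           trial_index = 0L, block = block))
}

# truth amplitude lookup for (cell, event) pairs in a calls table
truthAmps <- function(sim, calls) {
  amps <- sim$truth@eventAmps
  amps[cbind(match(calls$cell_id, rownames(amps)), calls$event_index)]
}
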