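test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulateExperiment(nCells = 8, seed = 42)
  s2 <- simulateExperiment(nCells = 8, seed = 42)
  expect_identical(fluor(s1$traces), fluor(s2$traces))
  expect_identical(s1$truth@eventAmps, s2$truth@eventAmps)
  s3 <- simulateExperiment(nCells = 8, seed = 43)
  expect_false(identical(fluor(s1$traces), fluor(s3$traces)))
})

test_that("cells with zero mechanical amplitude never respond to filaments", {
  arch <- defaultArchetypes()[4, ]   # no LT amplitude
  arch$prob <- 1
  cells <- cellPopulation(10, archetypes = arch, seed = 2)
  expect_true(all(cells$amp_lt == 0))
  sim <- simulateExperiment(cells = cells, seed = 2)
  ev <- as.data.frame(events(sim$timeline))
  lt <- which(ev$family == "static_LT")
  expect_true(all(sim$truth@eventAmps[, lt] == 0))
})

test_that("noise-only segments of generated dF/F average to zero", {
  # generator-level invariant: before any baselining, event-free stretches
  # of F / (baselineF * bleach) - 1 are centred on zero
  k <- kernelParams(spontRateHz = 0, bleachFraction = 0, oscAmp = 0)
  sim <- simulateExperiment(nCells = 20, seed = 6, kernel = k,
                            protocol = buildProtocol(capsaicin = FALSE,
                                                     ligands = FALSE))
  f <- fluor(sim$traces)
  dffRaw <- f / k$baselineF - 1
  ev <- as.data.frame(events(sim$timeline))
  lastEnd <- max(ev$onset_s) + 30
  quiet <- (round(lastEnd) + 1):ncol(f)     # tail after all transients decay
  expect_gt(length(quiet), 50)
  m <- mean(dffRaw[, quiet])
  se <- sd(dffRaw[, quiet]) / sqrt(length(quiet) * nrow(f))
  expect_lt(abs(m), 3 * se + 1e-3)
})

test_that("the event-triggered transient follows the kernel's shape", {
  # at 10 Hz sampling: the sampled peak of the event-triggered average sits
  # at the kernel's analytic argmax (within one frame), and the response
  # decays below 10% of peak within 5 decay time constants
  k <- kernelParams(noiseSd = 0.01, spontRateHz = 0, bleachFraction = 0, oscAmp = 0)
  tl <- EventTimeline(data.frame(kind = "stimulus", family = "brush",
                                 onset_s = c(60, 120, 180), duration_s = 1,
                                 trial_index = 0:2, block = "pre"))
  proto <- list(timeline = tl, injection_s = NA_real_, duration_s = 300)
  arch <- defaultArchetypes()[1, ]; arch$prob <- 1
  cells <- cellPopulation(30, archetypes = arch, seed = 3)
  sim <- simulateExperiment(cells = cells, protocol = proto,
                            kernel = k, frameRate = 10, seed = 3)
  f <- fluor(sim$traces)
  eta <- colMeans(f / k$baselineF - 1)
  onset <- 60 * 10 + 1
  seg <- eta[onset:(onset + 99)]
  tPeak <- (which.max(seg) - 1) / 10
  tStar <- log(k$decayTauS / k$riseTauS) / (1 / k$riseTauS - 1 / k$decayTauS)
  expect_lte(abs(tPeak - tStar), 0.1)
  after5tau <- seg[round(5 * k$decayTauS * 10)]
  expect_lt(after5tau, 0.1 * max(seg))
})

test_that("planted low-threshold gain appears in post/pre peak ratios", {
  arch <- defaultArchetypes()[6, ]   # LT amplitude 1.6, gain 1.5
  arch$prob <- 1; arch$rf_expansion <- 1
  cells <- cellPopulation(100, archetypes = arch, seed = 9)
  sim <- simulateExperiment(cells = cells, seed = 9)
  amps <- sim$truth@eventAmps
  ev <- as.data.frame(events(sim$timeline))
  pre <- amps[, ev$family == "static_LT" & ev$block == "pre", drop = FALSE]
  post <- amps[, ev$family == "static_LT" & ev$block == "post", drop = FALSE]
  ratio <- mean(post[post > 0]) / mean(pre[pre > 0])
  expect_equal(ratio, 1.5, tolerance = 0.15)
})

test_that("post-block receptive fields grow by the planted fold", {
  arch <- defaultArchetypes()[6, ]
  arch$prob <- 1                      # rf_expansion 4
  cells <- cellPopulation(60, archetypes = arch, seed = 10)
  sim <- simulateExperiment(cells = cells, seed = 10)
  sizes <- t(vapply(sim$truth@rf, function(r)
    c(pre = length(r$pre), post = length(r$post)), numeric(2)))
  expect_equal(mean(sizes[, "post"]) / mean(sizes[, "pre"]), 4,
               tolerance = 0.15)
  expect_true(all(sizes[, "post"] <= 16))
})

test_that("annotation labels flip at the requested rate", {
  sim <- simulateExperiment(nCells = 20, seed = 12)
  ann0 <- simulateAnnotations(sim$truth, sim$timeline, 0, seed = 1)
  expect_true(all(ann0$label == ann0$true_responder))
  ev <- as.data.frame(events(sim$timeline))
  expect_equal(nrow(ann0), 20 * sum(ev$kind == "stimulus"))
  ann <- simulateAnnotations(sim$truth, sim$timeline, 0.05, seed = 1)
  flipped <- mean(ann$label != ann$true_responder)
  n <- nrow(ann)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n   # binomial 99% interval
  expect_gte(flipped, ci[1])
  expect_lte(flipped, ci[2])
})

test_that("protocols longer than the recording are rejected", {
  tl <- EventTimeline(data.frame(kind = "stimulus", family = "brush",
                                 onset_s = 500, duration_s = 1,
                                 trial_index = 0L, block = "pre"))
  proto <- list(timeline = tl, injection_s = NA_real_, duration_s = 400)
  expect_error(simulateExperiment(nCells = 2, protocol = proto, seed = 1),
               "configuration error")
})
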