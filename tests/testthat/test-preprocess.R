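test_that("constant traces get a constant baseline and zero dF/F", {
  tr <- constantTrace(600, 100)
  b <- rollingBaseline(tr, 300, 30, 1)
  expect_equal(b, rep(100, 600))
  expect_equal(computeDff(tr, b), rep(0, 600))
})

test_that("a short transient does not perturb the 30th-percentile baseline", {
  tr <- constantTrace(600, 100)
  tr[300:305] <- 200
  b <- rollingBaseline(tr, 300, 30, 1)
  expect_equal(b, rep(100, 600))
})

test_that("rolling baseline equals a brute-force per-frame percentile", {
  # independent naive oracle: recompute the window percentile per frame
  naiveBaseline <- function(x, windowS, pct, fr) {
    half <- floor(round(windowS * fr) / 2)
    vapply(seq_along(x), function(i) {
      w <- x[max(1, i - half):min(length(x), i + half)]
      stats::quantile(w, pct / 100, names = FALSE, na.rm = TRUE)
    }, numeric(1))
  }
  set.seed(42)
  for (rep in 1:20) {
    x <- 100 * exp(rnorm(1000, 0, 0.2))
    expect_equal(rollingBaseline(x, 300, 30, 1),
                 naiveBaseline(x, 300, 30, 1), tolerance = 1e-12)
  }
  # NA frames are excluded, matching na.rm percentiles
  x <- 100 + rnorm(500)
  x[200:260] <- NA
  expect_equal(rollingBaseline(x, 300, 30, 1), naiveBaseline(x, 300, 30, 1),
               tolerance = 1e-12)
})

test_that("baseline is translation-equivariant and dF/F scale-invariant", {
  set.seed(7)
  x <- 100 + rnorm(800)
  expect_equal(rollingBaseline(x + 55, 300, 30, 1),
               rollingBaseline(x, 300, 30, 1) + 55, tolerance = 1e-10)
  b <- rollingBaseline(x, 300, 30, 1)
  expect_equal(computeDff(3.7 * x, 3.7 * b), computeDff(x, b),
               tolerance = 1e-12)
})

test_that("dF/F arithmetic matches its definition and flags bad baselines", {
  expect_equal(computeDff(250, 100), 1.5)
  expect_error(computeDff(c(1, 2), c(1, 0)), "frame 2")
})

test_that("drift QC applies the 200% binned-median rule", {
  set.seed(3)
  stable <- 100 * (1 + 0.05 * runif(1200, -1, 1))
  expect_true(driftQC(stable)$keep)
  step <- c(rep(100, 600), rep(400, 600)) + rnorm(1200)
  out <- driftQC(step)
  expect_false(out$keep)            # ratio 4 -> 300% drift > 200%
  expect_match(out$reason, "drift")
  # 10% monotone bleach survives: max/min ~ 1.11
  bleach <- 100 * exp(seq(0, log(0.9), length.out = 1200))
  expect_true(driftQC(bleach)$keep)
  # boundary: ratio 3.0 is exactly 200% drift, kept; just above is dropped
  expect_true(driftQC(c(rep(100, 600), rep(300, 600)))$keep)
  expect_false(driftQC(c(rep(100, 600), rep(302, 600)))$keep)
})

test_that("preprocessTraces wires baseline, dF/F and QC into a DffSet", {
  fx <- fixExperiment()
  d <- fx$dffset
  expect_s4_class(d, "DffSet")
  expect_identical(dim(d), dim(fx$sim$traces))
  b <- baselineFluor(d)
  expect_true(all(b[!is.na(dff(d))] > 0))
  expect_named(qcKeep(d))
  # a cell with a mid-recording step gets discarded with a recorded reason
  f <- fluor(fx$sim$traces)
  f[1, seq(ncol(f) / 2, ncol(f))] <- f[1, seq(ncol(f) / 2, ncol(f))] * 5
  ts <- TraceSet(f, cellIds = cellIds(fx$sim$traces), frameRate = 1)
  d2 <- preprocessTraces(ts, fx$cfg)
  expect_false(qcKeep(d2)[1])
  expect_match(rowData(d2)$qc_reason[1], "drift")
})

test_that("a generator transient's amplitude is recovered in dF/F", {
  k <- kernelParams(noiseSd = 0.02, spontRateHz = 0, oscAmp = 0)
  sim <- simulateExperiment(nCells = 12, seed = 5, kernel = k)
  dffset <- preprocessTraces(sim$traces, cicadaConfig())
  resp <- detectResponses(dffset, sim$timeline, cicadaConfig())
  ta <- truthAmps(sim, resp)
  # pre-block events only: post-block peaks of capsaicin-driven cells
  # legitimately ride on the injection surge
  sel <- ta >= 1.5 & resp$kind == "stimulus" & resp$block == "pre"
  expect_gt(sum(sel), 20)
  expect_lt(max(abs(resp$peak_amp[sel] - ta[sel])), 0.1)
})
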