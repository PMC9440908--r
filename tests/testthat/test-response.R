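test_that("the responder rule applies both amplitude and sigma criteria", {
  # noise window scaled to exactly the nominal SD so the worked examples
  # hold by arithmetic, not sampling luck
  mkTrace <- function(peak, sigma, n = 120, onset = 60) {
    set.seed(1)
    tr <- rep(0, n)
    z <- rnorm(30)
    tr[(onset - 29):onset] <- (z - mean(z)) / sd(z) * sigma
    tr[onset + 2] <- peak
    tr
  }
  # peak 2.0, sigma 0.05: passes both 1.25 and 6*sigma = 0.3
  r <- detectResponse(mkTrace(2.0, 0.05), 60)
  expect_true(r$responder)
  expect_equal(r$peak_amp, 2.0)
  # peak 1.0 fails the 1.25 amplitude criterion
  expect_false(detectResponse(mkTrace(1.0, 0.05), 60)$responder)
  # peak 1.5 with sigma 0.30 fails the 6-sigma criterion (1.8 > 1.5)
  expect_false(detectResponse(mkTrace(1.5, 0.30), 60)$responder)
  # windows outside the recording are range errors
  expect_error(detectResponse(rep(0, 120), 10), "range error")
  expect_error(detectResponse(rep(0, 120), 118), "range error")
})

test_that("ligand detection uses the wide window", {
  set.seed(2)
  tr <- rnorm(400, 0, 0.05)
  onset <- 150
  tr[onset + 80] <- 2.0   # slow-onset transient peaking 80 s in
  expect_true(detectLigandResponse(tr, onset)$responder)
  expect_false(detectResponse(tr, onset)$responder)  # 5 s window misses it
})

test_that("noise sigma masks frames inside other events' windows", {
  set.seed(3)
  tr <- rnorm(200, 0, 0.05)
  tr[81:84] <- 3          # a big prior response 20 s before our event
  onset <- 100
  masked <- detectResponse(tr, onset, maskFrames = 81:86)
  unmasked <- detectResponse(tr, onset)
  expect_lt(masked$noise_sigma, 0.1)
  expect_gt(unmasked$noise_sigma, 0.3)
})

test_that("family assignment uses 2-of-3 for brush/airpuff, 1-of-N otherwise", {
  mk <- function(family, responders) data.frame(
    cell_id = "c1", event_index = seq_along(responders), kind = "stimulus",
    family = family, block = "pre", trial_index = seq_along(responders) - 1L,
    grid_row = NA_integer_, grid_col = NA_integer_, onset_s = 0,
    peak_amp = 1, noise_sigma = 0.01, responder = responders)
  expect_true(assignFamilyResponse(mk("brush", c(TRUE, TRUE, FALSE)))$responder)
  expect_false(assignFamilyResponse(mk("brush", c(TRUE, FALSE, FALSE)))$responder)
  expect_true(assignFamilyResponse(mk("heat", c(FALSE, TRUE)))$responder)
  expect_true(assignFamilyResponse(mk("cold", c(TRUE, FALSE)))$responder)
  expect_error(assignFamilyResponse(mk("brush", TRUE)[0, ]),
               "assignment error")
})

test_that("responder monotonicity: larger peaks never flip to non-responder", {
  set.seed(11)
  for (i in 1:1000) {
    sigma <- runif(1, 0.01, 0.4)
    peak <- runif(1, 0, 3)
    base <- peak > 1.25 && peak > 6 * sigma
    bigger <- (peak + runif(1, 0, 2))
    up <- bigger > 1.25 && bigger > 6 * sigma
    if (base) expect_true(up)
  }
})

test_that("detection recovers generator truth at default SNR", {
  fx <- fixExperiment()
  stim <- fx$resp[fx$resp$kind == "stimulus", ]
  ta <- truthAmps(fx$sim, stim)
  expect_gt(mean(stim$responder[ta >= 1.5]), 0.95)
  expect_gt(mean(!stim$responder[ta == 0]), 0.99)
})

test_that("cells without the ligand receptor are not called ligand responders", {
  fx <- fixExperiment()
  lig <- fx$resp[fx$resp$kind == "ligand", ]
  ta <- truthAmps(fx$sim, lig)
  expect_gt(sum(ta == 0), 100)
  expect_gt(mean(!lig$responder[ta == 0]), 0.99)
  expect_gt(mean(lig$responder[ta >= 1.5]), 0.95)
})

test_that("capsaicin responder rule compares 2-min averages at 150%", {
  cfg <- cicadaConfig()
  # deterministic dff matrix: 600 frames, injection at 300
  d <- matrix(0.20, 3, 600)
  d[1, 331:450] <- 0.35    # 175% of pre -> responder
  d[2, 331:450] <- 0.25    # 125% -> non-responder
  d[3, ] <- 0              # indeterminate pre
  rownames(d) <- c("a", "b", "c")
  out <- capsaicinResponder(d, 300, cfg)
  expect_equal(out$responder, c(TRUE, FALSE, FALSE))
  expect_equal(out$indeterminate, c(FALSE, FALSE, TRUE))
  expect_equal(out$pre_mean[1], 0.20)
  expect_equal(out$post_mean[1], 0.35)
})
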