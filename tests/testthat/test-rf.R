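test_that("receptive-field size is the trial-averaged responsive-site count", {
  all16 <- matrix(TRUE, 4, 4)
  none <- matrix(FALSE, 4, 4)
  expect_equal(rfSize(list(all16, all16))$size, 16)
  expect_equal(rfSize(list(none, none))$size, 0)
  g4 <- matrix(FALSE, 4, 4); g4[1, ] <- TRUE          # 4 sites
  g2 <- matrix(FALSE, 4, 4); g2[1, 1:2] <- TRUE       # 2 sites
  expect_equal(rfSize(list(g4, g2))$size, 3.0)
  expect_error(rfSize(list(matrix(TRUE, 3, 4))), "shape error")
})

test_that("receptive-field area uses the grid's per-site skin area", {
  expect_equal(rfArea(4), 15)
  expect_equal(rfArea(0), 0)
  expect_equal(rfArea(16), 60)
  expect_equal(rfArea(2.5, 3.75), 9.375)
})

test_that("rfTable reconstructs generator receptive fields within one site", {
  fx <- fixExperiment()
  rf <- rfTable(fx$resp, "static_HT", "pre", fx$cfg)
  truthSizes <- vapply(fx$sim$truth@rf, function(r) length(r$pre), numeric(1))
  names(truthSizes) <- fx$sim$truth@cells$cell_id
  # only cells with a detectable HT amplitude can be recovered
  ht <- fx$sim$truth@cells$amp_ht
  names(ht) <- fx$sim$truth@cells$cell_id
  ok <- rf$cell_id[ht[rf$cell_id] >= 1.5]
  expect_gt(length(ok), 30)
  err <- abs(rf$size[match(ok, rf$cell_id)] - truthSizes[ok])
  expect_lte(max(err), 1)
  expect_lte(mean(err), 0.25)
})

test_that("wasserstein1 matches closed-form cases", {
  expect_equal(wasserstein1(c(0, 1), c(0, 1)), 0)
  expect_equal(wasserstein1(0, 1), 1)                  # point masses
  expect_equal(wasserstein1(c(0, 0), c(1, 3)), 2)      # mean shift
  set.seed(41)
  a <- rnorm(100)
  expect_equal(wasserstein1(a, a + 5), 5, tolerance = 1e-9)
})

test_that("injection locus is recovered from somatotopic distributions", {
  set.seed(42)
  refs <- lapply(0:3, function(col) rnorm(60, mean = 400 - col * 100, sd = 25))
  names(refs) <- 0:3
  # responders drawn from the column-2 distribution
  resp <- rnorm(40, 200, 25)
  out <- inferInjectionLocus(resp, refs)
  expect_equal(out$locus, 2)
  expect_false(out$low_confidence)
  # a 50/50 mixture of columns 2 and 3 spreads over both
  mix <- c(rnorm(25, 200, 25), rnorm(25, 100, 25))
  outm <- inferInjectionLocus(mix, refs)
  expect_true(all(c(2, 3) %in% outm$spread))
  # too few responders: flagged, no estimate
  few <- inferInjectionLocus(rnorm(3, 200, 25), refs)
  expect_true(few$low_confidence)
  expect_true(is.na(few$locus))
  # uniform responders give a weak margin
  unif <- inferInjectionLocus(runif(60, 0, 500), refs)
  expect_true(unif$low_confidence)
})
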