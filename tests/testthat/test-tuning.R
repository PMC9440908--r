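test_that("tuning geometry matches the basis construction", {
  # single-modality cell points exactly along its basis angle
  expect_equal(tuningVector(c(1, 0, 0))$angle_deg, 90)
  expect_equal(tuningVector(c(0, 1, 0))$angle_deg, 210)
  expect_equal(tuningVector(c(0, 0, 1))$angle_deg, 330)
  # equal tri-modal: the three 120-degree unit vectors cancel
  expect_equal(tuningVector(c(1, 1, 1))$magnitude, 0, tolerance = 1e-12)
  # worked component arithmetic: normalized (2,1,0) sums to (-sqrt(3)/2, 3/2)
  tv <- tuningVector(c(2, 1, 0))
  expect_equal(tv$angle_deg, 120)
  expect_equal(tv$magnitude, sqrt(3))
})

test_that("tuning is invariant to uniform amplitude scaling", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(3, 0, 3)
    if (all(a == 0)) next
    t1 <- tuningVector(a)
    t2 <- tuningVector(a * runif(1, 0.1, 10))
    expect_equal(t1$angle_deg, t2$angle_deg, tolerance = 1e-9)
    expect_equal(t1$magnitude, t2$magnitude, tolerance = 1e-9)
  }
})

test_that("the basis unit vectors sum to zero at machine precision", {
  ang <- cicadaConfig()@basisAngles
  v <- c(sum(cospi(ang / 180)), sum(sinpi(ang / 180)))
  expect_equal(v, c(0, 0), tolerance = 1e-14)
})

test_that("all-zero amplitudes yield an exclusion signal, not a vector", {
  tv <- tuningVector(c(0, 0, 0))
  expect_true(tv$excluded)
  expect_true(is.na(tv$angle_deg))
  expect_error(tuningVector(c(-1, 0, 0)), "non-negative")
})

test_that("angle standardization is modular and signed", {
  expect_equal(standardizeAngles(c(1, -359), 0), c(1, 1))
  expect_equal(standardizeAngles(360, 0), 0)
  expect_equal(standardizeAngles(181, 0), -179)
  expect_equal(standardizeAngles(180, 0), 180)
  # adding whole turns never changes the result
  set.seed(32)
  a <- runif(50, -720, 720)
  k <- sample(-3:3, 50, replace = TRUE)
  expect_equal(standardizeAngles(a + 360 * k, 77), standardizeAngles(a, 77))
})

test_that("preference scores follow (X_i - X_avg)/X_max and its bound", {
  expect_equal(unname(preferenceScore(c(2, 1, 0))), c(0.5, 0, -0.5))
  expect_equal(unname(preferenceScore(c(1, 1, 1))), c(0, 0, 0))
  set.seed(33)
  for (i in 1:100) {
    s <- preferenceScore(runif(3, 0.01, 5))
    expect_lte(max(s), 2 / 3)
  }
  expect_true(attr(preferenceScore(c(0, 0, 0)), "degenerate"))
})

test_that("single-modality synthetic cells recover basis angles within noise", {
  # pure-heat cells under measurement noise: circular spread stays tight
  fx <- fixExperiment()
  tr <- fx$sim$truth@cells
  tun <- tuningTable(fx$fam, "pre", "cardinal", fx$cfg)
  tun <- merge(tun, data.frame(cell_id = tr$cell_id, arch = tr$archetype))
  # A5/A7-like archetypes are mechanical-only: angle near 210
  mech <- tun[tun$arch %in% c("A5", "A7") & !tun$excluded, ]
  expect_gt(nrow(mech), 3)
  dev <- standardizeAngles(mech$angle_deg, 210)
  expect_lt(max(abs(dev)), 25)
})
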