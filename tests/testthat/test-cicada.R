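test_that("profile normalization follows (X - Xmin)/Xmax with its fallback", {
  x <- c(2.0, 0.1, 0.5, 0.3, 0.2, 0.15, 0.1, 0.4)
  nz <- normalizeProfile(x, TRUE)
  expect_equal(nz[1], (2.0 - 0.1) / 2.0)      # 0.95, not 1
  expect_equal(min(nz), 0)                     # smallest value becomes 0
  expect_equal(max(nz), (max(x) - min(x)) / max(x))
  # single-ligand responder: (1, 0, ..., 0)
  expect_equal(unname(normalizeProfile(c(2, rep(0, 7)), TRUE)),
               c(1, rep(0, 7)))
  # non-responder fallback divides by the mean
  expect_equal(unname(normalizeProfile(rep(0.2, 8), FALSE)), rep(1, 8))
  # all-zero non-responder: zero vector, flagged
  z <- normalizeProfile(rep(0, 8), FALSE)
  expect_equal(as.numeric(z), rep(0, 8))
  expect_true(attr(z, "degenerate"))
  # conventional min-max alternative
  expect_equal(max(normalizeProfile(x, TRUE, "minmax")), 1)
})

.planted <- function(n = 300, k = 3, sep = 5, seed = 51) {
  set.seed(seed)
  centers <- matrix(0, k, 8)
  for (i in seq_len(k)) centers[i, (2 * i - 1):(2 * i)] <- sep * 0.12
  lab <- sample.int(k, n, replace = TRUE)
  m <- centers[lab, ] + matrix(rnorm(n * 8, 0, 0.12), n, 8)
  rownames(m) <- sprintf("c%03d", seq_len(n))
  list(m = m, lab = lab)
}

test_that("k-means recovers well-separated planted archetypes", {
  p <- .planted()
  cl <- clusterProfiles(p$m, k = 3, seed = 7)
  expect_gte(mclust::adjustedRandIndex(cl$labels, p$lab), 0.95)
})

test_that("clustering is deterministic and permutation-invariant", {
  p <- .planted(n = 150)
  c1 <- clusterProfiles(p$m, k = 3, seed = 9)
  c2 <- clusterProfiles(p$m, k = 3, seed = 9)
  expect_identical(c1$labels, c2$labels)
  perm <- sample(nrow(p$m))
  c3 <- clusterProfiles(p$m[perm, ], k = 3, seed = 9)
  expect_equal(mclust::adjustedRandIndex(c1$labels[rownames(p$m)[perm]],
                                         c3$labels), 1)
  # k = 1: everything in one cluster
  expect_true(all(clusterProfiles(p$m, k = 1)$labels == 1L))
  expect_error(clusterProfiles(p$m, k = 0), "configuration error")
  expect_error(clusterProfiles(p$m, k = nrow(p$m) + 1), "configuration error")
})

test_that("depth-ordered relabeling is stable and ordered", {
  p <- .planted(n = 200)
  depths <- stats::setNames(10 * p$lab + rnorm(200, 0, 1), rownames(p$m))
  c1 <- clusterProfiles(p$m, k = 3, seed = 3, depths = depths)
  c2 <- clusterProfiles(p$m, k = 3, seed = 3, depths = depths)
  expect_identical(c1$labels, c2$labels)
  med <- vapply(1:3, function(cl)
    median(depths[names(c1$labels)[c1$labels == cl]]), numeric(1))
  expect_true(all(diff(med) > 0))   # label 1 shallowest
})

test_that("selectK picks the planted cluster count", {
  p <- .planted(n = 240)
  sel <- selectK(p$m, 2:6, seed = 5)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$table), 5)
  sel2 <- selectK(p$m, 2, seed = 5)
  expect_equal(sel2$k, 2)
  expect_error(selectK(matrix(1, 20, 8), 2:3), "selection error")
  set.seed(8)
  noise <- matrix(rnorm(400), 50, 8)
  rownames(noise) <- sprintf("n%02d", 1:50)
  expect_warning(selectK(noise, 2:4, seed = 5), "weak cluster structure")
})

test_that("cluster summaries conserve abundance and average profiles", {
  p <- .planted(n = 120)
  cl <- clusterProfiles(p$m, k = 3, seed = 2)
  depths <- stats::setNames(runif(120, 5, 60), rownames(p$m))
  cs <- clusterSummary(cl$labels, p$m, depths)
  expect_equal(sum(cs$abundance_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cs$n), 120)
  # a cluster of identical profiles averages to that profile
  ident <- matrix(rep(c(1, 0, 0.5, 0, 0, 0, 0, 0), each = 10), 10, 8)
  dimnames(ident) <- list(sprintf("i%02d", 1:10), paste0("L", 1:8))
  lab <- stats::setNames(rep(1L, 10), rownames(ident))
  cs2 <- clusterSummary(lab, ident)
  expect_equal(unname(unlist(cs2[1, paste0("mean_", colnames(ident))])),
               c(1, 0, 0.5, 0, 0, 0, 0, 0))
})

test_that("end-to-end ligand profiles separate the default archetypes", {
  fx <- fixExperiment()
  profs <- cicadaProfiles(fx$resp, fx$cfg)
  expect_equal(nrow(profs), 50)
  rp <- profs[profs$any_responder, ]
  m <- as.matrix(rp[paste0("norm_", c("SP", "OXT", "GRP", "Oxo",
                                      "taltirelin", "NMB", "CCK", "NKB"))])
  rownames(m) <- rp$cell_id
  expect_gte(nrow(m), 40)
  cl <- clusterProfiles(m, k = 7, seed = 1)
  arch <- fx$sim$truth@cells$archetype[
    match(rownames(m), fx$sim$truth@cells$cell_id)]
  expect_gte(mclust::adjustedRandIndex(cl$labels, arch), 0.9)
})
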