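test_that("window expansion replicates components and inverts exactly", {
  d <- generateCohort(separatedCohort(n = 5, seed = 1))
  ex <- expandWindows(d, window_size = 200)
  expect_equal(dim(sampleMatrix(ex$data)), c(15L, 600L))
  expect_equal(unique(featureClass(ex$data)), "window-snp")
  expect_equal(unname(table(ex$map)), rep(200L, 3), ignore_attr = TRUE)

  # window_size = 1 is the identity up to feature ids
  id1 <- expandWindows(d, window_size = 1)
  expect_equal(unname(sampleMatrix(id1$data)), unname(sampleMatrix(d)))

  # collapse(expand(x)) = x with nothing missing
  back <- collapseWindows(ex$data, ex$map)
  expect_equal(unname(sampleMatrix(back)), unname(sampleMatrix(d)),
               tolerance = 1e-12)
  expect_error(expandWindows(d, 0), "integer")
})

test_that("missingness injection nullifies the exact entry count", {
  d <- generateCohort(separatedCohort(n = 10, seed = 2))
  ex <- expandWindows(d, window_size = 50)
  expect_identical(injectMissingness(ex$data, 0), ex$data)
  half <- injectMissingness(ex$data, 0.5, seed = 3)
  expect_equal(sum(missingMask(half)), round(0.5 * 30 * 150))
  # a rate that wipes out a sample is refused with the offender named
  tiny <- ColorDataset(matrix(runif(6), 2, 3), c("A", "B"))
  expect_error(injectMissingness(tiny, 0.9, seed = 1), "fully missing")
  expect_error(injectMissingness(tiny, 1), "must lie in")
})

test_that("missing-aware collapse recovers components at the expected accuracy", {
  d <- generateCohort(separatedCohort(n = 20, seed = 4))
  ex <- expandWindows(d, window_size = 200, feature_noise_sd = 0.01,
                      seed = 5)
  wd <- injectMissingness(ex$data, 0.9, seed = 6)
  rec <- collapseWindows(wd, ex$map)
  # ~20 observed replicates per component: error SE = 0.01/sqrt(20)
  err <- sampleMatrix(rec) - sampleMatrix(d)
  obs <- matrix(0, nrow(err), 3)
  M <- missingMask(wd)
  for (c in 1:3) obs[, c] <- rowSums(!M[, ex$map == c, drop = FALSE])
  expect_true(all(abs(err) < 3 * 0.01 / sqrt(pmax(obs, 1)) + 1e-12))

  # a single observed feature per component passes through exactly
  two <- ColorDataset(rbind(1:6 / 10, 1:6 / 10), c("A", "A"),
                      feature_class = "window-snp",
                      missing_mask = rbind(c(FALSE, TRUE, TRUE,
                                             FALSE, TRUE, TRUE),
                                           rep(FALSE, 6)))
  map <- rep(1:3, each = 2)
  rec2 <- collapseWindows(two, map)
  expect_equal(unname(sampleMatrix(rec2)[1, 1:2]), c(0.1, 0.4),
               tolerance = 1e-12)
  expect_true(missingMask(rec2)[1, 3])   # third component unobserved
})

test_that("collapse error scales with the root of the observed window count", {
  rates <- c(0, 0.5, 0.9)
  d <- generateCohort(separatedCohort(n = 30, seed = 7))
  rmse <- vapply(rates, function(rate) {
    ex <- expandWindows(d, window_size = 200, feature_noise_sd = 0.05,
                        seed = 8)
    wd <- if (rate > 0) injectMissingness(ex$data, rate, seed = 9) else
      ex$data
    rec <- collapseWindows(wd, ex$map)
    sqrt(mean((sampleMatrix(rec) - sampleMatrix(d))^2))
  }, numeric(1))
  expected <- 0.05 / sqrt(200 * (1 - rates))
  ratio <- rmse / expected
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("noise markers dilute explained variance without moving the center", {
  d <- generateCohort(separatedCohort(n = 25, seed = 10))
  expect_identical(addNoiseMarkers(d, 0), d)
  grid <- c(30L, 300L, 3000L)
  ev <- vapply(grid, function(m) {
    noisy <- addNoiseMarkers(d, m, seed = 11)
    model <- fitPCA(noisy)
    expect_equal(model@center[1:3], colMeans(sampleMatrix(d)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    explainedVariance(model, 2)$fraction
  }, numeric(1))
  base <- explainedVariance(fitPCA(d), 2)$fraction
  expect_true(all(diff(c(base, ev)) < 0))
})

test_that("pervasive low-level noise perturbs within its stated level", {
  d <- generateCohort(separatedCohort(n = 5, seed = 12))
  p <- perturbAllMarkers(d, level = 0.1, seed = 13)
  delta <- sampleMatrix(p) - sampleMatrix(d)
  expect_true(all(abs(delta) <= 0.05 + 1e-12))
  expect_gt(max(abs(delta)), 0)
})

test_that("feature-class subsetting drives per-marker-class PCA runs", {
  d <- generateCohort(separatedCohort(n = 10, seed = 14))
  noisy <- addNoiseMarkers(d, 20, seed = 15)
  colors_only <- subsetFeatureClass(noisy, "color-component")
  expect_equal(unname(sampleMatrix(colors_only)), unname(sampleMatrix(d)))
  noise_only <- subsetFeatureClass(noisy, "noise-marker")
  expect_equal(ncol(sampleMatrix(noise_only)), 20L)
  expect_error(subsetFeatureClass(d, "genotype"), "no features")
})

test_that("structure retention is exact for identical data and robust to 50% missingness", {
  d <- generateCohort(separatedCohort(n = 20, seed = 16))
  same <- structureRetention(d, d)
  expect_equal(same$disagreement, 0, tolerance = 1e-12)
  expect_equal(same$homogeneity_delta, 0)

  b <- runExperiment("fig21A")
  expect_lt(b$retention$disagreement, 0.05)
})
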