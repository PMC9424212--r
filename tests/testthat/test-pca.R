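test_that("noiseless simplex eigenvalues match the closed form", {
  # covariance of the 4-point simplex is 0.25*I - (1/12)*(J - I); its
  # eigenvalues are 1/3 (twice, sum-zero directions) and 1/12 (the
  # all-ones direction)
  m <- fitPCA(noiselessSimplex())
  expect_equal(m@eigenvalues, c(1/3, 1/3, 1/12), tolerance = 1e-12)
  expect_equal(sum(m@explained_fraction), 1, tolerance = 1e-10)
})

test_that("PCA agrees with a brute-force covariance eigen-decomposition", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(24), 6, 4)
    m <- fitPCA(X)
    oracle <- bruteForcePCA(X)
    expect_equal(m@eigenvalues, oracle$eigenvalues[seq_len(m@rank)],
                 tolerance = 1e-8)
    expect_columns_equal_up_to_sign(m@loadings,
                                    oracle$loadings[, seq_len(m@rank)])
  }
})

test_that("degenerate inputs are handled: identical rows, bad args", {
  flat <- ColorDataset(matrix(0.4, 5, 3), rep("X", 5))
  m <- fitPCA(flat)
  expect_equal(m@eigenvalues, rep(0, 3), tolerance = 1e-12)

  expect_error(fitPCA(ColorDataset(matrix(1, 1, 3), "X")), "two samples")
  withmiss <- injectMissingness(ColorDataset(matrix(runif(30), 10, 3),
                                             rep("X", 10)), 0.2, seed = 1)
  expect_error(fitPCA(withmiss), "missing")
})

test_that("explained variance follows the eigenvalue shares", {
  m <- fitPCA(noiselessSimplex())
  ev <- explainedVariance(m, 2)
  expect_equal(ev$fraction, 8 / 9, tolerance = 1e-12)
  expect_equal(ev$percent, 89)      # 88.9 rounds half away from zero
  expect_equal(explainedVariance(m, m@rank)$fraction, 1, tolerance = 1e-12)
  expect_error(explainedVariance(m, 4), "rank")
  expect_error(explainedVariance(m, 0), "integer")
})

test_that("the noisy four-color cohort explains ~88-89% on two PCs", {
  b <- runExperiment("fig1", seed = 123)
  expect_gte(100 * b$explained2$fraction, 87.9)
  expect_lte(100 * b$explained2$fraction, 89.9)
})

test_that("transform reproduces training scores and maps the center to 0", {
  d <- generateCohort(separatedCohort(n = 10, seed = 2))
  m <- fitPCA(d)
  expect_equal(pcaTransform(m, d), m@scores, tolerance = 1e-10)
  expect_equal(as.numeric(pcaTransform(m, m@center, k = m@rank)),
               rep(0, m@rank), tolerance = 1e-10)
  expect_error(pcaTransform(m, matrix(0, 1, 5)), "feature mismatch")
})

test_that("the Black sample sits at squared distance 2/3 from each primary in the PC plane", {
  d <- noiselessSimplex()
  m <- fitPCA(d)
  S <- m@scores[, 1:2]
  black <- S[4, ]
  for (i in 1:3)
    expect_equal(sum((S[i, ] - black)^2), 2 / 3, tolerance = 1e-10)
})

test_that("full-rank rotation preserves all pairwise distances", {
  for (seed in 1:100) {
    d <- generateCohort(randomCohort(seed))
    m <- fitPCA(d)
    orig <- dist(sampleMatrix(d))
    rot <- dist(m@scores)
    expect_lt(max(abs(orig - rot)), 1e-8)
  }
})

test_that("reconstruction error is nonincreasing in k and exact at full rank", {
  d <- generateCohort(separatedCohort(n = 8, seed = 6))
  m <- fitPCA(d)
  X <- sampleMatrix(d)
  errs <- vapply(seq_len(m@rank), function(k) {
    Xhat <- sweep(m@scores[, 1:k, drop = FALSE] %*%
                    t(m@loadings[, 1:k, drop = FALSE]), 2, m@center, `+`)
    sqrt(mean((X - Xhat)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[m@rank], 1e-8)
})

test_that("projection restricted to observed features matches the closed form", {
  d <- generateCohort(separatedCohort(n = 20, seed = 3))
  m <- fitPCA(d)

  # fully observed: identical to transform (rescale factor p/p_obs = 1)
  x <- sampleMatrix(d)[1, ]
  expect_equal(projectSample(m, x, k = 2),
               drop(pcaTransform(m, x, k = 2))[1:2], tolerance = 1e-10,
               ignore_attr = TRUE)

  # two-feature toy: observing only a feature with zero loading on PC1
  # leaves score_1 = -center_obs * loading_obs,1 exactly
  toy <- matrix(c(1, 0, 2, 0, 3, 0, 4, 0,
                  0, 1, 0, 2, 0, 3, 0, 4), ncol = 2)
  tm <- fitPCA(toy)
  j <- which.min(abs(tm@loadings[, 1]))        # feature inert on PC1
  x2 <- rep(NA_real_, 2); x2[j] <- 5
  s <- projectSample(tm, x2, k = 1, rescale = FALSE)
  expect_equal(unname(s),
               (5 - tm@center[j]) * tm@loadings[j, 1], tolerance = 1e-12)

  expect_error(projectSample(m, c(NA, NA, 1), k = 2), "observes")
})

test_that("projected cohorts drawn from the base ColorSpecs overlap the base centroids", {
  base_cc <- cohortConfig(list(colorSpec("Red", pal$Red, 0.02),
                               colorSpec("Green", pal$Green, 0.02),
                               colorSpec("Blue", pal$Blue, 0.02),
                               colorSpec("Purple", pal$Purple, 0.02)),
                          n = c(200L, 10L, 200L, 10L), seed = 21)
  proj_cc <- base_cc
  proj_cc@n <- c(200L, 200L, 10L, 10L)
  proj_cc@seed <- 22L
  base <- generateCohort(base_cc)
  proj <- generateCohort(proj_cc)
  m <- fitPCA(base)
  ps <- projectDataset(m, proj, k = 2)
  bl <- populationLabels(base); plab <- populationLabels(proj)
  for (g in unique(bl)) {
    cb <- colMeans(m@scores[bl == g, 1:2, drop = FALSE])
    cp <- colMeans(ps[plab == g, , drop = FALSE])
    n1 <- sum(bl == g); n2 <- sum(plab == g)
    se <- sqrt(2 * 0.02^2 * (1 / n1 + 1 / n2))   # 2 coords, indep noise
    expect_lt(sqrt(sum((cb - cp)^2)), 3 * se)
  }
})

test_that("PCA models serialize to text and back", {
  d <- generateCohort(separatedCohort(n = 6, seed = 8))
  m <- fitPCA(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePCAModel(m, path)
  back <- readPCAModel(path)
  expect_equal(back$center, unname(m@center), tolerance = 1e-12)
  expect_equal(unname(back$loadings), unname(m@loadings),
               tolerance = 1e-12)
  expect_equal(back$eigenvalues, m@eigenvalues, tolerance = 1e-12)
})
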