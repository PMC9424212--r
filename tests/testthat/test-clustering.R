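test_that("the square-root-of-n cluster count rounds half away from zero", {
  expect_equal(autoK(100), 10L)
  expect_equal(autoK(90), 9L)     # sqrt(90) = 9.49 rounds down
  expect_equal(autoK(91), 10L)    # sqrt(91) = 9.54 rounds up
  expect_equal(autoK(2), 1L)
  expect_equal(autoK(1), 1L)
})

test_that("well-separated colors cluster with full homogeneity", {
  d <- generateCohort(separatedCohort(n = 30, seed = 2))
  m <- fitPCA(d)
  rep3 <- clusterHomogeneity(m@scores[, 1:2], populationLabels(d), K = 3,
                             seed = 1)
  expect_equal(rep3@pct_homogeneous_clusters, 100)
  expect_equal(rep3@pct_individuals_in_homogeneous, 100)

  # a single population is homogeneous under any K
  one <- clusterHomogeneity(m@scores[1:30, 1:2], rep("Red", 30), K = 5,
                            seed = 1)
  expect_equal(one@pct_homogeneous_clusters, 100)
})

test_that("the individuals-in-homogeneous percentage is the exact size ratio", {
  d <- generateCohort(cohortConfig(
    list(colorSpec("A", c(0.2, 0.2, 0.2)), colorSpec("B", c(0.8, 0.8, 0.8)),
         colorSpec("C", c(0.2, 0.8, 0.2))),
    n = c(10, 20, 15), seed = 6))
  m <- fitPCA(d)
  r <- clusterHomogeneity(m@scores[, 1:2], populationLabels(d), K = 7,
                          seed = 3)
  expect_equal(r@pct_individuals_in_homogeneous,
               100 * sum(r@cluster_sizes[r@homogeneous]) /
                 length(r@assignments))
  expect_equal(sum(r@cluster_sizes), 45L)
  # identical call, identical partition
  r2 <- clusterHomogeneity(m@scores[, 1:2], populationLabels(d), K = 7,
                           seed = 3)
  expect_identical(r@assignments, r2@assignments)
})

test_that("overlapping populations match the exhaustive relabeling oracle", {
  # two indistinguishable populations of 6: for a fixed k-means partition
  # the expected percent of individuals in monochrome clusters over all
  # C(12,6) labelings has a hypergeometric closed form; enumerating every
  # labeling through the scoring function must reproduce it exactly
  d <- generatePopulation(colorSpec("X", c(0.5, 0.5, 0.5), 0.01), 12,
                          seed = 31)
  m <- fitPCA(d)
  S <- m@scores[, 1:2]
  K <- autoK(12)   # 3
  base <- clusterHomogeneity(S, rep(c("A", "B"), each = 6), K = K,
                             seed = 2)
  sizes <- base@cluster_sizes

  closed_form <- 100 / 12 * sum(vapply(sizes, function(s)
    s * (choose(12 - s, 6 - s) + choose(12 - s, 6)) / choose(12, 6),
    numeric(1)))

  combos <- utils::combn(12, 6)
  vals <- apply(combos, 2, function(idx) {
    lab <- rep("B", 12); lab[idx] <- "A"
    r <- clusterHomogeneity(S, lab, K = K, seed = 2)
    stopifnot(identical(r@assignments, base@assignments))
    r@pct_individuals_in_homogeneous
  })
  expect_equal(mean(vals), closed_form, tolerance = 1e-10)
})

test_that("structure confined to the top PCs is invisible on higher ones", {
  d <- generateCohort(separatedCohort(n = 40, seed = 12))
  ex <- expandWindows(d, window_size = 20, feature_noise_sd = 0.05,
                      seed = 3)
  m <- fitPCA(ex$data)
  prof <- homogeneityAcrossPCs(ex$data, m,
                               pc_pairs = list(c(1, 2), c(3, 4)),
                               seed = 5)
  expect_gte(prof[["PC1-2"]]@pct_individuals_in_homogeneous,
             prof[["PC3-4"]]@pct_individuals_in_homogeneous)
  # explicit default equivalence
  byhand <- clusterHomogeneity(m@scores[, 1:2], populationLabels(d),
                               seed = 5)
  expect_equal(prof[["PC1-2"]]@pct_individuals_in_homogeneous,
               byhand@pct_individuals_in_homogeneous)
  expect_error(homogeneityAcrossPCs(ex$data, m,
                                    pc_pairs = list(c(1, 1e4))),
               "rank")
})

test_that("mixed-size partitions report the Kruskal-Wallis size comparison", {
  set.seed(8)
  # engineered labels: some clusters pure, some mixed
  S <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20),
             matrix(rnorm(40, 20), 20))
  lab <- c(rep("A", 20), rep("A", 10), rep("B", 10), rep("B", 20))
  r <- clusterHomogeneity(S, lab, K = 3, seed = 1)
  expect_true(any(r@homogeneous) && !all(r@homogeneous))
  expect_true(is.numeric(r@size_test$p.value))
})

test_that("eroding the separation never raises expected homogeneity", {
  seps <- c(1, 0.3, 0.05)
  meanhom <- vapply(seps, function(sep) {
    hs <- vapply(1:5, function(s) {
      cc <- cohortConfig(list(colorSpec("A", c(0, 0, 0), 0.05),
                              colorSpec("B", c(sep, 0, 0) * 0.9, 0.05)),
                         n = c(25, 25), seed = s)
      d <- generateCohort(cc)
      m <- fitPCA(d)
      clusterHomogeneity(m@scores[, 1:2], populationLabels(d),
                         seed = s)@pct_individuals_in_homogeneous
    }, numeric(1))
    mean(hs)
  }, numeric(1))
  expect_true(all(diff(meanhom) <= 1e-9))
})

test_that("cluster-count preconditions are enforced", {
  expect_error(clusterHomogeneity(matrix(0, 3, 2), c("a", "b", "c"), K = 4),
               "exceeds")
})
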