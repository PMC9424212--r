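mkCohort <- function(n_red = 30L, n_blue = 10L, noise = 0.01, seed = 1L) {
  generateCohort(cohortConfig(list(colorSpec("Red", pal$Red, noise),
                                   colorSpec("Blue", pal$Blue, noise)),
                              n = c(n_red, n_blue), seed = seed))
}

test_that("label assignment builds even arms and honours the minority rule", {
  d <- mkCohort(150L, 150L)
  des <- caseControlDesign("random", seed = 3)
  y <- simulateLabels(d, des)
  expect_equal(sum(y == "case"), 150L)
  expect_identical(simulateLabels(d, des), y)

  d2 <- mkCohort(300L, 20L)
  des2 <- caseControlDesign("structured", minority = "Blue", seed = 4)
  y2 <- simulateLabels(d2, des2)
  expect_equal(sum(y2 == "control"), 160L)
  expect_true(all(y2[populationLabels(d2) == "Blue"] == "control"))

  expect_error(simulateLabels(mkCohort(10L, 30L), des2), "larger than")
  expect_error(simulateLabels(mkCohort(10L, 10L),
                              caseControlDesign("structured",
                                                minority = "Green")),
               "absent")
})

test_that("null and zero-effect causal markers are statistically alike", {
  d <- mkCohort(100L, 100L, noise = 0)
  des <- caseControlDesign("random", n_null_markers = 300L,
                           n_causal_markers = 300L, effect_size = 0,
                           structure_spread = 0, seed = 5)
  y <- simulateLabels(d, des)
  sim <- simulateMarkers(d, y, des)
  res <- associationScan(sim$genotypes, y, causal = sim$causal,
                         alpha = 0.05)
  mk <- res$markers
  # both classes reject at about alpha
  for (cls in c(TRUE, FALSE)) {
    rate <- mean(mk$significant[mk$causal == cls])
    expect_gt(rate, qbinom(0.005, 300, 0.05) / 300)
    expect_lt(rate, qbinom(0.995, 300, 0.05) / 300)
  }
})

test_that("a strong effect reaches the analytically predicted power", {
  d <- mkCohort(250L, 250L, noise = 0)
  des <- caseControlDesign("random", n_null_markers = 0L,
                           n_causal_markers = 100L, effect_size = 1,
                           structure_spread = 0, seed = 6)
  y <- simulateLabels(d, des)
  sim <- simulateMarkers(d, y, des)
  res <- associationScan(sim$genotypes, y, causal = sim$causal,
                         alpha = 0.05)
  power <- mean(res$markers$significant)
  # closed-form Wald power at the least informative base frequency
  # (f = 0.1): se = 1/sqrt(n * 2f(1-f) * 1/4), z = beta/se
  se_worst <- 1 / sqrt(500 * 2 * 0.1 * 0.9 * 0.25)
  analytic_floor <- pnorm(1 / se_worst - qnorm(0.975))
  expect_gt(analytic_floor, 0.8)
  expect_gt(power, 0.8)
})

test_that("the trend statistic matches its hand-computed value and a permutation oracle", {
  # 2x3 table - cases 10/20/10, controls 20/20/0 for dosages 0/1/2:
  # T = sum x_i (r_i - n_i/2) = 10, Var = 0.25 (120 - 60^2/80) = 8.75,
  # chi2 = 100/8.75 = 80/7
  g <- rep(c(0, 1, 2, 0, 1, 2), c(10, 20, 10, 20, 20, 0))
  y <- rep(c("case", "control"), c(40, 40))
  tt <- PCAtruth:::.trendTest(g, y)
  expect_equal(unname(tt["statistic"]), 80 / 7, tolerance = 1e-12)

  set.seed(9)
  B <- 4000
  obs <- tt["statistic"]
  perm <- replicate(B, PCAtruth:::.trendTest(g, sample(y))["statistic"])
  perm_p <- mean(perm >= obs - 1e-12)
  expect_lt(abs(perm_p - tt["p"]), 3 * sqrt(tt["p"] / B) + 1e-3)
})

test_that("logistic Wald p-values track the trend test on unadjusted scans", {
  d <- mkCohort(100L, 100L, noise = 0)
  des <- caseControlDesign("random", n_null_markers = 50L,
                           n_causal_markers = 0L, structure_spread = 0.5,
                           seed = 10)
  y <- simulateLabels(d, des)
  sim <- simulateMarkers(d, y, des)
  res <- associationScan(sim$genotypes, y)
  mk <- res$markers
  ok <- !is.na(mk$p) & !is.na(mk$trend_p)
  expect_gt(cor(-log10(mk$p[ok]), -log10(mk$trend_p[ok])), 0.99)
})

test_that("uninformative and degenerate markers behave sanely", {
  y <- rep(c("case", "control"), each = 30)
  flat <- matrix(rep(c(0, 1, 2), 20), ncol = 1)  # identical in both arms
  r <- associationScan(flat, y)
  expect_gt(r$markers$p[1], 0.9)
  expect_false(r$markers$significant[1])

  # a perfectly separating marker is flagged and excluded
  sep <- matrix(as.integer(y == "case") * 2L, ncol = 1)
  r2 <- associationScan(sep, y)
  expect_true(r2$markers$separated[1])
  expect_true(is.na(r2$markers$p[1]))
  expect_equal(r2$summary$n_tested, 0L)

  expect_error(associationScan(matrix(3, 10, 1),
                               rep(c("case", "control"), 5)), "dosages")
})

test_that("true positives do not decrease along an effect-size grid", {
  grid <- c(0.2, 0.5, 1)
  tp <- vapply(grid, function(es) {
    mean(vapply(1:3, function(s) {
      d <- mkCohort(150L, 150L, noise = 0, seed = s)
      des <- caseControlDesign("random", n_null_markers = 0L,
                               n_causal_markers = 40L, effect_size = es,
                               structure_spread = 0, seed = s)
      y <- simulateLabels(d, des)
      sim <- simulateMarkers(d, y, des)
      associationScan(sim$genotypes, y, causal = sim$causal,
                      alpha = 0.05)$summary$true_positive_count
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tp) >= 0))
})

test_that("adjustment experiments are reproducible and calibrated under the null", {
  d <- mkCohort(60L, 20L)
  ex <- expandWindows(d, window_size = 10, feature_noise_sd = 0.01,
                      seed = 2)
  des <- caseControlDesign("structured", minority = "Blue",
                           n_null_markers = 30L, n_causal_markers = 5L,
                           adjust_pcs = c(0L, 2L), seed = 12)
  r1 <- adjustmentExperiment(ex$data, des, replicates = 2L)
  r2 <- adjustmentExperiment(ex$data, des, replicates = 2L)
  expect_identical(r1$table, r2$table)
  expect_named(r1$summary$versus_unadjusted, "pc2")

  # no structure + random labels: adjusted and unadjusted both ~ alpha
  d0 <- mkCohort(100L, 100L, noise = 0)
  ex0 <- expandWindows(d0, window_size = 10, feature_noise_sd = 0.01,
                       seed = 3)
  des0 <- caseControlDesign("random", n_null_markers = 400L,
                            n_causal_markers = 0L, structure_spread = 0,
                            adjust_pcs = c(0L, 2L), seed = 13)
  r0 <- adjustmentExperiment(ex0$data, des0, replicates = 1L)
  lo <- qbinom(0.005, 400, 0.05); hi <- qbinom(0.995, 400, 0.05)
  expect_true(all(r0$table$false_positives >= lo &
                  r0$table$false_positives <= hi))
})
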