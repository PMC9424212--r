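# Shared fixtures, built in code.

pal <- colorPalette()

# Noiseless unit simplex: Red, Green, Blue, Black with zero noise.
noiselessSimplex <- function() {
  ColorDataset(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
               c("Red", "Green", "Blue", "Black"))
}

# The four-color near-perfect cohort at a given size and noise.
simplexCohort <- function(n = 1L, noise_sd = 0.01, seed = 1L) {
  cohortConfig(list(colorSpec("Red", pal$Red, noise_sd),
                    colorSpec("Green", pal$Green, noise_sd),
                    colorSpec("Blue", pal$Blue, noise_sd),
                    colorSpec("Black", pal$Black, noise_sd)),
               n = rep(n, 4), seed = seed)
}

# Three well-separated colors (centroid distances >> noise).
separatedCohort <- function(n = 30L, noise_sd = 0.01, seed = 1L) {
  cohortConfig(list(colorSpec("Red", pal$Red, noise_sd),
                    colorSpec("Green", pal$Green, noise_sd),
                    colorSpec("Blue", pal$Blue, noise_sd)),
               n = rep(n, 3), seed = seed)
}

# Random small cohort for property loops: 2-4 populations at random
# means, sizes 2-6, noise 0.01.
randomCohort <- function(seed) {
  set.seed(seed)
  npop <- sample(2:4, 1)
  specs <- lapply(seq_len(npop), function(i)
    colorSpec(paste0("P", i), stats::runif(3), 0.01))
  cohortConfig(specs, n = sample(2:6, npop, replace = TRUE), seed = seed)
}

# Brute-force PCA oracle: eigen-decomposition of the sample covariance.
bruteForcePCA <- function(X) {
  e <- eigen(stats::cov(X), symmetric = TRUE)
  list(eigenvalues = pmax(e$values, 0), loadings = e$vectors)
}

expect_columns_equal_up_to_sign <- function(A, B, tol = 1e-8) {
  expect_equal(dim(A), dim(B))
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}
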