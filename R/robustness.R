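#' Expand color components into SNP-like marker windows
#'
#' Each of the three color components is spread across a window of
#' `window_size` features (default 200, giving the 600-"SNP" construction):
#' every windowed feature repeats its source component's value, optionally
#' with fresh independent Gaussian noise per feature
#' (`feature_noise_sd > 0`), which emulates a window of noisy SNP readings
#' of the same underlying component. With `feature_noise_sd = 0` the
#' expansion is pure replication and [collapseWindows()] inverts it exactly.
#'
#' @param data a [ColorDataset-class] with 3 color-component features and no
#'   missingness.
#' @param window_size features per component (>= 1).
#' @param feature_noise_sd per-feature independent noise SD (default 0).
#' @param seed seed for the per-feature noise.
#' @return list with `data` (the n-by-3*window_size windowed
#'   [ColorDataset-class], feature class "window-snp") and `map` (integer
#'   vector mapping each windowed feature to its source component).
#' @export
expandWindows <- function(data, window_size = 200L, feature_noise_sd = 0,
                          seed = 1L) {
  stopifnot(is(data, "ColorDataset"))
  window_size <- .assertCount(window_size, "window_size")
  if (ncol(sampleMatrix(data)) != 3L)
    stop("window expansion expects the 3 color components", call. = FALSE)
  if (any(missingMask(data)))
    stop("window expansion expects complete data", call. = FALSE)
  X <- sampleMatrix(data)
  comp_of <- rep(1:3, each = window_size)
  W <- X[, comp_of, drop = FALSE]
  if (feature_noise_sd > 0)
    W <- W + withSeed(seed,
      matrix(stats::rnorm(length(W), sd = feature_noise_sd), nrow = nrow(W)))
  ids <- sprintf("%s_w%03d", c("R", "G", "B")[comp_of],
                 sequence(rep(window_size, 3)))
  out <- .makeDataset(W, populationLabels(data), feature_ids = ids,
                      feature_class = "window-snp")
  list(data = out, map = stats::setNames(comp_of, ids))
}

#' Randomly nullify matrix entries
#'
#' Marks a uniform random subset of `round(rate * n * p)` entries as
#' missing (entry-wise, no per-sample quota). Errors if any sample would be
#' left with no observed feature.
#'
#' @param data a [ColorDataset-class].
#' @param rate missingness fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return the dataset with its missing mask set.
#' @export
injectMissingness <- function(data, rate, seed = 1L) {
  stopifnot(is(data, "ColorDataset"))
  rate <- .assertFraction(rate, "rate", open_hi = TRUE)
  if (rate == 0) return(data)
  M <- missingMask(data)
  n_entries <- length(M)
  n_missing <- round(rate * n_entries)
  hit <- withSeed(seed, sample.int(n_entries, n_missing))
  M[hit] <- TRUE
  bad <- which(rowSums(!M) == 0L)
  if (length(bad))
    stop(sprintf("rate %g leaves sample(s) %s fully missing", rate,
                 paste(rownames(sampleMatrix(data))[bad], collapse = ", ")),
         call. = FALSE)
  .makeDataset(sampleMatrix(data), populationLabels(data),
               feature_ids = featureIds(data),
               feature_class = featureClass(data), missing_mask = M)
}

#' Collapse marker windows back to color components
#'
#' The reverse of [expandWindows()]: per sample and component, the mean of
#' that component's observed windowed features. Missing entries are simply
#' left out of the mean; a component with zero observed features is missing
#' in the output.
#'
#' @param data a windowed [ColorDataset-class], possibly with missingness.
#' @param map the `map` returned by [expandWindows()].
#' @return a [ColorDataset-class] with 3 color-component features.
#' @export
collapseWindows <- function(data, map) {
  stopifnot(is(data, "ColorDataset"))
  X <- sampleMatrix(data)
  M <- missingMask(data)
  if (ncol(X) != length(map))
    stop("window map does not match the dataset's features", call. = FALSE)
  n <- nrow(X)
  vals <- matrix(NA_real_, n, 3L)
  miss <- matrix(TRUE, n, 3L)
  Xobs <- X; Xobs[M] <- 0
  for (c in 1:3) {
    cols <- which(map == c)
    cnt <- rowSums(!M[, cols, drop = FALSE])
    s <- rowSums(Xobs[, cols, drop = FALSE])
    ok <- cnt > 0
    vals[ok, c] <- s[ok] / cnt[ok]
    miss[, c] <- !ok
  }
  vals[miss] <- 0   # placeholder under the mask
  .makeDataset(vals, populationLabels(data), missing_mask = miss)
}

#' Append random noise markers
#'
#' Adds `m` features whose entries are independent uniform [0, 1] draws,
#' tagged feature class "noise-marker". The fitted centering of the
#' original features is untouched (centering is per column), but the noise
#' competes with the structure for the top components.
#'
#' @param data a [ColorDataset-class].
#' @param m number of noise markers (>= 0).
#' @param seed integer seed.
#' @return the dataset with m extra features.
#' @export
addNoiseMarkers <- function(data, m, seed = 1L) {
  stopifnot(is(data, "ColorDataset"))
  if (length(m) != 1L || is.na(m) || m < 0L)
    stop("'m' must be a single nonnegative integer", call. = FALSE)
  m <- as.integer(m)
  if (m == 0L) return(data)
  X <- sampleMatrix(data)
  noise <- withSeed(seed, matrix(stats::runif(nrow(X) * m), nrow = nrow(X)))
  colnames(noise) <- sprintf("noise%04d", seq_len(m))
  .makeDataset(cbind(X, noise), populationLabels(data),
               feature_ids = c(featureIds(data), colnames(noise)),
               feature_class = c(featureClass(data), rep("noise-marker", m)),
               missing_mask = cbind(missingMask(data),
                                    matrix(FALSE, nrow(X), m)))
}

#' Add low-level noise to every marker
#'
#' Uniform `[-level/2, level/2]` perturbation of all observed entries,
#' modelling pervasive low-level measurement error (default level 0.1).
#'
#' @param data a [ColorDataset-class].
#' @param level total width of the uniform perturbation.
#' @param seed integer seed.
#' @return the perturbed dataset.
#' @export
perturbAllMarkers <- function(data, level = 0.1, seed = 1L) {
  stopifnot(is(data, "ColorDataset"))
  X <- sampleMatrix(data)
  eps <- withSeed(seed,
    matrix(stats::runif(length(X), -level / 2, level / 2), nrow = nrow(X)))
  .makeDataset(X + eps, populationLabels(data),
               feature_ids = featureIds(data),
               feature_class = featureClass(data),
               missing_mask = missingMask(data))
}

#' Subset features by class
#'
#' Selects the features carrying one or more class tags, enabling
#' per-marker-class PCA runs.
#'
#' @param data a [ColorDataset-class].
#' @param classes character vector of feature classes to keep.
#' @return the restricted dataset.
#' @export
subsetFeatureClass <- function(data, classes) {
  keep <- featureClass(data) %in% classes
  if (!any(keep)) stop("no features of the requested class", call. = FALSE)
  .makeDataset(sampleMatrix(data)[, keep, drop = FALSE],
               populationLabels(data),
               feature_ids = featureIds(data)[keep],
               feature_class = featureClass(data)[keep],
               missing_mask = missingMask(data)[, keep, drop = FALSE])
}

#' Structure retention between a reference and a perturbed dataset
#'
#' Operationalizes "the original population structure was recovered" as a
#' number: PCAs are fitted independently on the two datasets, and the
#' Procrustes disagreement between their top-k population-centroid
#' configurations is returned, together with the change in cluster
#' homogeneity. 0 disagreement means the perturbation left the structure
#' geometrically intact.
#'
#' @param data_ref,data_perturbed [ColorDataset-class] objects over the same
#'   samples and labels (both complete; collapse windows first).
#' @param k number of leading components (default 2).
#' @param seed seed for the homogeneity clustering.
#' @return list with `disagreement`, `homogeneity_ref`,
#'   `homogeneity_perturbed` and `homogeneity_delta` (percent individuals in
#'   homogeneous clusters, perturbed minus reference).
#' @export
structureRetention <- function(data_ref, data_perturbed, k = 2L, seed = 1L) {
  stopifnot(is(data_ref, "ColorDataset"), is(data_perturbed, "ColorDataset"))
  lr <- populationLabels(data_ref)
  lp <- populationLabels(data_perturbed)
  if (!identical(lr, lp))
    stop("datasets must carry identical samples and labels", call. = FALSE)
  mr <- fitPCA(data_ref)
  mp <- fitPCA(data_perturbed)
  k <- min(k, mr@rank, mp@rank)
  pops <- unique(lr)
  dis <- configurationAgreement(
    centroidConfiguration(data_ref, mr, k, pops),
    centroidConfiguration(data_perturbed, mp, k, pops))
  hr <- clusterHomogeneity(mr@scores[, seq_len(min(2L, mr@rank)),
                                     drop = FALSE], lr, seed = seed)
  hp <- clusterHomogeneity(mp@scores[, seq_len(min(2L, mp@rank)),
                                     drop = FALSE], lp, seed = seed)
  list(disagreement = dis,
       homogeneity_ref = hr@pct_individuals_in_homogeneous,
       homogeneity_perturbed = hp@pct_individuals_in_homogeneous,
       homogeneity_delta = hp@pct_individuals_in_homogeneous -
         hr@pct_individuals_in_homogeneous)
}
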