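.distanceReport <- function(pairs, k, normalized = FALSE) {
  new("DistanceReport", pairs = pairs, k = as.integer(k),
      normalized = isTRUE(normalized))
}

#' Population-centroid distances, true versus reduced space
#'
#' For every pair of population labels, computes the Euclidean distance
#' between the label centroids in the original feature space
#' (`true_distance`) and in the top-k PC score plane (`pc_distance`, raw
#' unrescaled scores). Over all r components the two coincide: centering
#' plus an orthonormal rotation preserves Euclidean geometry, so any
#' discrepancy at k < r is distortion introduced by the truncation.
#'
#' @param data the [ColorDataset-class] the model was fitted on.
#' @param model the fitted [PCAModel-class].
#' @param k number of leading components for `pc_distance` (default 2).
#' @return a [DistanceReport-class] with one row per unordered label pair.
#' @export
centroidDistances <- function(data, model, k = 2L) {
  stopifnot(is(data, "ColorDataset"), is(model, "PCAModel"))
  k <- .assertCount(k, "k")
  if (k > model@rank) stop("k exceeds the model rank", call. = FALSE)
  X <- sampleMatrix(data)
  labels <- populationLabels(data)
  if (nrow(model@scores) != nrow(X))
    stop("model was not fitted on this dataset", call. = FALSE)
  S <- model@scores[, seq_len(k), drop = FALSE]
  pops <- unique(labels)
  groupCentroids <- function(M) do.call(rbind, lapply(pops, function(g)
    colMeans(M[labels == g, , drop = FALSE])))
  ctrX <- groupCentroids(X)
  ctrS <- groupCentroids(S)
  idx <- utils::combn(length(pops), 2L)
  pairs <- data.frame(
    a = pops[idx[1L, ]], b = pops[idx[2L, ]], kind = "population",
    true_distance = sqrt(colSums((t(ctrX[idx[1L, ], , drop = FALSE]) -
                                  t(ctrX[idx[2L, ], , drop = FALSE]))^2)),
    pc_distance = sqrt(colSums((t(ctrS[idx[1L, ], , drop = FALSE]) -
                                t(ctrS[idx[2L, ], , drop = FALSE]))^2)),
    stringsAsFactors = FALSE)
  .distanceReport(pairs, k)
}

#' Random individual-pair distances
#'
#' Samples `n_pairs` distinct unordered sample pairs and records the same
#' two distances as [centroidDistances()], per pair of individuals.
#'
#' @inheritParams centroidDistances
#' @param n_pairs number of random pairs (capped at choose(n, 2) with a
#'   warning).
#' @param seed integer seed for the pair draw.
#' @return a [DistanceReport-class].
#' @export
samplePairDistances <- function(data, model, k = 2L, n_pairs = 2000L,
                                seed = 1L) {
  stopifnot(is(data, "ColorDataset"), is(model, "PCAModel"))
  k <- .assertCount(k, "k")
  n_pairs <- .assertCount(n_pairs, "n_pairs")
  X <- sampleMatrix(data)
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  total <- n * (n - 1) / 2
  if (n_pairs > total) {
    warning(sprintf("n_pairs capped at the %d distinct pairs available",
                    total))
    n_pairs <- as.integer(total)
  }
  # sample unordered pairs without replacement via their linear index
  pick <- withSeed(seed, sample.int(total, n_pairs))
  # invert the linear index of the pair (i < j)
  j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
  i <- pick - (j - 1) * (j - 2) / 2
  S <- model@scores[, seq_len(k), drop = FALSE]
  ids <- rownames(X)
  pairs <- data.frame(
    a = ids[i], b = ids[j], kind = "individual",
    true_distance = sqrt(rowSums((X[i, , drop = FALSE] -
                                  X[j, , drop = FALSE])^2)),
    pc_distance = sqrt(rowSums((S[i, , drop = FALSE] -
                                S[j, , drop = FALSE])^2)),
    stringsAsFactors = FALSE)
  .distanceReport(pairs, k)
}

#' Min-max normalize a distance report
#'
#' Applies min-max normalization independently to the true and PC distance
#' columns, mapping each to `[0, 1]` (min to 0, max to 1). Affine
#' transformations of a column do not change its normalized form.
#'
#' @param report a [DistanceReport-class] with at least two distinct values
#'   per column.
#' @return the report with `true_norm` and `pc_norm` columns added.
#' @export
normalizeReport <- function(report) {
  stopifnot(is(report, "DistanceReport"))
  norm1 <- function(d, what) {
    r <- range(d)
    if (diff(r) == 0)
      stop(sprintf("%s is constant; min-max normalization undefined", what),
           call. = FALSE)
    (d - r[1]) / diff(r)
  }
  pairs <- report@pairs
  pairs$true_norm <- norm1(pairs$true_distance, "true_distance")
  pairs$pc_norm <- norm1(pairs$pc_distance, "pc_distance")
  .distanceReport(pairs, report@k, normalized = TRUE)
}

#' Summarize distance distortion
#'
#' A pair is "correctly projected" when its reduced-space distance is within
#' `tolerance` of its true distance (on the normalized columns when present,
#' else the raw ones). Also reports the maximum absolute distortion and the
#' worst pair.
#'
#' @param report a [DistanceReport-class].
#' @param tolerance admissible |pc - true| (default 0.05, in normalized
#'   units when the report is normalized).
#' @param use_normalized use the normalized columns (default: yes when
#'   available).
#' @return list with `fraction_correct`, `n_correct`, `max_distortion`,
#'   `worst_pair` (one-row data.frame) and the per-pair `distortion` vector.
#' @export
distortionSummary <- function(report, tolerance = 0.05,
                              use_normalized = report@normalized) {
  stopifnot(is(report, "DistanceReport"))
  p <- report@pairs
  d <- if (use_normalized) {
    if (!report@normalized)
      stop("report is not normalized; run normalizeReport() first",
           call. = FALSE)
    p$pc_norm - p$true_norm
  } else p$pc_distance - p$true_distance
  ok <- abs(d) <= tolerance
  list(fraction_correct = mean(ok), n_correct = sum(ok),
       max_distortion = max(abs(d)),
       worst_pair = p[which.max(abs(d)), , drop = FALSE],
       distortion = d)
}

#' Procrustes disagreement between two score configurations
#'
#' Measures whether two PCA outcomes describe the same geometry: after
#' optimal translation, rotation/reflection and scaling (symmetric
#' Procrustes, via \pkg{vegan}), returns the symmetric Procrustes sum of
#' squares m^2_12 -- the standard ordination-comparison statistic,
#' dimensionless in [0, 1]. 0 means identical geometry; sign flips and
#' axis swaps are absorbed.
#'
#' @param scores_a,scores_b matrices with matching row counts (rows =
#'   entities, columns = coordinates).
#' @return single nonnegative disagreement score.
#' @export
configurationAgreement <- function(scores_a, scores_b) {
  A <- as.matrix(scores_a); B <- as.matrix(scores_b)
  if (nrow(A) != nrow(B))
    stop("configurations must have the same number of rows", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("configurations must have the same number of columns",
         call. = FALSE)
  pr <- vegan::procrustes(A, B, symmetric = TRUE)
  unname(pr$ss)
}

#' Centroid configuration of a dataset in PC space
#'
#' Helper assembling the per-population centroid matrix of the top-k scores
#' of a fitted model, ordered by `pops` so configurations from different
#' cohorts are comparable.
#'
#' @inheritParams centroidDistances
#' @param pops population order (default: order of appearance).
#' @return length(pops)-by-k centroid matrix.
#' @export
centroidConfiguration <- function(data, model, k = 2L, pops = NULL) {
  labels <- populationLabels(data)
  if (is.null(pops)) pops <- unique(labels)
  S <- model@scores[, seq_len(k), drop = FALSE]
  cfg <- do.call(rbind, lapply(pops, function(g)
    colMeans(S[labels == g, , drop = FALSE])))
  rownames(cfg) <- pops
  cfg
}
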