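#' Number of k-means clusters from the sample size
#'
#' The cluster count convention: K is the square root of the number of
#' samples, rounded half away from zero, with a floor of 1.
#'
#' @param n sample count.
#' @return integer K.
#' @examples
#' autoK(100)  # 10
#' autoK(90)   # 9 (sqrt = 9.49 rounds down)
#' @export
autoK <- function(n) {
  n <- .assertCount(n, "n")
  max(1L, as.integer(roundHalfUp(sqrt(n))))
}

#' k-means cluster homogeneity
#'
#' Runs k-means (squared-Euclidean objective, best inertia over `restarts`
#' starts) on the supplied score columns and scores the partition against
#' the true population labels: a cluster is homogeneous iff all of its
#' members share one label. Reports the percentage of homogeneous clusters,
#' the percentage of individuals sitting in them, and the mean sizes of the
#' two cluster groups together with a Kruskal-Wallis comparison of the size
#' distributions. Singleton clusters are vacuously monochrome; they count
#' as homogeneous but are tallied separately because they inflate the
#' metric.
#'
#' @param scores n-by-k numeric score matrix (e.g. `model@scores[, 1:2]`).
#' @param labels length-n population labels.
#' @param K cluster count, or `"auto"` for [autoK()] of n.
#' @param seed integer seed controlling the k-means starts.
#' @param restarts number of random starts (default 20).
#' @param pcs_used bookkeeping: which score columns these are.
#' @return a [ClusterReport-class].
#' @export
clusterHomogeneity <- function(scores, labels, K = "auto", seed = 1L,
                               restarts = 20L, pcs_used = seq_len(ncol(scores))) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  n <- nrow(scores)
  stopifnot(length(labels) == n)
  if (identical(K, "auto")) K <- autoK(n)
  K <- .assertCount(K, "K")
  if (K > n) stop(sprintf("K = %d exceeds n = %d", K, n), call. = FALSE)
  restarts <- .assertCount(restarts, "restarts")

  assignments <- if (K == 1L) rep(1L, n) else withSeed(seed,
    stats::kmeans(scores, centers = K, nstart = restarts,
                  iter.max = 100L)$cluster)
  sizes <- tabulate(assignments, nbins = K)
  homog <- vapply(seq_len(K), function(c)
    length(unique(labels[assignments == c])) == 1L, logical(1))
  homog[sizes == 0L] <- FALSE   # an empty cluster is not a cluster
  present <- sizes > 0L
  n_hom <- sum(homog[present])
  n_clusters <- sum(present)
  size_test <- list()
  if (n_hom > 0 && n_hom < n_clusters) {
    grp <- factor(ifelse(homog[present], "homogeneous", "other"))
    kw <- stats::kruskal.test(sizes[present], grp)
    size_test <- list(statistic = unname(kw$statistic),
                      p.value = kw$p.value)
  }
  new("ClusterReport",
      K = K, assignments = as.integer(assignments), labels = labels,
      homogeneous = homog, cluster_sizes = as.integer(sizes),
      pct_homogeneous_clusters = 100 * n_hom / n_clusters,
      pct_individuals_in_homogeneous =
        100 * sum(sizes[homog]) / n,
      mean_size_homogeneous = mean(sizes[present & homog]),
      mean_size_nonhomogeneous = mean(sizes[present & !homog]),
      n_singleton_homogeneous = sum(homog & sizes == 1L),
      pcs_used = as.integer(pcs_used), seed = as.integer(seed),
      restarts = restarts, size_test = size_test)
}

#' Homogeneity profile across PC pairs
#'
#' Recomputes [clusterHomogeneity()] on successive score-column pairs of a
#' fitted model, e.g. `list(c(1, 2), c(3, 4))`, to profile how cluster
#' homogeneity degrades on higher components.
#'
#' @param data the [ColorDataset-class] the model was fitted on.
#' @param model a [PCAModel-class].
#' @param pc_pairs list of integer index vectors (usually pairs).
#' @param ... passed to [clusterHomogeneity()].
#' @return named list of [ClusterReport-class], one per entry of `pc_pairs`.
#' @export
homogeneityAcrossPCs <- function(data, model, pc_pairs = list(c(1L, 2L)),
                                 ...) {
  stopifnot(is(data, "ColorDataset"), is(model, "PCAModel"))
  labels <- populationLabels(data)
  out <- lapply(pc_pairs, function(pcs) {
    pcs <- as.integer(pcs)
    if (max(pcs) > model@rank)
      stop(sprintf("PC index %d exceeds the model rank %d", max(pcs),
                   model@rank), call. = FALSE)
    clusterHomogeneity(model@scores[, pcs, drop = FALSE], labels,
                       pcs_used = pcs, ...)
  })
  names(out) <- vapply(pc_pairs, function(p)
    paste0("PC", paste(p, collapse = "-")), character(1))
  out
}
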