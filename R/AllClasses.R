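#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ColorSpec: a ground-truth synthetic population
#'
#' A color population is a point in the RGB unit cube \eqn{[0,1]^3} together
#' with a Gaussian noise scale. Individuals drawn from the population are the
#' mean vector plus independent N(0, noise_sd^2) noise on each of the three
#' components; the components play the role of SNPs, and the point itself is
#' the population's true, unambiguous location in feature space.
#'
#' @slot name single character label, e.g. "Red".
#' @slot mean numeric length-3 vector with components in [0, 1].
#' @slot noise_sd single nonnegative numeric, the noise scale N.
#'
#' @seealso [colorSpec()], [generatePopulation()], [eraSpec()]
#' @exportClass ColorSpec
setClass("ColorSpec",
  representation(name = "character", mean = "numeric", noise_sd = "numeric"))

setValidity("ColorSpec", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@mean) != 3L || anyNA(object@mean))
    msg <- c(msg, "'mean' must be a numeric 3-vector")
  else if (any(object@mean < 0) || any(object@mean > 1))
    msg <- c(msg, "'mean' components must lie in [0, 1]")
  if (length(object@noise_sd) != 1L || is.na(object@noise_sd) ||
      object@noise_sd < 0)
    msg <- c(msg, "'noise_sd' must be a single nonnegative number")
  if (is.null(msg)) TRUE else msg
})

#' CohortConfig: an ordered set of color populations with sample sizes
#'
#' Declares a synthetic cohort: which populations to draw, how many
#' individuals from each (in order), and the root seed from which each
#' population's private random stream is derived.
#'
#' @slot specs list of [ColorSpec-class] objects, in cohort order.
#' @slot n integer vector of per-population sample sizes (all >= 1).
#' @slot seed single integer root seed.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(specs = "list", n = "integer", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (length(object@specs) == 0L)
    msg <- c(msg, "cohort must contain at least one population")
  if (!all(vapply(object@specs, is, logical(1), "ColorSpec")))
    msg <- c(msg, "'specs' must be a list of ColorSpec objects")
  if (length(object@n) != length(object@specs))
    msg <- c(msg, "'n' must have one entry per population")
  if (anyNA(object@n) || any(object@n < 1L))
    msg <- c(msg, "every sample size must be a positive integer")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (is.null(msg)) TRUE else msg
})

#' ColorDataset: a labeled sample-by-feature matrix
#'
#' The common currency of the package: real-valued measurements for n samples
#' over p features, with a population label per sample, a class tag per
#' feature ("color-component", "window-snp", "noise-marker" or "genotype"),
#' and an explicit missingness mask. Internally a
#' [SummarizedExperiment::SummarizedExperiment] with a features-by-samples
#' `"values"` assay and a logical `"missing"` assay; user-facing accessors
#' return the conventional samples-by-features orientation.
#'
#' @seealso [ColorDataset()], [sampleMatrix()], [populationLabels()],
#'   [missingMask()], [featureClass()]
#' @exportClass ColorDataset
setClass("ColorDataset", contains = "SummarizedExperiment")

.FEATURE_CLASSES <- c("color-component", "window-snp", "noise-marker",
                      "genotype")

setValidity("ColorDataset", function(object) {
  msg <- NULL
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "missing") %in% a))
    return("assays 'values' and 'missing' are required")
  vals <- SummarizedExperiment::assay(object, "values")
  miss <- SummarizedExperiment::assay(object, "missing")
  if (!is.logical(miss) || !identical(dim(vals), dim(miss)))
    msg <- c(msg, "'missing' must be a logical matrix matching 'values'")
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry a 'population' column")
  rd <- SummarizedExperiment::rowData(object)
  if (!"feature_class" %in% colnames(rd))
    msg <- c(msg, "rowData must carry a 'feature_class' column")
  else if (!all(rd$feature_class %in% .FEATURE_CLASSES))
    msg <- c(msg, sprintf("feature_class entries must be one of: %s",
                          paste(.FEATURE_CLASSES, collapse = ", ")))
  if (is.logical(miss) && ncol(miss) > 0 && any(colSums(!miss) == 0L))
    msg <- c(msg, "every sample must observe at least one feature")
  if ("feature_class" %in% colnames(rd)) {
    g <- rd$feature_class == "genotype"
    if (any(g)) {
      obs <- vals[g, , drop = FALSE][!miss[g, , drop = FALSE]]
      if (length(obs) && !all(obs %in% c(0, 1, 2)))
        msg <- c(msg, "observed genotype dosages must be 0, 1 or 2")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' PCAModel: a fitted principal component basis
#'
#' Holds the centering vector, orthonormal loadings, sample-covariance
#' eigenvalues (SVD of the centered matrix with n-1 normalization),
#' per-component explained-variance fractions, and the training scores.
#'
#' @slot center length-p feature means used for centering.
#' @slot loadings p-by-r orthonormal matrix; columns are components.
#' @slot eigenvalues length-r nonincreasing nonnegative reals.
#' @slot explained_fraction length-r fractions summing to one.
#' @slot scores n-by-r training coordinates, `(X - center) %*% loadings`.
#' @slot rank number of components retained.
#' @slot feature_ids feature identifiers matching `center`.
#' @slot labels training-sample population labels (for centroid reports).
#' @slot scaled logical; was per-feature variance scaling applied (off by
#'   default, matching SmartPCA run without normalization).
#'
#' @seealso [fitPCA()], [pcaTransform()], [projectSample()]
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", explained_fraction = "numeric",
                 scores = "matrix", rank = "integer",
                 feature_ids = "character", labels = "character",
                 scaled = "logical"))

setValidity("PCAModel", function(object) {
  msg <- NULL
  p <- length(object@center)
  r <- object@rank
  if (!identical(dim(object@loadings), c(p, as.integer(r))))
    msg <- c(msg, "'loadings' must be p-by-r")
  if (length(object@eigenvalues) != r ||
      is.unsorted(rev(object@eigenvalues)) || any(object@eigenvalues < -1e-12))
    msg <- c(msg, "'eigenvalues' must be nonincreasing and nonnegative")
  if (ncol(object@scores) != r)
    msg <- c(msg, "'scores' must have r columns")
  if (nrow(object@scores) != length(object@labels))
    msg <- c(msg, "'labels' must match the training rows")
  if (r > 0) {
    ctc <- crossprod(object@loadings)
    if (max(abs(ctc - diag(r))) > 1e-10)
      msg <- c(msg, "loadings are not orthonormal (tolerance 1e-10)")
  }
  if (is.null(msg)) TRUE else msg
})

#' DistanceReport: true-space versus reduced-space distances
#'
#' Per-pair records of the Euclidean distance in the original feature space
#' (`true_distance`) and in the top-k principal-component plane
#' (`pc_distance`), optionally min-max normalized per column.
#'
#' @slot pairs data.frame with columns a, b, kind, true_distance,
#'   pc_distance and, after [normalizeReport()], true_norm and pc_norm.
#' @slot k number of components used for `pc_distance`.
#' @slot normalized logical flag.
#'
#' @seealso [centroidDistances()], [samplePairDistances()],
#'   [normalizeReport()], [distortionSummary()]
#' @exportClass DistanceReport
setClass("DistanceReport",
  representation(pairs = "data.frame", k = "integer", normalized = "logical"))

setValidity("DistanceReport", function(object) {
  msg <- NULL
  need <- c("a", "b", "kind", "true_distance", "pc_distance")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, sprintf("'pairs' must have columns %s",
                          paste(need, collapse = ", ")))
  else if (any(object@pairs$true_distance < 0) ||
           any(object@pairs$pc_distance < 0))
    msg <- c(msg, "distances must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' ClusterReport: k-means homogeneity summary
#'
#' The partition produced by k-means on selected PC score columns, with the
#' homogeneity bookkeeping: a cluster is homogeneous iff all of its members
#' carry the same population label.
#'
#' @slot K number of clusters requested.
#' @slot assignments integer cluster id per sample.
#' @slot labels population label per sample.
#' @slot homogeneous logical flag per cluster.
#' @slot cluster_sizes integer size per cluster.
#' @slot pct_homogeneous_clusters percent of clusters that are homogeneous.
#' @slot pct_individuals_in_homogeneous percent of samples sitting in
#'   homogeneous clusters.
#' @slot mean_size_homogeneous,mean_size_nonhomogeneous mean cluster sizes
#'   (NaN when a group is empty).
#' @slot n_singleton_homogeneous singleton clusters counted as homogeneous
#'   (vacuously monochrome; they inflate the metric).
#' @slot pcs_used score columns the clustering ran on.
#' @slot seed,restarts the k-means randomization policy.
#' @slot size_test Kruskal-Wallis comparison of homogeneous vs
#'   non-homogeneous cluster sizes (list; empty when not computable).
#'
#' @seealso [clusterHomogeneity()], [autoK()], [homogeneityAcrossPCs()]
#' @exportClass ClusterReport
setClass("ClusterReport",
  representation(K = "integer", assignments = "integer", labels = "character",
                 homogeneous = "logical", cluster_sizes = "integer",
                 pct_homogeneous_clusters = "numeric",
                 pct_individuals_in_homogeneous = "numeric",
                 mean_size_homogeneous = "numeric",
                 mean_size_nonhomogeneous = "numeric",
                 n_singleton_homogeneous = "integer",
                 pcs_used = "integer", seed = "integer", restarts = "integer",
                 size_test = "list"))

setValidity("ClusterReport", function(object) {
  msg <- NULL
  if (sum(object@cluster_sizes) != length(object@assignments))
    msg <- c(msg, "cluster sizes must sum to n")
  if (length(object@homogeneous) != length(object@cluster_sizes))
    msg <- c(msg, "one homogeneity flag per cluster required")
  pc <- c(object@pct_homogeneous_clusters,
          object@pct_individuals_in_homogeneous)
  if (any(pc < 0 | pc > 100))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (is.null(msg)) TRUE else msg
})

#' CaseControlDesign: configuration of a stratified association experiment
#'
#' @slot labeling "structured" (one designated minority population entirely
#'   controls, the rest split at random into even arms) or "random".
#' @slot minority population label forced into the control arm under
#'   structured labeling (ignored otherwise; may be NA).
#' @slot n_null_markers,n_causal_markers marker counts.
#' @slot effect_size per-allele log-odds separation between arms for causal
#'   markers.
#' @slot structure_spread logit-scale coupling between a population's color
#'   mean and its marker frequencies; 0 removes structure from the markers.
#' @slot adjust_pcs PC-adjustment levels to compare (0 = unadjusted).
#' @slot alpha per-marker significance threshold.
#' @slot seed root seed.
#'
#' @seealso [caseControlDesign()], [simulateLabels()], [simulateMarkers()],
#'   [associationScan()], [adjustmentExperiment()]
#' @exportClass CaseControlDesign
setClass("CaseControlDesign",
  representation(labeling = "character", minority = "character",
                 n_null_markers = "integer", n_causal_markers = "integer",
                 effect_size = "numeric", structure_spread = "numeric",
                 adjust_pcs = "integer", alpha = "numeric", seed = "integer"))

setValidity("CaseControlDesign", function(object) {
  msg <- NULL
  if (!object@labeling %in% c("structured", "random"))
    msg <- c(msg, "'labeling' must be \"structured\" or \"random\"")
  if (object@labeling == "structured" &&
      (length(object@minority) != 1L || is.na(object@minority)))
    msg <- c(msg, "structured labeling needs a 'minority' population")
  if (!is.finite(object@effect_size))
    msg <- c(msg, "'effect_size' must be finite")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  if (any(object@adjust_pcs < 0))
    msg <- c(msg, "'adjust_pcs' entries must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' ExperimentSpec: a registered synthetic test case
#'
#' A declarative description of one of the package's ready-made experiments:
#' the cohort to generate, the analysis stages to run, and any stage
#' parameters. See [experimentRegistry()].
#'
#' @slot id registry tag, e.g. "fig1".
#' @slot description one-line human-readable summary.
#' @slot cohort a [CohortConfig-class].
#' @slot stages character vector of stage names, executed in order
#'   (subset of "pca", "centroid_distances", "pair_distances", "cluster",
#'   "expand_missing", "noise_markers", "project", "gwas").
#' @slot params named list of stage parameters.
#' @slot ambiguous TRUE when the source description pinned sizes or colors
#'   only as a range and the registry chose one assignment.
#'
#' @exportClass ExperimentSpec
setClass("ExperimentSpec",
  representation(id = "character", description = "character",
                 cohort = "CohortConfig", stages = "character",
                 params = "list", ambiguous = "logical"))
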