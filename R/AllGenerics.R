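#' Accessors for ColorDataset
#'
#' `sampleMatrix()` returns the samples-by-features value matrix,
#' `missingMask()` the matching logical mask (TRUE = absent),
#' `populationLabels()` the per-sample labels, `featureIds()` and
#' `featureClass()` the feature metadata.
#'
#' @param x a [ColorDataset-class].
#' @return matrix, logical matrix or character vector as described.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))

#' @rdname dataset-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname dataset-accessors
#' @export
setGeneric("populationLabels",
           function(x) standardGeneric("populationLabels"))

#' @rdname dataset-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname dataset-accessors
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))

#' @rdname dataset-accessors
#' @export
setMethod("sampleMatrix", "ColorDataset", function(x)
  t(SummarizedExperiment::assay(x, "values")))

#' @rdname dataset-accessors
#' @export
setMethod("missingMask", "ColorDataset", function(x)
  t(SummarizedExperiment::assay(x, "missing")))

#' @rdname dataset-accessors
#' @export
setMethod("populationLabels", "ColorDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$population))

#' @rdname dataset-accessors
#' @export
setMethod("featureIds", "ColorDataset", function(x) rownames(x))

#' @rdname dataset-accessors
#' @export
setMethod("featureClass", "ColorDataset", function(x)
  as.character(SummarizedExperiment::rowData(x)$feature_class))

setMethod("show", "ColorSpec", function(object) {
  cat(sprintf("ColorSpec '%s': mean [%s], noise_sd %g\n", object@name,
              paste(format(object@mean), collapse = ", "), object@noise_sd))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d populations, %d samples, seed %d\n",
              length(object@specs), sum(object@n), object@seed))
  for (i in seq_along(object@specs))
    cat(sprintf("  %-10s n = %-5d mean [%s], sd %g\n",
                object@specs[[i]]@name, object@n[i],
                paste(format(object@specs[[i]]@mean), collapse = ", "),
                object@specs[[i]]@noise_sd))
})

setMethod("show", "ColorDataset", function(object) {
  lab <- populationLabels(object)
  cat(sprintf("ColorDataset: %d samples x %d features (%s)\n",
              ncol(object), nrow(object),
              paste(unique(featureClass(object)), collapse = ", ")))
  tt <- table(factor(lab, levels = unique(lab)))
  cat("  populations:",
      paste(sprintf("%s(%d)", names(tt), tt), collapse = ", "), "\n")
  nm <- sum(SummarizedExperiment::assay(object, "missing"))
  if (nm > 0)
    cat(sprintf("  missing entries: %d (%.1f%%)\n", nm,
                100 * nm / prod(dim(object))))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d features, %d samples, rank %d\n",
              length(object@center), nrow(object@scores), object@rank))
  k <- min(object@rank, 5L)
  cat("  explained fraction:",
      paste(sprintf("PC%d %.3f", seq_len(k), object@explained_fraction[1:k]),
            collapse = ", "),
      if (object@rank > k) "..." else "", "\n")
})

setMethod("show", "DistanceReport", function(object) {
  cat(sprintf("DistanceReport: %d pairs, k = %d%s\n", nrow(object@pairs),
              object@k, if (object@normalized) ", min-max normalized" else ""))
  print(utils::head(object@pairs, 6))
  if (nrow(object@pairs) > 6) cat("  ...\n")
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf(
    "ClusterReport: K = %d, %.1f%% clusters homogeneous, %.1f%% individuals\n",
    object@K, object@pct_homogeneous_clusters,
    object@pct_individuals_in_homogeneous))
  cat(sprintf("  mean size homogeneous %.2f, non-homogeneous %.2f; %d singleton homogeneous\n",
              object@mean_size_homogeneous, object@mean_size_nonhomogeneous,
              object@n_singleton_homogeneous))
})

setMethod("show", "CaseControlDesign", function(object) {
  cat(sprintf(
    "CaseControlDesign: %s labeling, %d null + %d causal markers, effect %g\n",
    object@labeling, object@n_null_markers, object@n_causal_markers,
    object@effect_size))
  cat(sprintf("  adjust_pcs {%s}, alpha %g, seed %d\n",
              paste(object@adjust_pcs, collapse = ", "), object@alpha,
              object@seed))
})

setMethod("show", "ExperimentSpec", function(object) {
  cat(sprintf("ExperimentSpec '%s'%s: %s\n", object@id,
              if (object@ambiguous) " [ambiguous sizes pinned]" else "",
              object@description))
  show(object@cohort)
  cat("  stages:", paste(object@stages, collapse = " -> "), "\n")
})
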