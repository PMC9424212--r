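#' Dataset TSV round trip
#'
#' Writes a [ColorDataset-class] as a tab-separated table (sample_id,
#' population, one column per feature; missing entries as NA) for
#' inspection, and reads it back.
#'
#' @param data a [ColorDataset-class].
#' @param path file path.
#' @param feature_class class tag to restore on read (a single tag or one
#'   per feature).
#' @return `readDatasetTSV` returns the reconstructed dataset.
#' @export
writeDatasetTSV <- function(data, path) {
  X <- sampleMatrix(data)
  X[missingMask(data)] <- NA
  tab <- data.frame(sample_id = rownames(X),
                    population = populationLabels(data), X,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetTSV
#' @export
readDatasetTSV <- function(path, feature_class = "color-component") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -(1:2), drop = FALSE])
  .makeDataset(ifelse(is.na(X), 0, X), tab$population,
               feature_ids = colnames(X), feature_class = feature_class,
               missing_mask = is.na(X))
}

#' Cohort configs as declarative YAML
#'
#' A cohort config serializes to a small YAML document: a `seed` and a list
#' of `populations`, each with `name`, `mean` (RGB triple), `noise_sd` and `size`.
#'
#' @param config a [CohortConfig-class].
#' @param path file path.
#' @return `readCohortConfig` returns the [CohortConfig-class].
#' @export
writeCohortConfig <- function(config, path) {
  doc <- list(seed = config@seed,
              populations = lapply(seq_along(config@specs), function(i) {
                s <- config@specs[[i]]
                list(name = s@name, mean = as.numeric(s@mean),
                     noise_sd = s@noise_sd, size = config@n[i])
              }))
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  specs <- lapply(doc$populations, function(p)
    colorSpec(p$name, unlist(p$mean), p$noise_sd))
  cohortConfig(specs, n = vapply(doc$populations, function(p)
    as.integer(p$size), integer(1)), seed = doc$seed)
}
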