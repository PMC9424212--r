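#' Construct a ColorSpec
#'
#' @param name population label.
#' @param mean numeric length-3 RGB mean in `[0,1]`.
#' @param noise_sd Gaussian noise scale (per draw, per component); default
#'   0.01, the value used in almost all synthetic analyses.
#' @return a [ColorSpec-class] object.
#' @examples
#' colorSpec("Red", c(1, 0, 0))
#' @export
colorSpec <- function(name, mean, noise_sd = 0.01) {
  new("ColorSpec", name = as.character(name), mean = as.numeric(mean),
      noise_sd = as.numeric(noise_sd))
}

# Canonical palette: unit 0/1 patterns for the primary and secondary color
# directions plus the grey axis. eraSpec() brightens/darkens these patterns.
.PALETTE <- list(
  Red    = c(1, 0, 0),
  Green  = c(0, 1, 0),
  Blue   = c(0, 0, 1),
  Black  = c(0, 0, 0),
  White  = c(1, 1, 1),
  Cyan   = c(0, 1, 1),
  Purple = c(1, 0, 1),
  Yellow = c(1, 1, 0),
  Grey   = c(0.5, 0.5, 0.5)
)

#' Canonical color directions
#'
#' Named list of the built-in RGB patterns (primaries, secondaries, Black,
#' White, Grey) used by [eraSpec()] and the experiment registry.
#' @return named list of numeric 3-vectors.
#' @export
colorPalette <- function() .PALETTE

#' Derive an "ancient" or "modern" variant of a canonical color
#'
#' Ancient populations are modeled as brighter colors: every nonzero
#' component of the base pattern is set to 0.95 and the noise SD to 0.05.
#' Modern populations are darker: nonzero components 0.6, noise SD 0.02
#' (e.g. modern Red is the dark Red `[0.6, 0, 0]`). Zero components stay
#' zero, so Black has no brightness to gain and only its noise changes.
#' The era SD applies to all three dimensions.
#'
#' @param base_name a name from [colorPalette()].
#' @param era `"ancient"` or `"modern"`.
#' @return a [ColorSpec-class] named e.g. `"aRed"` or `"mRed"`.
#' @examples
#' eraSpec("Red", "ancient")   # mean (0.95, 0, 0), sd 0.05
#' eraSpec("Red", "modern")    # mean (0.60, 0, 0), sd 0.02
#' @export
eraSpec <- function(base_name, era = c("ancient", "modern")) {
  era <- match.arg(era)
  base <- .PALETTE[[base_name]]
  if (is.null(base))
    stop(sprintf("unknown base color '%s'; see colorPalette()", base_name),
         call. = FALSE)
  if (!all(base %in% c(0, 1)))
    stop(sprintf("'%s' is not a unit 0/1 color pattern", base_name),
         call. = FALSE)
  level <- if (era == "ancient") 0.95 else 0.6
  sd    <- if (era == "ancient") 0.05 else 0.02
  prefix <- if (era == "ancient") "a" else "m"
  colorSpec(paste0(prefix, base_name), base * level, sd)
}

#' Construct a CohortConfig
#'
#' @param members list of `list(spec, n)` pairs, or a list of
#'   [ColorSpec-class] objects combined with the `n` vector.
#' @param n integer vector of sample sizes (used when `members` is a plain
#'   list of ColorSpecs).
#' @param seed root seed; each member population receives a private child
#'   seed derived from `(seed, member index, member name)`, so appending a
#'   population never changes the draws of earlier ones.
#' @return a [CohortConfig-class].
#' @examples
#' cohortConfig(list(colorSpec("Red", c(1, 0, 0)),
#'                   colorSpec("Black", c(0, 0, 0))), n = c(10, 10), seed = 1)
#' @export
cohortConfig <- function(members, n = NULL, seed = 1L) {
  if (is.null(n)) {
    specs <- lapply(members, `[[`, 1L)
    n <- vapply(members, function(m) as.integer(m[[2L]]), integer(1))
  } else {
    specs <- members
  }
  new("CohortConfig", specs = specs, n = as.integer(n),
      seed = as.integer(seed))
}

.makeDataset <- function(values, labels, feature_ids = NULL,
                         feature_class = NULL, missing_mask = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(feature_ids))
    feature_ids <- if (p == 3L) c("R", "G", "B") else paste0("f", seq_len(p))
  if (is.null(feature_class))
    feature_class <- rep("color-component", p)
  if (length(feature_class) == 1L) feature_class <- rep(feature_class, p)
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, n, p)
  sample_ids <- sprintf("s%04d_%s", seq_len(n), labels)
  vals <- t(values); miss <- t(missing_mask)
  dimnames(vals) <- list(feature_ids, sample_ids)
  dimnames(miss) <- dimnames(vals)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = vals, missing = miss),
    colData = S4Vectors::DataFrame(population = as.character(labels),
                                   row.names = sample_ids),
    rowData = S4Vectors::DataFrame(feature_class = as.character(feature_class),
                                   row.names = feature_ids))
  new("ColorDataset", se)
}

#' Construct a ColorDataset from a samples-by-features matrix
#'
#' @param values n-by-p numeric matrix (samples in rows).
#' @param labels length-n population labels.
#' @param feature_ids optional feature identifiers.
#' @param feature_class feature class tag(s): "color-component",
#'   "window-snp", "noise-marker" or "genotype".
#' @param missing_mask optional n-by-p logical matrix, TRUE = absent.
#' @return a [ColorDataset-class].
#' @export
ColorDataset <- function(values, labels, feature_ids = NULL,
                         feature_class = NULL, missing_mask = NULL) {
  .makeDataset(values, labels, feature_ids, feature_class, missing_mask)
}

#' Draw one synthetic color population
#'
#' Each individual is `spec@mean + R * spec@noise_sd`, with `R` a fresh
#' 3-vector of standard-normal draws. Values are deliberately not clipped to
#' `[0,1]`: clipping would halve the noise on boundary components and bias
#' the population centroids.
#'
#' @param spec a [ColorSpec-class].
#' @param n number of individuals (>= 1).
#' @param seed integer seed; identical `(spec, n, seed)` give bit-identical
#'   output.
#' @return a [ColorDataset-class] with n rows and 3 color-component features.
#' @examples
#' d <- generatePopulation(colorSpec("Red", c(1, 0, 0), 0), n = 2, seed = 1)
#' sampleMatrix(d)   # exactly (1, 0, 0) twice: zero noise
#' @export
generatePopulation <- function(spec, n, seed = 1L) {
  stopifnot(is(spec, "ColorSpec"))
  n <- .assertCount(n, "n")
  values <- withSeed(seed, {
    noise <- matrix(stats::rnorm(n * 3L), nrow = n, ncol = 3L)
    sweep(noise * spec@noise_sd, 2L, spec@mean, `+`)
  })
  .makeDataset(values, rep(spec@name, n))
}

#' Generate a multi-population cohort
#'
#' Row-block concatenation of [generatePopulation()] outputs in member
#' order. Each member draws from its own child seed derived from
#' `(config@seed, index, name)`, so the draws for population i do not depend
#' on which other populations are present.
#'
#' @param config a [CohortConfig-class].
#' @return a [ColorDataset-class] with `sum(config@n)` rows.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  parts <- lapply(seq_along(config@specs), function(i) {
    spec <- config@specs[[i]]
    child <- deriveSeed(config@seed, i, spec@name)
    sampleMatrix(generatePopulation(spec, config@n[i], child))
  })
  labels <- rep(vapply(config@specs, slot, character(1), "name"), config@n)
  .makeDataset(do.call(rbind, parts), labels)
}
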