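# Registry of the package's ready-made synthetic test cases. Each entry
# pins a cohort (colors, sizes, noise SDs, seed) and the analysis stages to
# run. Entries whose source description gives sizes or colors only as a
# range carry ambiguous = TRUE and document the pinned assignment.

.spec <- function(id, description, cohort, stages = c("pca",
                  "centroid_distances", "cluster"), params = list(),
                  ambiguous = FALSE) {
  new("ExperimentSpec", id = id, description = description,
      cohort = cohort, stages = stages, params = params,
      ambiguous = isTRUE(ambiguous))
}

.cs <- function(name, mean, sd = 0.01) colorSpec(name, mean, sd)

.buildRegistry <- function() {
  pal <- colorPalette()
  reg <- list()
  add <- function(s) reg[[s@id]] <<- s

  four <- function(nR, nG, nB, nK, seed = 1L, sd = 0.01)
    cohortConfig(list(.cs("Red", pal$Red, sd), .cs("Green", pal$Green, sd),
                      .cs("Blue", pal$Blue, sd),
                      .cs("Black", pal$Black, sd)),
                 n = c(nR, nG, nB, nK), seed = seed)

  add(.spec("fig1", "near-perfect case: one sample per primary color plus Black",
            four(1, 1, 1, 1),
            stages = c("pca", "centroid_distances")))
  add(.spec("fig1D", "near-perfect case at n = 100 per color",
            four(100, 100, 100, 100),
            stages = c("pca", "centroid_distances")))
  add(.spec("fig1E", "near-perfect case at n = 10000 per color",
            four(10000, 10000, 10000, 10000),
            stages = c("pca", "centroid_distances")))

  # uneven sample sizes, four primary-color populations
  f4 <- list(A = c(10, 10, 10, 200), B = c(10, 10, 5, 200),
             C = c(10, 200, 50, 200), D = c(25, 50, 50, 200),
             E = c(300, 200, 300, 300), F = c(1000, 2000, 300, 2000))
  for (panel in names(f4))
    add(.spec(paste0("fig4", panel),
              "uneven sample sizes distort the primary-color geometry",
              four(f4[[panel]][1], f4[[panel]][2], f4[[panel]][3],
                   f4[[panel]][4]),
              stages = c("pca", "centroid_distances", "pair_distances")))

  five <- function(nR, nG, nB, nC, nK, seed = 1L)
    cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                      .cs("Blue", pal$Blue), .cs("Cyan", pal$Cyan),
                      .cs("Black", pal$Black)),
                 n = c(nR, nG, nB, nC, nK), seed = seed)
  f8 <- list(A = c(100, 100, 100, 100, 200),
             B = c(100, 100, 100, 500, 500),
             C = c(100, 33, 400, 33, 400),
             D = c(100, 33, 33, 33, 100))
  for (panel in names(f8))
    add(.spec(paste0("fig8", panel),
              "primary colors plus admixed Cyan under shifting sample sizes",
              five(f8[[panel]][1], f8[[panel]][2], f8[[panel]][3],
                   f8[[panel]][4], f8[[panel]][5]),
              stages = c("pca", "centroid_distances", "pair_distances")))

  mixed <- function(n, seed = 1L)
    cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                      .cs("Blue", pal$Blue), .cs("Cyan", pal$Cyan),
                      .cs("Purple", pal$Purple), .cs("Yellow", pal$Yellow),
                      .cs("Pink", c(1, 0.5, 0.5)),
                      .cs("Black", pal$Black)), n = n, seed = seed)
  add(.spec("fig10A", "primary plus multiple mixed colors, even sizes",
            mixed(rep(50, 8))))
  add(.spec("fig10B", "primary plus multiple mixed colors, sizes 50 or 10",
            mixed(c(50, 10, 50, 10, 50, 10, 50, 50)), ambiguous = TRUE))
  add(.spec("fig10C", "primary plus multiple mixed colors, sizes in {50,5,100,25}",
            mixed(c(50, 5, 100, 25, 50, 5, 100, 25)), ambiguous = TRUE))
  add(.spec("fig10D", "primary plus multiple mixed colors, sizes in {50,5,100,25}",
            mixed(c(100, 25, 5, 50, 25, 100, 5, 50)),
            stages = c("pca", "centroid_distances", "pair_distances"),
            ambiguous = TRUE))
  add(.spec("fig10E", "distance-distortion report for the fig10D cohort",
            mixed(c(100, 25, 5, 50, 25, 100, 5, 50)),
            stages = c("pca", "centroid_distances", "pair_distances",
                       "distortion"),
            ambiguous = TRUE))

  add(.spec("fig11", "seed sensitivity: secondary colors and Black, n_all = 50",
            cohortConfig(list(.cs("Cyan", pal$Cyan),
                              .cs("Purple", pal$Purple),
                              .cs("Yellow", pal$Yellow),
                              .cs("Black", pal$Black)),
                         n = rep(50, 4), seed = 1L),
            stages = c("pca", "centroid_distances", "seed_sensitivity"),
            params = list(n_seeds = 5L)))
  add(.spec("fig11W", "seed sensitivity: secondary colors, White and Black",
            cohortConfig(list(.cs("Cyan", pal$Cyan),
                              .cs("Purple", pal$Purple),
                              .cs("Yellow", pal$Yellow),
                              .cs("White", pal$White),
                              .cs("Black", pal$Black)),
                         n = rep(50, 5), seed = 1L),
            stages = c("pca", "centroid_distances", "seed_sensitivity"),
            params = list(n_seeds = 5L)))

  # GWAS-style reference mismatch: heterogeneous test Cyan
  hetCyan <- .cs("Cyan", pal$Cyan, 0.17)
  refs13 <- list(.cs("Yellow", pal$Yellow, 0.05),
                 .cs("lightRed", c(1, 0, 0.5), 0.05),
                 .cs("Purple", pal$Purple, 0.05),
                 .cs("darkPurple", c(0.5, 0, 0.5), 0.05),
                 .cs("Black", pal$Black, 0.05),
                 .cs("darkGreen", c(0, 0.5, 0), 0.05),
                 .cs("Green", pal$Green, 0.05),
                 .cs("Blue", pal$Blue, 0.05))
  add(.spec("fig13A", "true distribution of the heterogeneous test Cyan",
            cohortConfig(list(hetCyan), n = 1000L, seed = 1L),
            stages = "pca"))
  add(.spec("fig13B", "test Cyan with eight even-sized reference populations",
            cohortConfig(c(list(hetCyan), refs13),
                         n = c(1000L, rep(250L, 8)), seed = 1L)))
  add(.spec("fig13C", "test Cyan with the Blue reference only",
            cohortConfig(list(hetCyan, .cs("Blue", pal$Blue, 0.05)),
                         n = c(1000L, 250L), seed = 1L)))
  add(.spec("fig13D", "test Cyan with five references including Cyan itself",
            cohortConfig(list(hetCyan, .cs("Cyan", pal$Cyan, 0.05),
                              .cs("Blue", pal$Blue, 0.05),
                              .cs("Green", pal$Green, 0.05),
                              .cs("Yellow", pal$Yellow, 0.05),
                              .cs("Black", pal$Black, 0.05)),
                         n = c(1000L, rep(250L, 5)), seed = 1L),
            ambiguous = TRUE))

  # projections (noise SD 0.02 for these runs)
  base17 <- cohortConfig(list(.cs("Red", pal$Red, 0.02),
                              .cs("Green", pal$Green, 0.02),
                              .cs("Blue", pal$Blue, 0.02),
                              .cs("Purple", pal$Purple, 0.02)),
                         n = c(200L, 10L, 200L, 10L), seed = 1L)
  proj17A <- cohortConfig(list(.cs("Red", c(1, 0.1, 0.1), 0.02),
                               .cs("Green", c(0.1, 1, 0.1), 0.02),
                               .cs("Blue", c(0.1, 0.1, 1), 0.02),
                               .cs("Purple", c(1, 0.1, 1), 0.02)),
                          n = c(200L, 200L, 10L, 10L), seed = 2L)
  add(.spec("fig17A", "projection of slightly varied matching populations",
            base17, stages = c("pca", "project"),
            params = list(projected = proj17A)))
  add(.spec("fig17Aident",
            "projection of populations identical to the base cohort",
            base17, stages = c("pca", "project"),
            params = list(projected = local({
              cc <- base17; cc@seed <- 2L
              cc@n <- c(200L, 200L, 10L, 10L); cc
            }))))
  proj17 <- function(specs, n, seed)
    cohortConfig(specs, n = n, seed = seed)
  mism <- list(.cs("Cyan", pal$Cyan, 0.02),
               .cs("Yellow", pal$Yellow, 0.02),
               .cs("Grey", pal$Grey, 0.02),
               .cs("White", pal$White, 0.02))
  for (panel in c("B", "C", "D")) {
    nn <- switch(panel, B = c(100L, 100L, 100L, 100L),
                 C = c(300L, 10L, 150L, 25L), D = c(10L, 300L, 10L, 300L))
    add(.spec(paste0("fig17", panel),
              "projection with unique populations in the two cohorts",
              base17, stages = c("pca", "project"),
              params = list(projected = proj17(mism, nn, 3L)),
              ambiguous = TRUE))
  }

  # ancient/modern colors
  anc <- function(names) lapply(names, eraSpec, era = "ancient")
  mod <- function(names) lapply(names, eraSpec, era = "modern")
  modern_set <- c("Red", "Green", "Blue", "Cyan", "Yellow", "Purple")
  anc_set <- c("Red", "Green", "Blue")
  mBlack <- colorSpec("Black", pal$Black, 0.02)
  add(.spec("fig19A", "separate PCAs of even-sized ancient and modern colors",
            cohortConfig(c(mod(modern_set), list(mBlack)),
                         n = rep(75L, 7), seed = 1L),
            stages = c("pca", "separate_pca"),
            params = list(second = cohortConfig(anc(anc_set),
                                                n = rep(25L, 3), seed = 2L))))
  add(.spec("fig19B", "separate PCAs of uneven ancient and modern colors",
            cohortConfig(c(mod(modern_set), list(mBlack)),
                         n = c(75L, 10L, 30L, 10L, 75L, 20L, 50L), seed = 1L),
            stages = c("pca", "separate_pca"),
            params = list(second = cohortConfig(anc(anc_set),
                                                n = c(25L, 10L, 18L),
                                                seed = 2L)),
            ambiguous = TRUE))
  add(.spec("fig19C", "ancient colors projected onto modern ones (n = 15)",
            cohortConfig(c(mod(modern_set), list(mBlack)),
                         n = rep(15L, 7), seed = 1L),
            stages = c("pca", "project"),
            params = list(projected = cohortConfig(anc(anc_set),
                                                   n = c(75L, 10L, 40L),
                                                   seed = 2L)),
            ambiguous = TRUE))
  add(.spec("fig19D", "ancient colors projected onto modern ones (n = 25)",
            cohortConfig(c(mod(modern_set), list(mBlack)),
                         n = rep(25L, 7), seed = 1L),
            stages = c("pca", "project"),
            params = list(projected = cohortConfig(anc(anc_set),
                                                   n = c(75L, 10L, 40L),
                                                   seed = 2L)),
            ambiguous = TRUE))

  # missingness / noise robustness on six fixed-size color populations
  six <- cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                           .cs("Blue", pal$Blue), .cs("Cyan", pal$Cyan),
                           .cs("Yellow", pal$Yellow),
                           .cs("Black", pal$Black)),
                      n = rep(50L, 6), seed = 1L)
  miss_stage <- c("pca", "window_missingness")
  add(.spec("fig21A", "50% missingness on the 600-SNP window expansion", six,
            stages = miss_stage,
            params = list(window_size = 200L, feature_noise_sd = 0.01,
                          missing_rate = 0.5)))
  add(.spec("fig21B", "90% missingness on the 600-SNP window expansion", six,
            stages = miss_stage,
            params = list(window_size = 200L, feature_noise_sd = 0.01,
                          missing_rate = 0.9)))
  add(.spec("fig21C", "90% missingness plus low-level noise in all markers",
            six, stages = miss_stage,
            params = list(window_size = 200L, feature_noise_sd = 0.01,
                          missing_rate = 0.9, perturb_level = 0.1)))
  for (m in c(A = 30L, B = 300L, C = 3000L)) {
    panel <- c("D", "E", "F")[match(m, c(30L, 300L, 3000L))]
    add(.spec(paste0("fig21", panel),
              sprintf("%d random uniform markers added to the color set", m),
              six, stages = c("pca", "noise_markers"),
              params = list(n_noise_markers = m)))
  }

  # single-individual ancestry
  add(.spec("fig23A", "light Green individual among even-sized references",
            cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                              .cs("brightCyan", c(0, 0.9, 0.8)),
                              .cs("darkCyan", c(0, 0.9, 0.6)),
                              .cs("hetCyan", c(0, 0.9, 0.4), 0.25),
                              .cs("lightGreen", c(0, 0.5, 0))),
                         n = c(rep(37L, 5), 1L), seed = 1L)))
  add(.spec("fig23B", "Yellow individual among uneven-sized references",
            cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                              .cs("brightCyan", c(0, 0.9, 0.8)),
                              .cs("darkCyan", c(0, 0.9, 0.6)),
                              .cs("hetCyan", c(0, 0.9, 0.4), 0.25),
                              .cs("Yellow", pal$Yellow)),
                         n = c(15L, 15L, 100L, 15L, 100L, 1L), seed = 1L)))
  add(.spec("fig23C", "Grey individual with a heterogeneous Cyan population",
            cohortConfig(list(.cs("Cyan", pal$Cyan, 0.25),
                              .cs("Grey", pal$Grey)),
                         n = c(300L, 1L), seed = 1L),
            stages = c("pca", "centroid_distances")))
  add(.spec("fig23D", "Blue individual with Red, Green and a mixed population",
            cohortConfig(list(.cs("Red", pal$Red), .cs("Green", pal$Green),
                              .cs("Mixed", c(1, 1, 0.5)),
                              .cs("Blue", pal$Blue)),
                         n = c(10L, 10L, 200L, 1L), seed = 1L)))

  # stratified case-control association
  add(.spec("gwas",
            "minority-all-controls association scan, adjusted vs unadjusted",
            cohortConfig(list(.cs("Red", pal$Red), .cs("Blue", pal$Blue)),
                         n = c(300L, 20L), seed = 1L),
            stages = c("pca", "gwas"),
            params = list(design = caseControlDesign(
              labeling = "structured", minority = "Blue",
              n_null_markers = 200L, n_causal_markers = 20L,
              effect_size = 0.4, structure_spread = 1.0,
              adjust_pcs = c(0L, 2L, 10L), alpha = 0.05, seed = 1L),
              window_size = 200L, feature_noise_sd = 0.01,
              replicates = 3L)))
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' The experiment registry
#'
#' Named list of all registered [ExperimentSpec-class] test cases (the
#' synthetic figure analogs plus the case-control experiment).
#'
#' @return named list of ExperimentSpec objects.
#' @seealso [runExperiment()], [seedSensitivity()]
#' @export
experimentRegistry <- function() {
  if (is.null(.registry_cache$reg))
    .registry_cache$reg <- .buildRegistry()
  .registry_cache$reg
}

#' @rdname experimentRegistry
#' @param id registry tag, e.g. `"fig1"`.
#' @export
getExperiment <- function(id) {
  reg <- experimentRegistry()
  if (!id %in% names(reg))
    stop(sprintf("unknown experiment '%s'; see names(experimentRegistry())",
                 id), call. = FALSE)
  reg[[id]]
}

#' Run a registered experiment
#'
#' Generates the cohort, executes the spec's stages in order, and returns
#' an artifact bundle (a named list). With `outdir` set, score tables,
#' distance and cluster reports and a YAML manifest (config, seed, package
#' version) are also written, so every output is reproducible from its
#' manifest alone. Runs are idempotent for a fixed seed.
#'
#' @param spec an [ExperimentSpec-class] or a registry id.
#' @param outdir optional output directory.
#' @param seed optional override of the cohort root seed.
#' @return named list with the cohort `data`, fitted `model` and one entry
#'   per executed stage.
#' @export
runExperiment <- function(spec, outdir = NULL, seed = NULL) {
  if (is.character(spec)) spec <- getExperiment(spec)
  stopifnot(is(spec, "ExperimentSpec"))
  cohort <- spec@cohort
  if (!is.null(seed)) cohort@seed <- as.integer(seed)
  prm <- spec@params
  data <- generateCohort(cohort)
  bundle <- list(id = spec@id, seed = cohort@seed, data = data)

  for (stage in spec@stages) {
    bundle <- switch(stage,
      pca = {
        bundle$model <- fitPCA(data)
        bundle$explained2 <- explainedVariance(
          bundle$model, min(2L, bundle$model@rank))
        bundle
      },
      centroid_distances = {
        bundle$centroid_distances <-
          centroidDistances(data, bundle$model, k = 2L)
        bundle
      },
      pair_distances = {
        n <- nrow(bundle$model@scores)
        bundle$pair_distances <- samplePairDistances(
          data, bundle$model, k = 2L,
          n_pairs = min(2000L, n * (n - 1L) / 2L),
          seed = deriveSeed(cohort@seed, 7L, "pairs"))
        bundle
      },
      distortion = {
        bundle$distortion <- distortionSummary(
          normalizeReport(bundle$pair_distances))
        bundle
      },
      cluster = {
        k <- min(2L, bundle$model@rank)
        bundle$cluster <- clusterHomogeneity(
          bundle$model@scores[, seq_len(k), drop = FALSE],
          populationLabels(data),
          seed = deriveSeed(cohort@seed, 11L, "kmeans"))
        bundle
      },
      seed_sensitivity = {
        bundle$seed_sensitivity <- seedSensitivity(
          spec, n_seeds = prm$n_seeds %||% 5L)
        bundle
      },
      project = {
        proj <- generateCohort(prm$projected)
        bundle$projected_data <- proj
        bundle$projected_scores <- projectDataset(bundle$model, proj,
                                                  k = 2L)
        bundle
      },
      separate_pca = {
        second <- generateCohort(prm$second)
        bundle$second_data <- second
        bundle$second_model <- fitPCA(second)
        bundle
      },
      window_missingness = {
        ws <- prm$window_size %||% 200L
        seed0 <- deriveSeed(cohort@seed, 13L, "windows")
        ex <- expandWindows(data, ws,
                            feature_noise_sd = prm$feature_noise_sd %||% 0,
                            seed = seed0)
        wd <- ex$data
        if (!is.null(prm$perturb_level))
          wd <- perturbAllMarkers(wd, prm$perturb_level,
                                  seed = deriveSeed(cohort@seed, 17L,
                                                    "perturb"))
        wd <- injectMissingness(wd, prm$missing_rate %||% 0,
                                seed = deriveSeed(cohort@seed, 19L,
                                                  "missing"))
        rec <- collapseWindows(wd, ex$map)
        bundle$windowed <- wd
        bundle$recovered <- rec
        bundle$retention <- structureRetention(data, rec, k = 2L)
        bundle
      },
      noise_markers = {
        noisy <- addNoiseMarkers(data, prm$n_noise_markers %||% 0L,
                                 seed = deriveSeed(cohort@seed, 23L,
                                                   "noise"))
        bundle$noisy_data <- noisy
        bundle$noisy_model <- fitPCA(noisy)
        bundle$noisy_explained2 <- explainedVariance(bundle$noisy_model, 2L)
        bundle$noisy_cluster <- clusterHomogeneity(
          bundle$noisy_model@scores[, 1:2], populationLabels(data),
          seed = deriveSeed(cohort@seed, 29L, "kmeans"))
        bundle
      },
      gwas = {
        ws <- prm$window_size %||% 200L
        ex <- expandWindows(data, ws,
                            feature_noise_sd = prm$feature_noise_sd %||% 0.01,
                            seed = deriveSeed(cohort@seed, 13L, "windows"))
        bundle$gwas <- adjustmentExperiment(ex$data, prm$design,
                                            replicates =
                                              prm$replicates %||% 1L)
        bundle
      },
      stop(sprintf("experiment '%s': unknown stage '%s'", spec@id, stage),
           call. = FALSE))
  }

  if (!is.null(outdir)) .writeBundle(spec, bundle, outdir)
  bundle
}

.writeBundle <- function(spec, bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, paste0(...))
  if (!is.null(bundle$model)) {
    sc <- data.frame(sample_id = rownames(sampleMatrix(bundle$data)),
                     population = populationLabels(bundle$data),
                     bundle$model@scores, check.names = FALSE)
    utils::write.table(sc, fp(spec@id, "_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$centroid_distances))
    utils::write.table(bundle$centroid_distances@pairs,
                       fp(spec@id, "_centroid_distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$cluster)) {
    cl <- bundle$cluster
    utils::write.table(
      data.frame(cluster = seq_along(cl@cluster_sizes),
                 size = cl@cluster_sizes, homogeneous = cl@homogeneous),
      fp(spec@id, "_clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  manifest <- list(
    id = spec@id, description = spec@description, seed = bundle$seed,
    ambiguous = spec@ambiguous, stages = spec@stages,
    package_version = as.character(utils::packageVersion("PCAtruth")),
    cohort = lapply(seq_along(spec@cohort@specs), function(i) {
      s <- spec@cohort@specs[[i]]
      list(name = s@name, mean = as.numeric(s@mean), noise_sd = s@noise_sd,
           size = spec@cohort@n[i])
    }))
  writeLines(yaml::as.yaml(manifest), fp(spec@id, "_manifest.yaml"))
  invisible(outdir)
}

#' Seed-sensitivity sweep of an experiment
#'
#' Reruns an experiment's cohort generation and PCA under `n_seeds`
#' different root seeds -- the only varying ingredient is the pseudorandom
#' draw -- and reports the per-seed top-2 centroid configurations, the
#' pairwise Procrustes disagreement matrix, and each population's nearest
#' neighbouring population per seed.
#'
#' @param spec an [ExperimentSpec-class] or registry id.
#' @param n_seeds number of seeds (>= 2).
#' @return list with `configurations`, `disagreement` (symmetric matrix,
#'   zero diagonal) and `nearest_neighbors` (populations x seeds).
#' @export
seedSensitivity <- function(spec, n_seeds = 5L) {
  if (is.character(spec)) spec <- getExperiment(spec)
  n_seeds <- .assertCount(n_seeds, "n_seeds", 2L)
  cohort <- spec@cohort
  pops <- vapply(cohort@specs, slot, character(1), "name")
  configs <- vector("list", n_seeds)
  nn <- matrix(NA_character_, length(pops), n_seeds,
               dimnames = list(pops, paste0("seed", seq_len(n_seeds))))
  for (s in seq_len(n_seeds)) {
    cc <- cohort
    cc@seed <- deriveSeed(cohort@seed, s, "sweep")
    data <- generateCohort(cc)
    model <- fitPCA(data)
    cfg <- centroidConfiguration(data, model, k = min(2L, model@rank),
                                 pops = pops)
    configs[[s]] <- cfg
    D <- as.matrix(stats::dist(cfg))
    diag(D) <- Inf
    nn[, s] <- pops[apply(D, 1L, which.min)]
  }
  dis <- matrix(0, n_seeds, n_seeds)
  for (i in seq_len(n_seeds - 1L)) for (j in (i + 1L):n_seeds)
    dis[i, j] <- dis[j, i] <- configurationAgreement(configs[[i]],
                                                     configs[[j]])
  list(configurations = configs, disagreement = dis,
       nearest_neighbors = nn)
}
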