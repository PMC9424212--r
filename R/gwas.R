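#' Construct a CaseControlDesign
#'
#' @param labeling "structured" (the designated minority population goes
#'   entirely into the control arm, remaining labels drawn at random to
#'   reach evenly sized arms) or "random" (uniform assignment into even
#'   arms).
#' @param minority population label forced into controls under structured
#'   labeling.
#' @param n_null_markers,n_causal_markers marker counts.
#' @param effect_size per-allele log-odds separation between arms at causal
#'   markers.
#' @param structure_spread logit-scale coupling between population color
#'   means and marker frequencies; 0 removes structure from the markers.
#' @param adjust_pcs PC-adjustment levels compared by
#'   [adjustmentExperiment()] (0 = unadjusted; default `c(0, 2, 10)`).
#' @param alpha per-marker significance threshold.
#' @param seed root seed.
#' @return a [CaseControlDesign-class].
#' @export
caseControlDesign <- function(labeling = c("structured", "random"),
                              minority = NA_character_,
                              n_null_markers = 200L, n_causal_markers = 20L,
                              effect_size = 0.4, structure_spread = 1.0,
                              adjust_pcs = c(0L, 2L, 10L), alpha = 0.05,
                              seed = 1L) {
  labeling <- match.arg(labeling)
  new("CaseControlDesign", labeling = labeling,
      minority = as.character(minority),
      n_null_markers = .assertCount(n_null_markers, "n_null_markers", 0L),
      n_causal_markers = .assertCount(n_causal_markers, "n_causal_markers",
                                      0L),
      effect_size = as.numeric(effect_size),
      structure_spread = as.numeric(structure_spread),
      adjust_pcs = as.integer(sort(unique(adjust_pcs))),
      alpha = as.numeric(alpha), seed = as.integer(seed))
}

#' Assign case-control labels to a cohort
#'
#' Arms are always evenly sized (n/2 each; n must be even). Under
#' structured labeling every member of the minority population is a
#' control and the remaining control slots are drawn at random from the
#' other populations; under random labeling all assignments are uniform.
#'
#' @param data a [ColorDataset-class].
#' @param design a [CaseControlDesign-class].
#' @param seed seed override (default: derived from `design@seed`).
#' @return character vector of "case"/"control" per sample.
#' @export
simulateLabels <- function(data, design, seed = NULL) {
  stopifnot(is(data, "ColorDataset"), is(design, "CaseControlDesign"))
  pops <- populationLabels(data)
  n <- length(pops)
  if (n %% 2L != 0L)
    stop("evenly sized arms require an even cohort size", call. = FALSE)
  arm <- n %/% 2L
  if (is.null(seed)) seed <- deriveSeed(design@seed, 1L, "labels")
  y <- rep("case", n)
  if (design@labeling == "structured") {
    minor <- which(pops == design@minority)
    if (length(minor) == 0L)
      stop(sprintf("minority population '%s' absent from the cohort",
                   design@minority), call. = FALSE)
    if (length(minor) > arm)
      stop("minority population larger than the control arm", call. = FALSE)
    extra <- withSeed(seed,
      sample(setdiff(seq_len(n), minor), arm - length(minor)))
    y[c(minor, extra)] <- "control"
  } else {
    y[withSeed(seed, sample.int(n, arm))] <- "control"
  }
  y
}

#' Simulate null and causal genotype markers on a labeled cohort
#'
#' Each marker gets a base allele frequency drawn uniformly on
#' `[0.1, 0.9]`. Population structure enters on the logit scale: the
#' frequency for an individual of population g is shifted by
#' `structure_spread * (mean_g[c] - 0.5)`, where c cycles over the three
#' color components, so the marker frequencies mirror the color structure.
#' Causal markers receive an additional `effect_size / 2` logit shift
#' upward in cases and downward in controls. Dosages are binomial(2, f).
#' Frequencies outside (0.001, 0.999) after shifting are clipped with a
#' warning.
#'
#' @param data the color cohort (provides population labels and means).
#' @param labels "case"/"control" vector from [simulateLabels()].
#' @param design a [CaseControlDesign-class].
#' @param seed seed override (default derived from `design@seed`).
#' @return list with `genotypes` (n-by-m dosage matrix) and `causal`
#'   (logical length-m flags).
#' @export
simulateMarkers <- function(data, labels, design, seed = NULL) {
  stopifnot(is(data, "ColorDataset"), is(design, "CaseControlDesign"))
  pops <- populationLabels(data)
  n <- length(pops)
  m <- design@n_null_markers + design@n_causal_markers
  causal <- c(rep(FALSE, design@n_null_markers),
              rep(TRUE, design@n_causal_markers))
  if (is.null(seed)) seed <- deriveSeed(design@seed, 2L, "markers")
  # population mean colors for the structure coupling
  upop <- unique(pops)
  cmean <- t(vapply(upop, function(g)
    colMeans(sampleMatrix(data)[pops == g, , drop = FALSE]),
    numeric(ncol(sampleMatrix(data)))))
  comp_of <- rep_len(seq_len(ncol(cmean)), m)
  withSeed(seed, {
    f0 <- stats::runif(m, 0.1, 0.9)
    G <- matrix(0L, n, m)
    clipped <- FALSE
    for (j in seq_len(m)) {
      lo <- stats::qlogis(f0[j]) +
        design@structure_spread *
          (cmean[match(pops, upop), comp_of[j]] - 0.5)
      if (causal[j])
        lo <- lo + ifelse(labels == "case", 1, -1) * design@effect_size / 2
      f <- stats::plogis(lo)
      if (any(f < 0.001 | f > 0.999)) {
        clipped <- TRUE
        f <- pmin(pmax(f, 0.001), 0.999)
      }
      G[, j] <- stats::rbinom(n, 2L, f)
    }
    if (clipped)
      warning("some marker frequencies fell outside (0.001, 0.999) and were clipped")
    colnames(G) <- sprintf("%s%04d", ifelse(causal, "causal", "null"),
                           seq_len(m))
    list(genotypes = G, causal = causal)
  })
}

# Cochran-Armitage trend statistic (scores 0,1,2); chi-squared with 1 df.
.trendTest <- function(g, y) {
  tab <- table(factor(y, levels = c("control", "case")),
               factor(g, levels = 0:2))
  ht <- suppressWarnings(stats::prop.trend.test(tab["case", ],
                                                colSums(tab), score = 0:2))
  c(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Per-marker case-control association scan
#'
#' Logistic regression of case status on allele dosage, with optional PC
#' score covariates; the per-marker p-value is the Wald test on the dosage
#' coefficient. Without covariates the Cochran-Armitage trend statistic is
#' reported alongside as a cross-check. Markers showing separation are
#' flagged and excluded from the significance counts (p set to NA).
#'
#' @param genotypes n-by-m dosage matrix in {0, 1, 2}.
#' @param labels "case"/"control" vector.
#' @param covariates optional n-by-q numeric matrix (top-q PC scores), or
#'   NULL for the unadjusted scan.
#' @param causal optional logical flags; defaults to all-null.
#' @param alpha significance threshold for the summary counts.
#' @return list with `markers` (data.frame: marker, beta, statistic, p,
#'   trend_statistic, trend_p, causal, significant, separated) and
#'   `summary` (false_positive_count, true_positive_count,
#'   median_causal_p, n_tested, alpha, adjusted_pcs).
#' @export
associationScan <- function(genotypes, labels, covariates = NULL,
                            causal = NULL, alpha = 0.05) {
  G <- as.matrix(genotypes)
  if (!all(G %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1 or 2", call. = FALSE)
  y <- as.integer(labels == "case")
  m <- ncol(G)
  if (is.null(causal)) causal <- rep(FALSE, m)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  beta <- stat <- p <- tstat <- tp <- rep(NA_real_, m)
  separated <- logical(m)
  for (j in seq_len(m)) {
    df <- if (q > 0) data.frame(y = y, g = G[, j], covariates)
          else data.frame(y = y, g = G[, j])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if ("g" %in% rownames(co)) {
      beta[j] <- co["g", 1L]
      stat[j] <- co["g", 3L]
      p[j] <- co["g", 4L]
    }
    # separation diagnosed on the dosage coefficient itself: a diverging
    # estimate or an exploding Wald SE (covariates may legitimately fit
    # some observations perfectly without harming the marker term)
    if (is.na(beta[j]) || abs(beta[j]) > 15 ||
        (!is.na(beta[j]) && co["g", 2L] > 100)) {
      separated[j] <- TRUE
      p[j] <- NA_real_
    }
    if (q == 0L && stats::var(G[, j]) > 0) {
      tt <- .trendTest(G[, j], labels)
      tstat[j] <- tt["statistic"]; tp[j] <- tt["p"]
    }
  }
  markers <- data.frame(
    marker = colnames(G) %||% paste0("m", seq_len(m)),
    beta = beta, statistic = stat, p = p,
    trend_statistic = tstat, trend_p = tp,
    causal = causal, significant = !is.na(p) & p < alpha,
    separated = separated, stringsAsFactors = FALSE)
  list(markers = markers,
       summary = list(
         false_positive_count = sum(markers$significant & !causal),
         true_positive_count = sum(markers$significant & causal),
         median_causal_p = if (any(causal))
           stats::median(p[causal], na.rm = TRUE) else NA_real_,
         n_tested = sum(!is.na(p)), alpha = alpha, adjusted_pcs = q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare association scans with and without PC adjustment
#'
#' The full experiment: for each replicate, labels and markers are drawn
#' afresh (child seeds from the design seed), the cohort's PCA is fitted on
#' its structure features, and one scan is run per adjustment level in
#' `design@adjust_pcs` (0 = unadjusted). Reports the per-replicate false
#' positive count, true positive count and median causal p, plus
#' cross-replicate medians and, per adjusted level, the number of
#' replicates in which adjustment yielded strictly fewer true positives /
#' strictly more false positives / a weaker (larger) median causal p than
#' the unadjusted scan.
#'
#' @param data the structured color cohort.
#' @param design a [CaseControlDesign-class] (include 0 in `adjust_pcs` to
#'   get the unadjusted reference).
#' @param replicates number of replicate draws (>= 1).
#' @return list with `table` (one row per replicate x adjustment level) and
#'   `summary` (per-level medians and the adjusted-vs-unadjusted sign
#'   counts).
#' @export
adjustmentExperiment <- function(data, design, replicates = 1L) {
  stopifnot(is(data, "ColorDataset"), is(design, "CaseControlDesign"))
  replicates <- .assertCount(replicates, "replicates")
  model <- fitPCA(data)
  if (max(design@adjust_pcs) > model@rank)
    stop(sprintf("adjustment with %d PCs requested but the cohort only supports rank %d",
                 max(design@adjust_pcs), model@rank), call. = FALSE)
  rows <- list()
  for (r in seq_len(replicates)) {
    lab_seed <- deriveSeed(design@seed, r, "labels")
    mrk_seed <- deriveSeed(design@seed, r, "markers")
    labels <- simulateLabels(data, design, seed = lab_seed)
    sim <- simulateMarkers(data, labels, design, seed = mrk_seed)
    for (q in design@adjust_pcs) {
      covar <- if (q > 0L) model@scores[, seq_len(q), drop = FALSE] else NULL
      res <- associationScan(sim$genotypes, labels, covar, sim$causal,
                             design@alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, adjusted_pcs = q,
        false_positives = res$summary$false_positive_count,
        true_positives = res$summary$true_positive_count,
        median_causal_p = res$summary$median_causal_p)
    }
  }
  tab <- do.call(rbind, rows)
  levels_adj <- setdiff(design@adjust_pcs, 0L)
  summ <- list(medians = stats::aggregate(
    cbind(false_positives, true_positives, median_causal_p) ~ adjusted_pcs,
    tab, stats::median, na.action = stats::na.pass))
  if (0L %in% design@adjust_pcs && length(levels_adj)) {
    base <- tab[tab$adjusted_pcs == 0L, ]
    cmp <- lapply(levels_adj, function(q) {
      adj <- tab[tab$adjusted_pcs == q, ]
      list(adjusted_pcs = q,
           fewer_true_positives = sum(adj$true_positives <
                                      base$true_positives),
           more_false_positives = sum(adj$false_positives >
                                      base$false_positives),
           weaker_causal_p = sum(adj$median_causal_p >
                                 base$median_causal_p, na.rm = TRUE),
           replicates = replicates)
    })
    names(cmp) <- paste0("pc", levels_adj)
    summ$versus_unadjusted <- cmp
  }
  list(table = tab, summary = summ)
}
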