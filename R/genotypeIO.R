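#' Read EIGENSTRAT text genotypes
#'
#' Reads the .geno/.snp/.ind triplet (text GENO format: one line per SNP,
#' one character per individual, `9` = missing). Population labels come
#' from the third column of the .ind file. Dosage bounds are enforced on
#' read; invalid characters raise a parse error with the line number.
#'
#' @param geno_path,snp_path,ind_path file paths.
#' @return a [ColorDataset-class] with feature class "genotype"; marker
#'   metadata (chrom, pos, a1, a2) lives in `rowData`, dropped/parse
#'   details in `metadata`.
#' @export
readEigenstrat <- function(geno_path, snp_path, ind_path) {
  ind <- utils::read.table(ind_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(ind) < 3L)
    stop("malformed .ind file: expected id, sex, population columns",
         call. = FALSE)
  snp <- utils::read.table(snp_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(snp) < 4L)
    stop("malformed .snp file: expected at least id, chrom, morgans, pos",
         call. = FALSE)
  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stop(sprintf("dimension mismatch: %d genotype lines but %d .snp records",
                 length(lines), nrow(snp)), call. = FALSE)
  n <- nrow(ind)
  G <- matrix(NA_integer_, nrow(snp), n)
  for (i in seq_along(lines)) {
    ch <- strsplit(lines[i], "")[[1]]
    if (length(ch) != n)
      stop(sprintf("line %d: %d genotypes for %d individuals", i,
                   length(ch), n), call. = FALSE)
    bad <- !ch %in% c("0", "1", "2", "9")
    if (any(bad))
      stop(sprintf("line %d: invalid genotype character '%s'", i,
                   ch[which(bad)[1L]]), call. = FALSE)
    v <- as.integer(ch)
    v[v == 9L] <- NA_integer_
    G[i, ] <- v
  }
  .genotypePanel(t(G), labels = ind[[3L]], sample_ids = ind[[1L]],
                 markers = data.frame(
                   id = snp[[1L]], chrom = snp[[2L]], pos = snp[[4L]],
                   a1 = if (ncol(snp) >= 5L) snp[[5L]] else "A",
                   a2 = if (ncol(snp) >= 6L) snp[[6L]] else "G",
                   stringsAsFactors = FALSE))
}

# Assemble a genotype ColorDataset with marker metadata in rowData.
.genotypePanel <- function(X, labels, sample_ids, markers) {
  M <- is.na(X)
  X[M] <- 0
  d <- .makeDataset(X, labels, feature_ids = markers$id,
                    feature_class = "genotype", missing_mask = M)
  rd <- SummarizedExperiment::rowData(d)
  rd$chrom <- markers$chrom; rd$pos <- markers$pos
  rd$a1 <- markers$a1; rd$a2 <- markers$a2
  SummarizedExperiment::rowData(d) <- rd
  colnames(d) <- sample_ids
  d
}

#' Marker metadata of a genotype panel
#' @param panel a genotype [ColorDataset-class].
#' @return data.frame with id, chrom, pos, a1, a2.
#' @export
markerInfo <- function(panel) {
  rd <- SummarizedExperiment::rowData(panel)
  data.frame(id = rownames(panel), chrom = rd$chrom, pos = rd$pos,
             a1 = rd$a1, a2 = rd$a2, stringsAsFactors = FALSE)
}

#' Write EIGENSTRAT text genotypes
#'
#' @param panel a genotype [ColorDataset-class] (see [readEigenstrat()]).
#' @param prefix output path prefix; writes `<prefix>.geno/.snp/.ind`.
#' @return the prefix, invisibly.
#' @export
writeEigenstrat <- function(panel, prefix) {
  X <- sampleMatrix(panel); M <- missingMask(panel)
  G <- t(X); G[t(M)] <- 9
  writeLines(apply(G, 1L, paste, collapse = ""),
             paste0(prefix, ".geno"))
  mi <- markerInfo(panel)
  utils::write.table(data.frame(mi$id, mi$chrom, 0, mi$pos, mi$a1, mi$a2),
                     paste0(prefix, ".snp"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(data.frame(colnames(panel), "U",
                                populationLabels(panel)),
                     paste0(prefix, ".ind"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read PLINK additive text genotypes (.raw / .traw)
#'
#' Handles both text dialects of PLINK's additive recode: `.raw`
#' (samples x markers, header FID IID PAT MAT SEX PHENOTYPE then one column
#' per marker) and `.traw` (markers x samples, header CHR SNP (C)M POS
#' COUNTED ALT then one column per sample). The orientation is detected
#' from the header. `NA` entries are missing. Population labels are taken
#' from the FID column (raw) or the FID part of FID_IID columns (traw).
#'
#' @param path file path ending in .raw or .traw (or matching either
#'   header).
#' @return a genotype [ColorDataset-class].
#' @export
readPlinkText <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (identical(header[1:6],
                c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    G <- as.matrix(tab[, -(1:6), drop = FALSE])
    ids <- tab$IID; labels <- tab$FID
    mk <- sub("_[ACGT0-9]+$", "", colnames(G))
    markers <- data.frame(id = mk, chrom = NA, pos = NA_integer_,
                          a1 = sub("^.*_", "", colnames(G)), a2 = NA,
                          stringsAsFactors = FALSE)
  } else if (identical(header[1:6],
                       c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT"))) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "")
    G <- t(as.matrix(tab[, -(1:6), drop = FALSE]))
    full <- colnames(tab)[-(1:6)]
    labels <- sub("_.*$", "", full)
    ids <- sub("^[^_]*_", "", full)
    markers <- data.frame(id = tab$SNP, chrom = tab$CHR, pos = tab$POS,
                          a1 = tab$COUNTED, a2 = tab$ALT,
                          stringsAsFactors = FALSE)
  } else {
    stop("malformed header: neither a PLINK .raw nor .traw dialect",
         call. = FALSE)
  }
  obs <- G[!is.na(G)]
  if (length(obs) && !all(obs %in% c(0, 1, 2)))
    stop("dosages outside {0,1,2} encountered; refusing to clamp",
         call. = FALSE)
  .genotypePanel(G, labels = labels, sample_ids = ids, markers = markers)
}

#' Write PLINK additive text genotypes
#'
#' @param panel a genotype [ColorDataset-class].
#' @param path output path.
#' @param dialect "raw" (samples x markers) or "traw" (markers x samples).
#' @return the path, invisibly.
#' @export
writePlinkText <- function(panel, path, dialect = c("raw", "traw")) {
  dialect <- match.arg(dialect)
  X <- sampleMatrix(panel); X[missingMask(panel)] <- NA
  mi <- markerInfo(panel)
  if (dialect == "raw") {
    tab <- data.frame(FID = populationLabels(panel), IID = colnames(panel),
                      PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                      check.names = FALSE)
    geno <- as.data.frame(X)
    names(geno) <- paste0(mi$id, "_", mi$a1)
    utils::write.table(cbind(tab, geno), path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
  } else {
    tab <- data.frame(CHR = mi$chrom %||% 1, SNP = mi$id, CM = 0,
                      POS = mi$pos, COUNTED = mi$a1, ALT = mi$a2,
                      check.names = FALSE)
    names(tab)[3] <- "(C)M"
    geno <- as.data.frame(t(X))
    names(geno) <- paste0(populationLabels(panel), "_", colnames(panel))
    utils::write.table(cbind(tab, geno), path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Drop samples exceeding a per-sample missingness threshold
#'
#' @param panel a genotype [ColorDataset-class].
#' @param max_missing_per_sample maximum missing markers tolerated per
#'   sample (default 5).
#' @return the filtered panel; dropped sample ids are recorded in
#'   `S4Vectors::metadata(panel)$dropped_samples`.
#' @export
filterMissingness <- function(panel, max_missing_per_sample = 5L) {
  M <- missingMask(panel)
  n_miss <- rowSums(M)
  drop <- n_miss > max_missing_per_sample
  out <- panel[, !drop]
  md <- S4Vectors::metadata(out)
  md$dropped_samples <- colnames(panel)[drop]
  S4Vectors::metadata(out) <- md
  out
}

#' Generate a random genotype fixture panel
#'
#' Small synthetic panel for tests and examples: markers draw binomial
#' dosages at population-specific frequencies, with optional uniform
#' missingness.
#'
#' @param n_per_pop samples per population (named vector; names become
#'   population labels).
#' @param p marker count.
#' @param missing_rate entry-wise missing probability.
#' @param seed integer seed.
#' @return a genotype [ColorDataset-class].
#' @export
randomGenotypePanel <- function(n_per_pop = c(POP1 = 5L, POP2 = 5L),
                                p = 20L, missing_rate = 0, seed = 1L) {
  withSeed(seed, {
    pops <- rep(names(n_per_pop), n_per_pop)
    n <- length(pops)
    f <- matrix(stats::runif(length(n_per_pop) * p, 0.05, 0.95),
                nrow = length(n_per_pop))
    G <- matrix(0L, n, p)
    for (i in seq_len(n))
      G[i, ] <- stats::rbinom(p, 2L, f[match(pops[i], names(n_per_pop)), ])
    if (missing_rate > 0)
      G[matrix(stats::runif(n * p) < missing_rate, n, p)] <- NA_integer_
    .genotypePanel(G, labels = pops,
                   sample_ids = sprintf("%s_%03d", pops,
                                        sequence(n_per_pop)),
                   markers = data.frame(
                     id = sprintf("rs%05d", seq_len(p)),
                     chrom = rep_len(1:22, p), pos = seq_len(p) * 1000L,
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE))
  })
}
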