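#' Fit centered, SVD-based PCA
#'
#' Columns are centered by their means; no per-feature variance scaling is
#' applied by default (set `scale = TRUE` to opt in). Eigenvalues are those
#' of the sample covariance matrix, i.e. squared singular values of the
#' centered matrix divided by n - 1. The sign of each component is fixed
#' deterministically: the loading with the largest magnitude is made
#' positive, so refits are reproducible even though the eigenvector sign is
#' mathematically arbitrary.
#'
#' @param data a [ColorDataset-class] with no missing entries, or a plain
#'   samples-by-features matrix.
#' @param scale logical; scale features to unit variance before the SVD.
#' @return a [PCAModel-class] retaining full rank `min(n - 1, p)`.
#' @examples
#' simplex <- ColorDataset(rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(0,0,0)),
#'                         c("Red", "Green", "Blue", "Black"))
#' m <- fitPCA(simplex)
#' m@eigenvalues          # 1/3, 1/3, 1/12
#' explainedVariance(m, 2)
#' @export
fitPCA <- function(data, scale = FALSE) {
  if (is(data, "ColorDataset")) {
    if (any(missingMask(data)))
      stop("dataset has missing entries; collapse the marker windows first ",
           "(see collapseWindows) or project samples one at a time ",
           "(see projectSample)", call. = FALSE)
    X <- sampleMatrix(data)
    labels <- populationLabels(data)
  } else {
    X <- as.matrix(data)
    if (anyNA(X))
      stop("matrix has missing entries; PCA requires complete data",
           call. = FALSE)
    labels <- rep(NA_character_, nrow(X))
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  if (p < 1L) stop("at least one feature is required", call. = FALSE)

  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    sds[sds == 0] <- 1
    Xc <- sweep(Xc, 2L, sds, `/`)
  }
  r <- min(n - 1L, p)
  sv <- svd(Xc, nu = 0L, nv = r)
  eig <- (sv$d[seq_len(r)]^2) / (n - 1L)
  eig[eig < 0] <- 0
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(r)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  total <- sum(sv$d^2) / (n - 1L)
  frac <- if (total > 0) eig / total else rep(0, r)
  scores <- Xc %*% loadings
  fid <- colnames(X)
  if (is.null(fid)) fid <- paste0("f", seq_len(p))
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(r))
  rownames(loadings) <- fid
  new("PCAModel", center = center, loadings = loadings, eigenvalues = eig,
      explained_fraction = frac, scores = scores, rank = as.integer(r),
      feature_ids = fid, labels = labels, scaled = isTRUE(scale))
}

#' Cumulative explained variance of the top k components
#'
#' @param model a [PCAModel-class].
#' @param k number of leading components, `1 <= k <= rank`.
#' @param as percent values are rounded half away from zero to integer
#'   percent when `digits = 0` (the display convention under which
#'   8/9 = 88.9\% prints as 89\%).
#' @param digits rounding for the percent form.
#' @return named list with `fraction` and `percent`.
#' @export
explainedVariance <- function(model, k, digits = 0) {
  stopifnot(is(model, "PCAModel"))
  k <- .assertCount(k, "k")
  if (k > model@rank)
    stop(sprintf("k = %d exceeds the model rank %d", k, model@rank),
         call. = FALSE)
  frac <- sum(model@explained_fraction[seq_len(k)])
  list(fraction = frac, percent = roundHalfUp(100 * frac, digits))
}

#' Transform data into a fitted PC basis
#'
#' Plain change of basis: `(X - center) %*% loadings[, 1:k]`. Requires the
#' same features as the training data and no missing entries.
#'
#' @param model a [PCAModel-class].
#' @param data [ColorDataset-class] or matrix with matching features.
#' @param k number of components (default: full rank).
#' @return n-by-k score matrix.
#' @export
pcaTransform <- function(model, data, k = model@rank) {
  stopifnot(is(model, "PCAModel"))
  k <- .assertCount(k, "k")
  if (k > model@rank) stop("k exceeds the model rank", call. = FALSE)
  if (is(data, "ColorDataset")) {
    if (any(missingMask(data)))
      stop("data has missing entries; use projectSample()", call. = FALSE)
    X <- sampleMatrix(data)
  } else if (is.null(dim(data))) {
    X <- matrix(as.numeric(data), nrow = 1L)   # a single sample row
  } else X <- as.matrix(data)
  if (ncol(X) != length(model@center))
    stop(sprintf("feature mismatch: model has %d features, data has %d",
                 length(model@center), ncol(X)), call. = FALSE)
  sweep(X, 2L, model@center) %*% model@loadings[, seq_len(k), drop = FALSE]
}

#' Project a single sample with missing features
#'
#' The projection strategy for sparse held-out samples (e.g. ancient
#' genomes): one sample at a time, the centering vector and loadings are
#' restricted to the features that sample observes, and the score is
#' `(x_obs - center_obs) %*% loadings_obs`, optionally rescaled by
#' `p / p_obs` so score magnitudes stay comparable across samples with
#' different amounts of missingness. Samples are never projected jointly,
#' and no shrinkage correction is applied.
#'
#' @param model a [PCAModel-class].
#' @param x length-p numeric vector; missing features as NA (or use
#'   `observed`).
#' @param k number of components to return.
#' @param observed optional logical vector overriding `!is.na(x)`.
#' @param rescale logical; apply the `p / p_obs` factor (default TRUE).
#' @return length-k score vector.
#' @export
projectSample <- function(model, x, k = 2L, observed = NULL,
                          rescale = TRUE) {
  stopifnot(is(model, "PCAModel"))
  k <- .assertCount(k, "k")
  if (k > model@rank) stop("k exceeds the model rank", call. = FALSE)
  x <- as.numeric(x)
  p <- length(model@center)
  if (length(x) != p) stop("feature mismatch", call. = FALSE)
  if (is.null(observed)) observed <- !is.na(x)
  if (sum(observed) < k)
    stop(sprintf("sample observes %d features but %d components requested",
                 sum(observed), k), call. = FALSE)
  L <- model@loadings[observed, seq_len(k), drop = FALSE]
  s <- as.numeric((x[observed] - model@center[observed]) %*% L)
  if (rescale) s <- s * p / sum(observed)
  stats::setNames(s, paste0("PC", seq_len(k)))
}

#' Project every sample of a dataset one at a time
#'
#' Convenience wrapper over [projectSample()] honouring the dataset's
#' missingness mask.
#'
#' @inheritParams projectSample
#' @param data a [ColorDataset-class] with the model's features.
#' @return n-by-k score matrix.
#' @export
projectDataset <- function(model, data, k = 2L, rescale = TRUE) {
  X <- sampleMatrix(data)
  M <- missingMask(data)
  t(vapply(seq_len(nrow(X)), function(i)
    projectSample(model, X[i, ], k, observed = !M[i, ], rescale = rescale),
    numeric(k)))
}

#' Write / read a PCAModel as a plain-text bundle
#'
#' Serializes center, loadings, eigenvalues and metadata to a single TSV
#' with a small header so projections are reproducible across runs.
#'
#' @param model a [PCAModel-class].
#' @param path file path.
#' @return `readPCAModel` returns a list with center, loadings and
#'   eigenvalues (scores are not stored).
#' @export
writePCAModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# PCAModel rank=%d scaled=%s", model@rank,
                     model@scaled), con)
  writeLines(paste(c("eigenvalues", format(model@eigenvalues, digits = 17)),
                   collapse = "\t"), con)
  writeLines(paste(c("feature", "center",
                     paste0("PC", seq_len(model@rank))), collapse = "\t"),
             con)
  tab <- cbind(format(model@center, digits = 17),
               matrix(format(model@loadings, digits = 17),
                      nrow = length(model@center)))
  utils::write.table(cbind(model@feature_ids, tab), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(path) {
  lines <- readLines(path)
  eig <- as.numeric(strsplit(lines[2], "\t")[[1]][-1])
  body <- utils::read.table(text = lines[-(1:3)], sep = "\t",
                            stringsAsFactors = FALSE)
  list(feature_ids = body[[1]], center = as.numeric(body[[2]]),
       loadings = as.matrix(body[, -(1:2), drop = FALSE]) |>
         `dimnames<-`(list(body[[1]], paste0("PC", seq_along(eig)))),
       eigenvalues = eig)
}
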