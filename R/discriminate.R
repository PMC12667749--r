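#' Pearson correlation between ROI mean spectra
#'
#' Correlates the mean (baseline-corrected) spectrum of every ROI with
#' every other; within-class blocks of high correlation against lower
#' cross-preparation blocks visualize how much spectral identity a
#' preparation preserves.
#'
#' @param spectra_sets List of `spectrum_set`s (>= 2), one per ROI, on a
#'   common grid.
#' @return Symmetric correlation matrix with unit diagonal, ROI ids as
#'   dimnames and a `labels` attribute (data.frame: roi_id, tissue, prep).
#' @export
roi_correlation <- function(spectra_sets) {
  stopifnot(length(spectra_sets) >= 2)
  grid <- spectra_sets[[1]]$grid
  for (s in spectra_sets) {
    stopifnot(inherits(s, "spectrum_set"))
    if (!grids_equal(s$grid, grid)) stop("ROIs are not on a common grid")
  }
  means <- t(vapply(spectra_sets, function(s) colMeans(s$matrix),
                    numeric(length(grid$values))))
  sds <- apply(means, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance mean spectrum in ROI ",
         spectra_sets[[which(sds == 0)[1]]]$roi_id)
  }
  m <- stats::cor(t(means))
  ids <- vapply(spectra_sets, function(s) as.character(s$roi_id), "")
  dimnames(m) <- list(ids, ids)
  attr(m, "labels") <- data.frame(
    roi_id = ids,
    tissue = vapply(spectra_sets, function(s) s$tissue, ""),
    prep = vapply(spectra_sets, function(s) s$prep, ""))
  m
}

#' Z-score normalize spectra
#'
#' Default is per-spectrum (SNV-style) normalization - each spectrum
#' independently centered to mean 0 and scaled to standard deviation 1 -
#' which removes per-pixel intensity and offset differences before shape
#' comparison and is invariant to affine transforms of a spectrum.
#' Per-wavenumber (column) standardization is available as an alternative.
#'
#' @param set A `spectrum_set`.
#' @param by `"spectrum"` (default) or `"wavenumber"`.
#' @return A `spectrum_set` with the normalized matrix.
#' @export
zscore_spectra <- function(set, by = c("spectrum", "wavenumber")) {
  stopifnot(inherits(set, "spectrum_set"))
  by <- match.arg(by)
  m <- set$matrix
  if (by == "spectrum") {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0)) {
      bad <- which(sdv == 0)[1]
      stop("constant spectrum cannot be z-scored: pixel (",
           set$pixel_ids$row[bad], ", ", set$pixel_ids$col[bad],
           ") in ROI ", set$roi_id)
    }
    m <- (m - mu) / sdv
  } else {
    sdv <- apply(m, 2, stats::sd)
    if (any(sdv == 0)) stop("constant wavenumber column cannot be z-scored")
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  spectrum_set(set$grid, m, set$pixel_ids, set$roi_id, set$tissue, set$prep)
}

combine_sets <- function(spectra_sets) {
  if (inherits(spectra_sets, "spectrum_set")) spectra_sets <- list(spectra_sets)
  grid <- spectra_sets[[1]]$grid
  for (s in spectra_sets) {
    if (!grids_equal(s$grid, grid)) stop("sets are not on a common grid")
  }
  X <- do.call(rbind, lapply(spectra_sets, function(s) s$matrix))
  labels <- do.call(rbind, lapply(spectra_sets, function(s) {
    data.frame(tissue = s$tissue, prep = s$prep,
               roi_id = as.character(s$roi_id),
               row = s$pixel_ids$row, col = s$pixel_ids$col)
  }))
  list(X = X, labels = labels, grid = grid)
}

#' PCA + UMAP embedding of spectra
#'
#' Reduces (z-scored) spectra to `n_components` principal components and
#' embeds the scores in 2-D with UMAP. Deterministic for fixed inputs and
#' seed (single-threaded layout optimization).
#'
#' @param spectra_sets A `spectrum_set` or list of them (typically
#'   z-score normalized) on a common grid.
#' @param n_components Number of principal components fed to UMAP
#'   (default 20).
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param seed Integer seed for the UMAP layout.
#' @return A list of class `embedding_result`: `coordinates` (n x 2),
#'   `labels` (tissue, prep, roi_id per spectrum), `pca_components`,
#'   `umap_params`.
#' @export
embed_spectra <- function(spectra_sets, n_components = 20, n_neighbors = 15,
                          min_dist = 0.1, seed = 1L) {
  comb <- combine_sets(spectra_sets)
  X <- comb$X
  if (n_components >= ncol(X)) {
    stop("n_components (", n_components, ") must be below the ", ncol(X),
         " spectral features")
  }
  if (nrow(X) <= n_components) {
    stop("need more than n_components spectra, got ", nrow(X))
  }
  if (max(apply(X, 2, stats::sd)) == 0) {
    stop("degenerate input: all spectra are identical")
  }
  scores <- stats::prcomp(X, center = TRUE, scale. = FALSE,
                          rank. = n_components)$x
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  coords <- uwot::umap(scores, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coordinates = coords, labels = comb$labels,
                 pca_components = n_components,
                 umap_params = list(n_neighbors = n_neighbors,
                                    min_dist = min_dist, seed = seed)),
            class = "embedding_result")
}

#' Wavenumber importance from regularized logistic regression
#'
#' Fits an L2-regularized (ridge) logistic regression of a binary class
#' label on the full wavenumber features and ranks wavenumbers by the
#' absolute standardized coefficient (|coefficient| x feature SD, i.e. the
#' coefficient the feature would carry on unit scale). The fit is
#' deterministic: no cross-validation, fixed penalty.
#'
#' @param spectra_sets A `spectrum_set` or list of them (z-scored spectra
#'   recommended) on a common grid.
#' @param response Which label defines the two classes: `"prep"` (default,
#'   FF vs FFPE) or `"tissue"`.
#' @param top_k Number of wavenumbers returned (default 40).
#' @param lambda Ridge penalty (default 1e-3).
#' @return A data.frame of class `feature_ranking` with columns `rank`,
#'   `wavenumber`, `score` (non-increasing), `top_k` rows.
#' @export
feature_importance <- function(spectra_sets, response = c("prep", "tissue"),
                               top_k = 40, lambda = 1e-3) {
  response <- match.arg(response)
  comb <- combine_sets(spectra_sets)
  y <- factor(comb$labels[[response]])
  if (nlevels(y) < 2) {
    stop("need both classes of '", response, "' present, got only: ",
         levels(y))
  }
  if (top_k > ncol(comb$X)) {
    stop("top_k (", top_k, ") exceeds the ", ncol(comb$X), " wavenumbers")
  }
  fit <- glmnet::glmnet(comb$X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.vector(fit$beta)
  score <- abs(beta) * apply(comb$X, 2, stats::sd)
  ord <- order(score, decreasing = TRUE)[seq_len(top_k)]
  structure(data.frame(rank = seq_len(top_k),
                       wavenumber = comb$grid$values[ord],
                       score = score[ord]),
            class = c("feature_ranking", "data.frame"))
}
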