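#' Quantile-normalize a linear-scale expression matrix
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the row-wise mean of the per-column sorted values, with ties within a
#' column receiving the mean of their assigned values.  Row ranks within
#' each column are preserved.  Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param matrix linear-scale probe/gene x sample matrix.
#' @return matrix of the same shape, linear scale.
#' @export
quantile_normalize <- function(matrix) {
  stop_if_not_scale(matrix, "linear", "expression matrix")
  if (ncol(matrix) < 2) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(matrix)) stop("matrix contains missing values", call. = FALSE)
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  set_expr_scale(out, "linear")
}

#' Log2-transform a linear-scale matrix
#'
#' @param matrix linear-scale matrix with strictly positive values.
#' @return log2-scale matrix (scale tag flipped).
#' @export
log2_transform <- function(matrix) {
  stop_if_not_scale(matrix, "linear", "expression matrix")
  if (any(matrix <= 0)) {
    stop("log2 transform requires strictly positive intensities",
         call. = FALSE)
  }
  set_expr_scale(log2(matrix), "log2")
}

#' Center hybridization-batch means per gene
#'
#' For each row, shifts every batch's mean onto the row's global mean, the
#' minimal correction consistent with mean-shift batch structure.  A
#' single-batch matrix is returned unchanged.  Each row's global mean is
#' preserved exactly.
#'
#' @param matrix log2-scale matrix.
#' @param batches per-sample batch labels (length = ncol).
#' @return corrected log2-scale matrix.
#' @export
batch_center <- function(matrix, batches) {
  stop_if_not_scale(matrix, "log2", "expression matrix")
  if (length(batches) != ncol(matrix)) {
    stop("'batches' must have one label per sample", call. = FALSE)
  }
  batches <- as.character(batches)
  tab <- table(batches)
  if (any(tab == 0)) stop("batch with zero samples", call. = FALSE)
  if (length(tab) == 1) return(matrix)
  global <- rowMeans(matrix)
  out <- matrix
  for (b in names(tab)) {
    idx <- which(batches == b)
    out[, idx] <- matrix[, idx] - (rowMeans(matrix[, idx, drop = FALSE]) -
                                     global)
  }
  set_expr_scale(out, "log2")
}

#' Sample-level principal component analysis
#'
#' PCA on samples with per-gene centering; returns sample scores for the
#' first `k` components and the variance fraction of each component (sorted
#' descending over all components).
#'
#' @param matrix log2-scale matrix (rows genes/probes, columns samples).
#' @param k number of components to return.
#' @return list with `scores` (samples x k) and `variance_fraction`.
#' @export
pca_samples <- function(matrix, k = 3) {
  assert_count(k, "k", min = 1)
  if (k > ncol(matrix) - 1) {
    stop("k must be at most the number of samples minus one", call. = FALSE)
  }
  if (nrow(matrix) < k) stop("need at least k genes", call. = FALSE)
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf)
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Agglomerative clustering with distance `1 - Pearson(sample profiles)` and
#' average linkage, the common expression-QC convention.
#'
#' @param matrix log2-scale matrix, >= 2 samples.
#' @return an [stats::hclust] object over samples.
#' @export
hclust_samples <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(matrix)[sds == 0] %||% which(sds == 0)
    stop("constant sample profile (zero variance): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(matrix))
  stats::hclust(d, method = "average")
}

#' Flag samples discordant with their labelled group
#'
#' Cuts the sample dendrogram into two flat clusters and flags every sample
#' whose label differs from its cluster's majority label.  Flags are
#' reported, never auto-removed; dropping a flagged sample is the caller's
#' decision (as in the original QC, where one case clustering with the
#' controls was removed by hand).
#'
#' @param dendrogram an [stats::hclust] object from [hclust_samples()].
#' @param labels per-sample group labels, named by sample or in dendrogram
#'   order; exactly 2 classes, both present.
#' @return list with `flagged` (character vector of sample names),
#'   `clusters` (cluster id per sample) and `labels`.
#' @export
flag_discordant_samples <- function(dendrogram, labels) {
  if (!inherits(dendrogram, "hclust")) {
    stop("'dendrogram' must be an hclust object", call. = FALSE)
  }
  samples <- dendrogram$labels %||% as.character(seq_along(labels))
  if (!is.null(names(labels))) labels <- labels[samples]
  if (length(unique(labels)) != 2) {
    stop("need exactly 2 label classes, both present", call. = FALSE)
  }
  cl <- stats::cutree(dendrogram, k = 2)
  flagged <- character()
  for (k in unique(cl)) {
    idx <- cl == k
    maj <- names(which.max(table(labels[idx])))
    flagged <- c(flagged, samples[idx][labels[idx] != maj])
  }
  list(flagged = sort(flagged), clusters = cl,
       labels = stats::setNames(labels, samples))
}

#' Run the full sample-QC stage
#'
#' Combines PCA, hierarchical clustering and discordant-sample flagging into
#' one QC report.
#'
#' @param matrix log2-scale matrix.
#' @param groups per-sample group labels.
#' @param k number of principal components to report.
#' @return list of class `qc_report` with `pca`, `dendrogram`, `flags`.
#' @export
qc_samples <- function(matrix, groups, k = 3) {
  dend <- hclust_samples(matrix)
  flags <- flag_discordant_samples(dend, stats::setNames(groups,
                                                         colnames(matrix)))
  structure(list(pca = pca_samples(matrix, k = k), dendrogram = dend,
                 flags = flags), class = "qc_report")
}
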