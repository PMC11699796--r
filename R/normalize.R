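#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed the standard RNA-seq way: for each gene
#' the geometric mean across samples is taken as a pseudo-reference, and the
#' size factor of sample j is the median over reference genes (those with a
#' positive geometric mean, i.e. nonzero in every sample) of
#' `count[i, j] / geomean[i]`.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratios <- function(counts) {
  if (ncol(counts) < 1) stop("need at least one sample", call. = FALSE)
  logc <- log(counts)              # zero counts -> -Inf, excluded below
  loggeo <- rowMeans(logc)
  ref <- is.finite(loggeo)
  if (!any(ref)) {
    stop("no gene is nonzero in every sample; median-of-ratios undefined. ",
         "Consider a raw library-size (CPM) normalization instead.",
         call. = FALSE)
  }
  sf <- apply(logc[ref, , drop = FALSE], 2,
              function(lc) exp(stats::median(lc - loggeo[ref])))
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("non-positive size factor computed; check the count matrix",
         call. = FALSE)
  }
  sf
}

#' Normalize counts to a log2 expression matrix
#'
#' Two modes: `cpm_log2` is `log2(1 + 1e6 * count / library_size)` on raw
#' library sizes (used for the global PCA overview); `mor_log2` is
#' `log2(1 + count / s_j)` with median-of-ratios size factors `s_j` (used as
#' the expression level in the QTT regression).
#'
#' @param counts Count matrix (genes x samples).
#' @param mode `"cpm_log2"` or `"mor_log2"`.
#' @param size_factors Optional precomputed size factors for `mor_log2`.
#' @return Numeric matrix of the same shape, with a `"mode"` attribute.
#' @export
normalize_counts <- function(counts, mode = c("cpm_log2", "mor_log2"),
                             size_factors = NULL) {
  mode <- match.arg(mode)
  if (mode == "cpm_log2") {
    libsize <- colSums(counts)
    if (any(libsize == 0)) {
      stop("zero library size in sample(s): ",
           paste(colnames(counts)[libsize == 0], collapse = ", "),
           call. = FALSE)
    }
    e <- log2(1 + sweep(counts, 2, 1e6 / libsize, `*`))
  } else {
    if (is.null(size_factors)) size_factors <- size_factors_median_ratios(counts)
    e <- log2(1 + sweep(counts, 2, size_factors, `/`))
  }
  attr(e, "mode") <- mode
  e
}

#' PCA overview of samples
#'
#' PCA with samples as observations and gene-centered expression values as
#' features. A deterministic sign convention is applied: each component is
#' flipped so that its largest-magnitude gene loading is positive.
#'
#' @param expression Normalized expression matrix (genes x samples),
#'   conventionally `cpm_log2`.
#' @param n_components Number of components to return.
#' @return `list(scores, explained_variance, loadings)`; `scores` is
#'   samples x K, `explained_variance` the per-component fraction of total
#'   variance, `loadings` genes x K.
#' @export
pca_overview <- function(expression, n_components = 3) {
  n <- ncol(expression)
  maxk <- min(n - 1, nrow(expression))
  if (n < 2) stop("PCA needs at least two samples", call. = FALSE)
  if (n_components > maxk) {
    stop("n_components = ", n_components, " exceeds the maximum of ", maxk,
         call. = FALSE)
  }
  pc <- stats::prcomp(t(expression), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[k],
       loadings = loadings)
}

#' Sample-sample correlation matrix
#'
#' Pairwise correlations of whole-transcriptome expression profiles.
#' Constant profiles yield undefined correlations which are reported as
#' `NA`; the diagonal is fixed at 1.
#'
#' @param expression Normalized expression matrix (genes x samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric samples x samples correlation matrix.
#' @export
sample_correlation_matrix <- function(expression,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(expression) < 3) stop("need at least 3 genes", call. = FALSE)
  r <- suppressWarnings(stats::cor(expression, method = method))
  diag(r) <- 1
  r
}
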