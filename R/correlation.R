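#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks. The
#' p-value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' with `n - 2` degrees of freedom; `|rho| = 1` gives `p = 0`. Pairs with a
#' missing value in either vector are dropped (pairwise-complete).
#'
#' @param x,y Numeric vectors of equal length.
#' @return `list(rho, pvalue, n)`; `rho`/`pvalue` are `NA` when fewer than 3
#'   complete pairs remain or either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, pvalue = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, pvalue = spearman_pvalue(rho, n), n = n)
}

# t-approximation p for a Spearman rho at sample size n (vectorized)
spearman_pvalue <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  sat <- !is.na(rho) & abs(rho) >= 1 - 1e-12
  p[sat] <- 0
  mid <- !is.na(rho) & !sat
  tstat <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), n - 2)
  p
}

#' Correlations of focal genes against the transcriptome
#'
#' Spearman correlation of each focal gene (e.g. the three LDH-coding
#' genes) against each target gene; targets default to every non-focal gene
#' in the matrix. Edge p-values are unadjusted, matching the `p < 0.05`
#' network rule.
#'
#' @param expression Normalized expression (genes x samples).
#' @param focal_ids Focal gene IDs (must be rows of `expression`).
#' @param target_ids Optional target gene IDs (default: all non-focal).
#' @return data.frame: `focal_id`, `target_id`, `rho`, `pvalue`, `n`.
#' @export
focal_gene_correlations <- function(expression, focal_ids, target_ids = NULL) {
  missing <- setdiff(focal_ids, rownames(expression))
  if (length(missing) > 0) {
    stop("focal gene ID(s) not in expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(target_ids)) {
    target_ids <- setdiff(rownames(expression), focal_ids)
  } else {
    missing_t <- setdiff(target_ids, rownames(expression))
    if (length(missing_t) > 0) {
      stop("target gene ID(s) not in expression matrix: ",
           paste(missing_t, collapse = ", "), call. = FALSE)
    }
  }
  if (length(target_ids) == 0) {
    return(data.frame(focal_id = character(0), target_id = character(0),
                      rho = numeric(0), pvalue = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  n <- ncol(expression)
  rank_rows <- function(ids) {
    t(apply(expression[ids, , drop = FALSE], 1, rank))
  }
  rf <- rank_rows(focal_ids)
  rt <- rank_rows(target_ids)
  rho <- suppressWarnings(stats::cor(t(rf), t(rt)))   # focal x target
  out <- data.frame(
    focal_id = rep(focal_ids, times = length(target_ids)),
    target_id = rep(target_ids, each = length(focal_ids)),
    rho = as.vector(rho), stringsAsFactors = FALSE)
  out$pvalue <- spearman_pvalue(out$rho, n)
  out$n <- n
  out
}

#' Build a significant-edge correlation network
#'
#' Keeps the correlation rows with `pvalue < p_threshold` (optionally after
#' BH adjustment), drops self-pairs, and returns an undirected `igraph`
#' whose nodes are the genes incident to at least one significant edge and
#' whose edges carry `rho` and `pvalue`.
#'
#' @param correlations data.frame with two ID columns then `rho`, `pvalue`
#'   (e.g. [focal_gene_correlations()] output).
#' @param p_threshold Edge significance threshold (default 0.05).
#' @param adjust Apply BH to the edge p-values first (default `FALSE`,
#'   matching the unadjusted edge rule).
#' @return An undirected `igraph`; attribute `p_threshold` records the rule.
#' @export
build_network <- function(correlations, p_threshold = 0.05, adjust = FALSE) {
  p <- if (adjust) bh_adjust(correlations$pvalue) else correlations$pvalue
  keep <- !is.na(p) & p < p_threshold &
    correlations[[1]] != correlations[[2]]
  edges <- correlations[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[[1]], to = edges[[2]],
               rho = edges$rho, pvalue = edges$pvalue,
               stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  g$p_threshold <- p_threshold
  g
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param network An `igraph` from [build_network()].
#' @param tsv_path Edge-list TSV path (`gene_a`, `gene_b`, `rho`, `pvalue`).
#' @param graphml_path Optional GraphML path.
#' @return `tsv_path`, invisibly.
#' @export
write_network <- function(network, tsv_path, graphml_path = NULL) {
  el <- igraph::as_data_frame(network, what = "edges")
  colnames(el)[1:2] <- c("gene_a", "gene_b")
  utils::write.table(el, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}

#' Pairwise metabolite correlations
#'
#' Spearman rho, p, and pairwise-complete sample counts for every pair of
#' metabolite columns measured at the end of fermentation.
#'
#' @param metabolites data.frame or matrix of numeric columns (samples x
#'   metabolites); missing values are handled pairwise.
#' @return `list(rho, pvalue, n)` of symmetric matrices.
#' @export
metabolite_correlations <- function(metabolites) {
  m <- as.matrix(metabolites)
  storage.mode(m) <- "double"
  vars <- colnames(m)
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pval <- rho
  nmat <- matrix(0L, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in i:k) {
      s <- spearman_cor(m[, i], m[, j])
      rho[i, j] <- rho[j, i] <- s$rho
      pval[i, j] <- pval[j, i] <- s$pvalue
      nmat[i, j] <- nmat[j, i] <- s$n
    }
  }
  list(rho = rho, pvalue = pval, n = nmat)
}
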