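#' Hypergeometric gene-set enrichment
#'
#' One-sided over-representation test per gene set: with universe size `U`,
#' set size `K` (after intersecting the set with the universe), query size
#' `n` and overlap `k`, the p-value is the upper hypergeometric tail
#' `P(X >= k)`. BH adjustment runs across sets; a set is significant when
#' `padj < alpha`.
#'
#' @param query_genes Character vector of query genes (e.g. the DEGs of one
#'   contrast). Genes outside the universe are dropped with a warning.
#' @param universe Character vector of background genes (conventionally all
#'   genes kept in the count matrix).
#' @param gene_sets Named list of gene-ID vectors ([read_gene_sets()]).
#' @param alpha Significance threshold on `padj` (default 0.05).
#' @return data.frame: `set_id`, `k`, `K`, `n`, `U`, `pvalue`, `padj`,
#'   `significant`.
#' @export
enrich_gene_sets <- function(query_genes, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  U <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, U = U, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), U = integer(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- !is.na(out$padj) & out$padj < alpha
  out
}

#' Accumulated fold-change of a gene set in one contrast
#'
#' Sum of log2 fold-changes over the contrast's DEGs (direction != "ns")
#' that belong to the set — the pathway-direction statistic. `scope =
#' "all"` sums over every set gene in the table instead.
#'
#' @param de_table A `de_table`.
#' @param gene_set Character vector of member gene IDs.
#' @param scope `"degs"` (default) or `"all"`.
#' @return `list(accumulated_fc, n_genes)`.
#' @export
accumulated_fc <- function(de_table, gene_set, scope = c("degs", "all")) {
  scope <- match.arg(scope)
  in_set <- de_table$gene_id %in% gene_set
  keep <- if (scope == "degs") in_set & de_table$direction != "ns" else in_set
  lfc <- de_table$log2FC[keep]
  lfc <- lfc[is.finite(lfc)]
  list(accumulated_fc = sum(lfc), n_genes = length(lfc))
}

#' Accumulated fold-change table across contrasts and sets
#'
#' @param de_tables Named list of `de_table`s.
#' @param gene_sets Named list of gene-ID vectors.
#' @param scope Passed to [accumulated_fc()].
#' @return data.frame: `set_id`, `subpopulation`, `accumulated_fc`,
#'   `n_genes`.
#' @export
accumulated_fc_table <- function(de_tables, gene_sets,
                                 scope = c("degs", "all")) {
  scope <- match.arg(scope)
  rows <- list()
  for (sp in names(de_tables)) {
    for (id in names(gene_sets)) {
      a <- accumulated_fc(de_tables[[sp]], gene_sets[[id]], scope)
      rows[[paste(sp, id)]] <- data.frame(
        set_id = id, subpopulation = sp,
        accumulated_fc = a$accumulated_fc, n_genes = a$n_genes,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
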