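#' Cluster-specific signature candidates
#'
#' From each one-vs-rest contrast, within each direction (up / down)
#' separately, candidates are the DEGs whose absolute log2 fold-change
#' exceeds `lfc_min` and whose adjusted p-value ranks in the top
#' `rank_fraction` of all DEGs of that direction (rank `<=
#' ceil(rank_fraction * n_direction)`). Ranks are assigned over all DEGs of
#' the direction (so the magnitude filter cannot promote lower-ranked
#' genes), ascending by `padj`, ties broken by larger `|log2FC|`, then gene
#' ID. `rank_scope = "pooled"` ranks up- and downregulated DEGs of a
#' contrast together instead.
#'
#' @param de_tables Named list of `de_table`s (one per subpopulation).
#' @param lfc_min Absolute log2FC threshold (default 1.6, i.e. ~3-fold).
#' @param rank_fraction Retained fraction of the padj ranking (default 0.5).
#' @param rank_scope `"direction"` (default) or `"pooled"`.
#' @return data.frame: `gene_id`, `subpopulation`, `direction`, `log2FC`,
#'   `padj`, `padj_rank`.
#' @export
css_candidates <- function(de_tables, lfc_min = 1.6, rank_fraction = 0.5,
                           rank_scope = c("direction", "pooled")) {
  rank_scope <- match.arg(rank_scope)
  stopifnot(lfc_min > 0, rank_fraction > 0, rank_fraction <= 1)
  if (is.null(names(de_tables))) {
    stop("de_tables must be a named list (names = subpopulations)",
         call. = FALSE)
  }
  one_block <- function(degs, subpop) {
    if (nrow(degs) == 0) return(NULL)
    ord <- order(degs$padj, -abs(degs$log2FC), degs$gene_id)
    degs <- degs[ord, , drop = FALSE]
    degs$padj_rank <- seq_len(nrow(degs))
    keep <- degs$padj_rank <= ceiling(rank_fraction * nrow(degs)) &
      abs(degs$log2FC) > lfc_min
    degs <- degs[keep, , drop = FALSE]
    if (nrow(degs) == 0) return(NULL)
    data.frame(gene_id = degs$gene_id, subpopulation = subpop,
               direction = degs$direction, log2FC = degs$log2FC,
               padj = degs$padj, padj_rank = degs$padj_rank,
               stringsAsFactors = FALSE)
  }
  pieces <- list()
  for (sp in names(de_tables)) {
    de <- de_tables[[sp]]
    degs <- de[de$direction != "ns", , drop = FALSE]
    if (rank_scope == "direction") {
      for (d in c("up", "down")) {
        pieces[[paste(sp, d)]] <-
          one_block(degs[degs$direction == d, , drop = FALSE], sp)
      }
    } else {
      pieces[[sp]] <- one_block(degs, sp)
    }
  }
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0) {
    return(data.frame(gene_id = character(0), subpopulation = character(0),
                      direction = character(0), log2FC = numeric(0),
                      padj = numeric(0), padj_rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Unique cluster-specific signatures
#'
#' Refines CSS candidates by removing genes that are candidates in more
#' than one subpopulation; uniqueness is at the gene level, so a gene up in
#' one subpopulation and down in another is discarded.
#'
#' @param candidates Output of [css_candidates()].
#' @return `list` of class `css_set`: `candidates` (input plus
#'   `unique_flag`), `unique` (retained rows), `counts` (named per
#'   subpopulation, zero-filled), `total`.
#' @export
unique_css <- function(candidates) {
  n_subpop <- tapply(candidates$subpopulation, candidates$gene_id,
                     function(s) length(unique(s)))
  uniq_genes <- names(n_subpop)[n_subpop == 1]
  candidates$unique_flag <- candidates$gene_id %in% uniq_genes
  uniq <- candidates[candidates$unique_flag, , drop = FALSE]
  counts <- table(factor(uniq$subpopulation,
                         levels = unique(candidates$subpopulation)))
  out <- list(candidates = candidates, unique = uniq,
              counts = stats::setNames(as.integer(counts), names(counts)),
              total = nrow(uniq))
  class(out) <- "css_set"
  out
}

#' @export
print.css_set <- function(x, ...) {
  cat("unique cluster-specific signatures per subpopulation:\n")
  print(x$counts)
  cat("total:", x$total, "\n")
  invisible(x)
}

#' Write a CSS set as TSV
#'
#' Columns: gene_id, subpopulation, direction, log2FC, padj, unique_flag.
#'
#' @param css A `css_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_css <- function(css, path) {
  cols <- c("gene_id", "subpopulation", "direction", "log2FC", "padj",
            "unique_flag")
  utils::write.table(css$candidates[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
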