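# Independent oracles used to check the package implementations.
# These are written from the textbook definitions and deliberately share no
# code with the package.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(k) = min_{j >= k} m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force CSS caller: literal reading of the two-step rule.
css_oracle <- function(de_tables, lfc_min = 1.6, rank_fraction = 0.5) {
  cand <- NULL
  for (sp in names(de_tables)) {
    tab <- de_tables[[sp]]
    for (dir in c("up", "down")) {
      d <- tab[tab$direction == dir, , drop = FALSE]
      if (nrow(d) == 0) next
      ord <- order(d$padj, -abs(d$log2FC), d$gene_id)
      d <- d[ord, , drop = FALSE]
      cutoff <- ceiling(rank_fraction * nrow(d))
      for (i in seq_len(nrow(d))) {
        if (i <= cutoff && abs(d$log2FC[i]) > lfc_min) {
          cand <- rbind(cand, data.frame(gene_id = d$gene_id[i],
                                         subpopulation = sp,
                                         stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(cand)) {
    return(list(candidates = character(0), unique = character(0),
                total = 0L))
  }
  per_gene <- tapply(cand$subpopulation, cand$gene_id,
                     function(s) length(unique(s)))
  uniq <- cand[cand$gene_id %in% names(per_gene)[per_gene == 1], ,
               drop = FALSE]
  list(candidates = sort(unique(paste(cand$gene_id, cand$subpopulation))),
       unique = sort(unique(paste(uniq$gene_id, uniq$subpopulation))),
       total = nrow(unique(uniq)))
}

# All permutations of 1..n (rows), for the exact Spearman permutation test.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Exhaustive two-sided permutation p-value for Spearman rho.
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  P <- all_perms(n)
  ry_perm <- matrix(ry[P], nrow(P))
  rx_c <- rx - mean(rx)
  denom <- sqrt(sum(rx_c^2)) * sqrt(sum((ry - mean(ry))^2))
  rho_all <- abs((ry_perm %*% rx_c) / denom)
  mean(rho_all >= obs - 1e-12)
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of size U containing a marked set of size K.
hyper_enum_p <- function(U, K, n, k) {
  draws <- utils::combn(U, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Random small DE table for CSS oracle-equivalence tests; padj ties are
# injected on purpose to exercise the tie-breaking.
random_de_table <- function(n_genes, gene_pool) {
  ids <- sample(gene_pool, n_genes)
  padj <- round(stats::runif(n_genes), 2)     # coarse -> frequent ties
  lfc <- stats::runif(n_genes, -4, 4)
  direction <- ifelse(padj < 0.5 & abs(lfc) > 1,
                      ifelse(lfc > 0, "up", "down"), "ns")
  structure(
    data.frame(gene_id = ids, base_mean = stats::runif(n_genes, 1, 100),
               log2FC = lfc, lfcSE = 0.1, stat = 0, pvalue = padj,
               padj = padj, direction = direction, converged = TRUE,
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
}
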