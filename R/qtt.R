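#' Expression principal components for the QTT model
#'
#' First `K` principal components of the gene-centered expression matrix
#' with samples as observations; these act as population-structure
#' covariates in the per-gene phenotype regression. Columns are centered by
#' construction and carry the same deterministic sign convention as
#' [pca_overview()].
#'
#' @param expression Normalized expression (genes x samples).
#' @param K Number of components (default 3); `K = 0` returns a zero-column
#'   matrix so the model reduces to intercept + phenotype (+ hidden factors).
#' @return samples x K numeric matrix, columns `PC1..PCK`.
#' @export
compute_pcs <- function(expression, K = 3) {
  n <- ncol(expression)
  if (K == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(colnames(expression), NULL)))
  }
  if (K > n - 1) stop("K = ", K, " exceeds n - 1 = ", n - 1, call. = FALSE)
  ov <- pca_overview(expression, n_components = K)
  scores <- ov$scores
  colnames(scores) <- paste0("PC", seq_len(K))
  scores
}

#' Hidden expression factors by two-step surrogate variable analysis
#'
#' Step one residualizes each gene on the primary model matrix (intercept +
#' phenotype + covariates) and decomposes the residual matrix by SVD. The
#' number of surrogate variables `N` is chosen by a permutation
#' (parallel-analysis) test: each gene's residual vector is permuted
#' independently, the permuted matrix is re-residualized on the model
#' matrix, and a component is kept while its variance share exceeds the
#' `quantile` of the permuted shares for that component (`N` = length of
#' the leading run).
#'
#' Step two rebuilds each retained surrogate from the raw data: the genes
#' significantly associated with the k-th residual eigengene (correlation
#' test, p < `sig_level`) are collected, and the surrogate is the
#' loading-weighted projection of their gene-centered *raw* expression onto
#' the factor (each selected gene weighted by the covariance of its
#' residual with the eigengene — a regression-style factor-score estimate).
#' Rebuilding from raw expression matters: residual eigengenes are
#' orthogonal to the protected design by construction, so they could never
#' absorb the component of a batch factor that is confounded with the
#' phenotype, whereas the raw-expression projection carries it. Surrogates
#' are scaled to unit variance; a surrogate almost entirely explained by
#' the protected design plus earlier surrogates (residual variance fraction
#' < 1%) is dropped to keep the regression design well conditioned.
#'
#' @param expression Normalized expression (genes x samples).
#' @param model_matrix samples x p design protected from removal (must
#'   include the intercept and phenotype).
#' @param B Number of permutations (default 100; must be >= 1).
#' @param quantile Null-share quantile for the keep decision (default 0.95).
#' @param sig_level Per-gene association p-value cutoff used to select the
#'   genes a surrogate is rebuilt from (default 0.05).
#' @param seed Optional integer seed for the permutations.
#' @return samples x N matrix with attributes `shares` (observed residual
#'   variance shares), `null_quantiles`, and `loadings` (genes x N
#'   residual-eigengene loadings, for diagnostics). `N` may be 0.
#' @export
estimate_hidden_factors <- function(expression, model_matrix, B = 100,
                                    quantile = 0.95, sig_level = 0.05,
                                    seed = NULL) {
  if (B < 1) stop("B must be a positive number of permutations", call. = FALSE)
  X <- as.matrix(model_matrix)
  n <- ncol(expression)
  p <- qr(X)$rank
  if (nrow(X) != n) stop("model_matrix rows must match samples", call. = FALSE)
  if (n < p + 2) stop("too few samples (", n, ") for ", p,
                      " model columns plus residual structure", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  H <- X %*% solve(crossprod(X), t(X))     # hat matrix, samples x samples
  M <- diag(n) - H                          # residual-forming projector
  Y <- as.matrix(expression)
  R <- Y %*% M                              # per-gene residuals
  r <- n - p                                # residual rank

  shares_of <- function(A) {
    ev <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)[seq_len(r)]
    ev / sum(ev)
  }
  shares <- shares_of(R)

  G <- nrow(R)
  null_shares <- matrix(NA_real_, B, r)
  for (b in seq_len(B)) {
    perm <- matrix(0, G, n)
    for (i in seq_len(G)) perm[i, ] <- R[i, sample.int(n)]
    null_shares[b, ] <- shares_of(perm %*% M)
  }
  qts <- apply(null_shares, 2, stats::quantile, probs = quantile, names = FALSE)

  keep <- shares > qts
  N <- if (keep[1]) {
    which(c(!keep, TRUE))[1] - 1L           # leading run of exceedances
  } else 0L

  empty <- matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(colnames(expression), NULL))
  if (N == 0) {
    hf <- empty
    loadings <- matrix(numeric(0), nrow = G, ncol = 0)
  } else {
    sv <- svd(R, nu = N, nv = N)
    eig <- sv$v[, seq_len(N), drop = FALSE]  # residual eigengenes
    loadings <- sv$u[, seq_len(N), drop = FALSE] %*%
      diag(sv$d[seq_len(N)], N, N)
    rownames(loadings) <- rownames(expression)

    Yc <- Y - rowMeans(Y)
    surrogates <- list()
    design_so_far <- X
    for (k in seq_len(N)) {
      ek <- eig[, k]
      rho <- as.vector(stats::cor(t(R), ek))
      rho[is.na(rho)] <- 0
      pk <- spearman_pvalue(rho, n)          # t-approx on the correlation
      sel <- which(pk < sig_level)
      sk <- if (length(sel) >= 3) {
        w <- as.vector(R[sel, , drop = FALSE] %*% ek)   # residual loadings
        as.vector(crossprod(Yc[sel, , drop = FALSE], w))
      } else {
        ek                                   # too few genes: keep eigengene
      }
      if (stats::cor(sk, ek) < 0) sk <- -sk
      resid_frac <- sum(qr.resid(qr(design_so_far), sk)^2) / sum(sk^2)
      if (resid_frac < 0.01) next            # redundant with design: drop
      sk <- as.numeric(scale(sk))
      surrogates[[length(surrogates) + 1]] <- sk
      design_so_far <- cbind(design_so_far, sk)
    }
    if (length(surrogates) == 0) {
      hf <- empty
    } else {
      hf <- do.call(cbind, surrogates)
      colnames(hf) <- paste0("HF", seq_len(ncol(hf)))
      rownames(hf) <- colnames(expression)
    }
  }
  attr(hf, "shares") <- shares
  attr(hf, "null_quantiles") <- qts
  attr(hf, "loadings") <- loadings
  hf
}

#' Per-gene phenotype regression
#'
#' Fits, for every gene j, the linear model
#' `E_ij = mu_j + alpha_j LA_i + sum_k beta_jk PC_ik + sum_k gamma_jk HF_ik
#' + e_ij` by ordinary least squares (one shared QR decomposition), and
#' tests `alpha_j` two-sided against t with `n - (2 + K + N)` degrees of
#' freedom. Hidden factors are treated as fixed covariates.
#'
#' @param expression Normalized expression (genes x samples), conventionally
#'   `mor_log2`.
#' @param phenotype Per-sample phenotype vector (lactic acid, g/L).
#' @param pcs samples x K PC score matrix (may have 0 columns).
#' @param hfs samples x N hidden-factor matrix (may have 0 columns).
#' @return `list` of class `qtt_fit`: `table` (data.frame `gene_id`,
#'   `intercept`, `alpha`, `se`, `stat`, `pvalue`), `coefficients` (p x
#'   genes), `residuals` (samples x genes), `df`, `design`.
#' @export
fit_qtt_model <- function(expression, phenotype, pcs = NULL, hfs = NULL) {
  n <- ncol(expression)
  if (length(phenotype) != n) stop("phenotype length must equal sample count",
                                   call. = FALSE)
  if (any(!is.finite(phenotype))) {
    stop("phenotype must be finite for every sample (QTT regression ",
         "requires a lactic acid value per sample)", call. = FALSE)
  }
  if (is.null(pcs)) pcs <- matrix(numeric(0), n, 0)
  if (is.null(hfs)) hfs <- matrix(numeric(0), n, 0)
  X <- cbind(`(Intercept)` = 1, LA = phenotype, pcs, hfs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  df <- n - ncol(X)
  if (df < 1) stop("no residual degrees of freedom (n = ", n, ", p = ",
                   ncol(X), ")", call. = FALSE)
  Y <- t(expression)
  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / df
  R <- qr.R(qx)
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  xtx_inv[qx$pivot, qx$pivot] <- chol2inv(R)
  la_col <- which(colnames(X) == "LA")
  se_alpha <- sqrt(sigma2 * xtx_inv[la_col, la_col])
  alpha <- coefs["LA", ]
  stat <- alpha / se_alpha
  pvalue <- 2 * stats::pt(-abs(stat), df)
  out <- list(
    table = data.frame(gene_id = rownames(expression),
                       intercept = coefs["(Intercept)", ],
                       alpha = alpha, se = se_alpha, stat = stat,
                       pvalue = pvalue, stringsAsFactors = FALSE,
                       row.names = NULL),
    coefficients = coefs, residuals = res, df = df, design = X)
  class(out) <- "qtt_fit"
  out
}

#' Call quantitative trait transcripts
#'
#' BH-adjusts the per-gene phenotype-coefficient p-values and classifies
#' genes with `padj <= alpha` (inclusive) as `positive` or `negative` QTTs
#' by the sign of the coefficient; all others are `none`.
#'
#' @param fit A `qtt_fit` (or its `table`).
#' @param alpha Adjusted-p threshold (default 0.001).
#' @return data.frame (class `qtt_table`): `gene_id`, `alpha`, `se`, `stat`,
#'   `pvalue`, `padj`, `qtt_class`.
#' @export
call_qtts <- function(fit, alpha = 0.001) {
  tab <- if (inherits(fit, "qtt_fit")) fit$table else fit
  padj <- bh_adjust(tab$pvalue)
  cls <- rep("none", nrow(tab))
  hit <- !is.na(padj) & padj <= alpha
  cls[hit & tab$alpha > 0] <- "positive"
  cls[hit & tab$alpha < 0] <- "negative"
  out <- data.frame(gene_id = tab$gene_id, alpha = tab$alpha, se = tab$se,
                    stat = tab$stat, pvalue = tab$pvalue, padj = padj,
                    qtt_class = cls, stringsAsFactors = FALSE)
  class(out) <- c("qtt_table", "data.frame")
  attr(out, "alpha_threshold") <- alpha
  out
}

#' Principal components of the end-point metabolome
#'
#' PCA on the standardized metabolite columns of the sample table (the
#' phenotype column is excluded so the phenotype coefficient stays
#' identifiable). Columns containing missing values are dropped.
#'
#' @param samples Sample table.
#' @param K Number of components.
#' @param cols Metabolite columns to use (default: the standard end-point
#'   panel present in the table).
#' @param exclude Column(s) to exclude (conventionally the phenotype).
#' @return samples x K score matrix, deterministic sign convention.
#' @export
metabolome_pcs <- function(samples, K = 3,
                           cols = c("residual_sugars", "glycerol", "ethanol",
                                    "acetic_acid", "pH", "total_acidity",
                                    "PAN", "ammonia"),
                           exclude = "lactic_acid_30h") {
  cols <- setdiff(intersect(cols, colnames(samples)), exclude)
  m <- as.matrix(samples[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  complete <- colSums(is.na(m)) == 0 & apply(m, 2, stats::sd) > 0
  m <- m[, complete, drop = FALSE]
  if (ncol(m) < K) {
    stop("fewer than K = ", K, " complete, non-constant metabolite columns ",
         "available for metabolome PCs", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  for (j in seq_len(K)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(K))
  rownames(scores) <- samples$sample_id
  scores
}

#' Full QTT analysis from counts
#'
#' Convenience wrapper: normalizes (`mor_log2` by default), computes `K`
#' covariate PCs, estimates hidden factors by SVA against intercept +
#' phenotype + PCs (plus optional metabolite covariates), fits the per-gene
#' model and calls QTTs.
#'
#' The PC covariates default to metabolome PCs ([metabolome_pcs()]); with
#' `pc_source = "expression"` the first `K` expression PCs are used
#' instead. Expression PCs are only appropriate when the phenotype-linked
#' module is a small part of total expression variance — when it dominates,
#' the leading expression PC is nearly collinear with the phenotype and the
#' phenotype coefficient loses identifiability (see the methods vignette).
#' If the metabolome is unavailable the function falls back to expression
#' PCs with a warning.
#'
#' @param counts Count matrix (all-zero genes dropped internally).
#' @param samples Aligned sample table with the phenotype column.
#' @param phenotype_col Phenotype column name (default `"lactic_acid_30h"`).
#' @param K Number of PC covariates (default 3).
#' @param pc_source `"metabolome"` (default) or `"expression"`.
#' @param sva Run surrogate variable analysis (default `TRUE`).
#' @param sva_covariates Optional extra sample-table columns protected in the
#'   SVA model matrix.
#' @param B Number of SVA permutations.
#' @param alpha QTT adjusted-p threshold (default 0.001).
#' @param mode Expression transform for the regression (default
#'   `"mor_log2"`).
#' @param seed Optional seed for the SVA permutations.
#' @return `list`: `qtt` (the `qtt_table`), `fit`, `pcs`, `hfs`,
#'   `expression`.
#' @export
qtt_analysis <- function(counts, samples, phenotype_col = "lactic_acid_30h",
                         K = 3, pc_source = c("metabolome", "expression"),
                         sva = TRUE, sva_covariates = NULL, B = 100,
                         alpha = 0.001, mode = "mor_log2", seed = NULL) {
  pc_source <- match.arg(pc_source)
  if (!phenotype_col %in% colnames(samples)) {
    stop("phenotype column '", phenotype_col, "' is absent from the sample ",
         "table; QTT analysis needs a per-sample lactic acid value",
         call. = FALSE)
  }
  counts <- drop_all_zero_genes(counts)
  expr <- normalize_counts(counts, mode)
  la <- samples[[phenotype_col]]
  pcs <- if (K == 0) {
    compute_pcs(expr, 0)
  } else if (pc_source == "metabolome") {
    tryCatch(metabolome_pcs(samples, K, exclude = phenotype_col),
             error = function(e) {
               warning("metabolome PCs unavailable (", conditionMessage(e),
                       "); falling back to expression PCs")
               compute_pcs(expr, K)
             })
  } else {
    compute_pcs(expr, K)
  }
  hfs <- NULL
  if (sva) {
    # PCs are protected covariates of the final model, so surrogate
    # variables are estimated from structure not already captured by them
    # (otherwise the surrogates duplicate the PCs and the design becomes
    # singular)
    mm <- cbind(1, la, pcs)
    if (!is.null(sva_covariates)) {
      mm <- cbind(mm, as.matrix(samples[, sva_covariates, drop = FALSE]))
    }
    hfs <- estimate_hidden_factors(expr, mm, B = B, seed = seed)
  }
  fit <- fit_qtt_model(expr, la, pcs, hfs)
  list(qtt = call_qtts(fit, alpha = alpha), fit = fit, pcs = pcs, hfs = hfs,
       expression = expr)
}
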