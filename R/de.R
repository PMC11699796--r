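#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up FDR adjustment; `NA` entries are excluded from the number of
#' tests and returned as `NA`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per-gene negative-binomial dispersions under the variance function
#' `var = mu + phi * mu^2`, estimated on size-factor-normalized counts:
#' `phi_i = max(floor, (var_i - mean_i) / mean_i^2)`. A log-linear
#' mean-dispersion trend is fitted by least squares over genes above the
#' floor, and the working dispersion shrinks the gene estimate toward the
#' trend in log space with fixed weight `trend_weight`.
#'
#' @param counts Count matrix (genes x samples), all-zero genes removed.
#' @param size_factors Per-sample size factors; computed if `NULL`.
#' @param floor Lower bound for all dispersions (default `1e-8`).
#' @param trend_weight Weight on the trend in the log-space combination
#'   (default 0.5).
#' @return A data.frame (`gene_id`, `base_mean`, `phi_mom`, `phi_trend`,
#'   `phi_shrunk`) with the fitted trend coefficients as attribute
#'   `"trend_coef"`.
#' @export
estimate_dispersions <- function(counts, size_factors = NULL, floor = 1e-8,
                                 trend_weight = 0.5) {
  if (ncol(counts) < 2) stop("dispersion estimation needs >= 2 samples",
                             call. = FALSE)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratios(counts)
  norm <- sweep(counts, 2, size_factors, `/`)
  mu <- rowMeans(norm)
  if (any(mu <= 0)) {
    stop("all-zero genes must be removed before dispersion estimation",
         call. = FALSE)
  }
  v <- rowSums((norm - mu)^2) / (ncol(norm) - 1)
  phi_mom <- pmax(floor, (v - mu) / mu^2)

  above <- phi_mom > floor
  if (sum(above) >= 2 && stats::sd(log(mu[above])) > 0) {
    fit <- stats::lm.fit(cbind(1, log(mu[above])), log(phi_mom[above]))
    ab <- fit$coefficients
  } else if (any(above)) {
    ab <- c(mean(log(phi_mom[above])), 0)
  } else {
    ab <- c(log(floor), 0)
  }
  phi_trend <- pmax(floor, exp(ab[1] + ab[2] * log(mu)))
  phi_shrunk <- exp(trend_weight * log(phi_trend) +
                      (1 - trend_weight) * log(phi_mom))
  phi_shrunk <- pmax(floor, phi_shrunk)

  out <- data.frame(gene_id = rownames(counts), base_mean = mu,
                    phi_mom = phi_mom, phi_trend = phi_trend,
                    phi_shrunk = phi_shrunk, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "trend_coef") <- stats::setNames(as.numeric(ab),
                                             c("intercept", "slope"))
  attr(out, "floor") <- floor
  out
}

#' One-vs-rest negative-binomial Wald contrast
#'
#' For every gene fits the NB generalized linear model with log link,
#' design `intercept + focal-group indicator`, per-sample offsets
#' `log(size_factor)` and a fixed gene-wise dispersion (variance
#' `mu + phi mu^2`). The focal coefficient divided by `ln 2` is the log2
#' fold-change of the focal subpopulation versus the pooled rest; its
#' standard error comes from the observed information, the Wald statistic is
#' referred to the standard normal, and BH adjustment runs over genes with a
#' defined p-value. A gene is a DEG (`direction` up/down) when
#' `padj < alpha` and `|log2FC| > lfc_threshold`.
#'
#' Fitting is iteratively reweighted least squares, run simultaneously for
#' all genes (the 2x2 weighted normal equations are solved in closed form);
#' convergence is a relative deviance change below `tol`. Genes that fail to
#' converge (including genes with all-zero counts in one group, whose
#' fold-change diverges) are flagged, get `NA` p-values, and do not count
#' toward the BH denominator.
#'
#' @param counts Count matrix (genes x samples), all-zero genes removed.
#' @param samples Sample table aligned to `counts` columns.
#' @param focal Focal subpopulation label (>= 2 samples; rest >= 2).
#' @param dispersions Either the result of [estimate_dispersions()] (its
#'   `phi_shrunk` column is used) or a single numeric / per-gene vector of
#'   fixed dispersions.
#' @param size_factors Optional precomputed size factors.
#' @param alpha FDR threshold of the DEG rule (default 0.05).
#' @param lfc_threshold |log2FC| threshold of the DEG rule (default 1).
#' @param max_iter,tol IRLS controls.
#' @return A `data.frame` (class `de_table`): `gene_id`, `base_mean`,
#'   `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`, `direction`, `converged`,
#'   with attributes `focal` and `thresholds`.
#' @export
de_contrast <- function(counts, samples, focal, dispersions = NULL,
                        size_factors = NULL, alpha = 0.05, lfc_threshold = 1,
                        max_iter = 100, tol = 1e-8) {
  stopifnot(ncol(counts) == nrow(samples))
  x <- as.numeric(samples$subpopulation == focal)
  if (sum(x) < 2) stop("focal group '", focal, "' needs >= 2 samples",
                       call. = FALSE)
  if (sum(1 - x) < 2) stop("reference group needs >= 2 samples", call. = FALSE)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratios(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, size_factors)
  }
  phi <- if (is.data.frame(dispersions)) {
    stopifnot(identical(dispersions$gene_id, rownames(counts)))
    dispersions$phi_shrunk
  } else {
    rep_len(as.numeric(dispersions), nrow(counts))
  }

  y <- counts
  storage.mode(y) <- "double"
  G <- nrow(y); n <- ncol(y)
  off <- matrix(log(size_factors), G, n, byrow = TRUE)
  xm <- matrix(x, G, n, byrow = TRUE)

  norm <- sweep(y, 2, size_factors, `/`)
  base_mean <- rowMeans(norm)
  m1 <- rowSums(norm * xm) / sum(x)
  m0 <- rowSums(norm * (1 - xm)) / sum(1 - x)
  b0 <- log(pmax(m0, 1e-4))
  b1 <- log(pmax(m1, 1e-4)) - b0

  nb_deviance <- function(y, mu, phi) {
    # saturated-minus-fitted log-likelihood, 2x; terms with y = 0 reduce
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
    2 * rowSums(t1 - t2)
  }

  clamp <- 30
  eta <- b0 + b1 * xm
  mu <- pmax(exp(eta + off), 1e-10)
  dev <- nb_deviance(y, mu, phi)
  active <- rep(TRUE, G)
  converged <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    w <- mu / (1 + phi * mu)                 # Fisher weights
    z <- (eta) + (y - mu) / mu               # working response, offset-free part
    sw  <- rowSums(w)
    swx <- rowSums(w * xm)
    sz  <- rowSums(w * z)
    szx <- rowSums(w * z * xm)
    det <- sw * swx - swx^2
    det[det <= 0 | !is.finite(det)] <- NA
    b1_new <- (sw * szx - swx * sz) / det
    b0_new <- (sz - swx * b1_new) / sw
    b1_new <- pmin(pmax(b1_new, -clamp), clamp)
    upd <- active & is.finite(b0_new) & is.finite(b1_new)
    b0[upd] <- b0_new[upd]
    b1[upd] <- b1_new[upd]
    eta <- b0 + b1 * xm
    mu <- pmax(exp(eta + off), 1e-10)
    dev_new <- nb_deviance(y, mu, phi)
    delta <- abs(dev_new - dev) / (abs(dev_new) + 0.1)
    newly <- active & upd & is.finite(delta) & delta < tol
    converged[newly] <- TRUE
    active[newly] <- FALSE
    active[!upd] <- FALSE                    # singular system: give up
    dev <- dev_new
  }
  converged[abs(b1) >= clamp] <- FALSE
  # a group with all-zero counts has a divergent fold-change: flag it
  zero_group <- rowSums(y * xm) == 0 | rowSums(y * (1 - xm)) == 0
  converged[zero_group] <- FALSE

  # observed information: -d2l/deta2 = mu (1 + phi y) / (1 + phi mu)^2
  d <- mu * (1 + phi * y) / (1 + phi * mu)^2
  sd_ <- rowSums(d)
  sdx <- rowSums(d * xm)
  det_d <- sd_ * sdx - sdx^2
  var_b1 <- ifelse(det_d > 0, sd_ / det_d, NA_real_)
  se_b1 <- sqrt(var_b1)

  log2fc <- b1 / log(2)
  lfc_se <- se_b1 / log(2)
  stat <- b1 / se_b1
  pvalue <- 2 * stats::pnorm(-abs(stat))
  bad <- !converged | !is.finite(stat)
  pvalue[bad] <- NA_real_
  padj <- bh_adjust(pvalue)

  direction <- rep("ns", G)
  is_deg <- !is.na(padj) & padj < alpha & abs(log2fc) > lfc_threshold
  direction[is_deg & log2fc > 0] <- "up"
  direction[is_deg & log2fc < 0] <- "down"

  out <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2FC = log2fc, lfcSE = lfc_se, stat = stat,
                    pvalue = pvalue, padj = padj, direction = direction,
                    converged = converged, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  attr(out, "focal") <- focal
  attr(out, "thresholds") <- c(alpha = alpha, lfc = lfc_threshold)
  out
}

#' Run every one-vs-rest contrast
#'
#' @param counts Count matrix (all-zero genes are dropped here).
#' @param samples Aligned sample table.
#' @param ... Passed to [de_contrast()].
#' @return Named list of `de_table`s, one per subpopulation.
#' @export
de_all_contrasts <- function(counts, samples, ...) {
  counts <- drop_all_zero_genes(counts)
  sf <- size_factors_median_ratios(counts)
  disp <- estimate_dispersions(counts, sf)
  subpops <- unique(samples$subpopulation)
  out <- lapply(subpops, function(sp) {
    de_contrast(counts, samples, sp, dispersions = disp, size_factors = sf, ...)
  })
  stats::setNames(out, subpops)
}

#' Summarize DEG counts across subpopulations
#'
#' Produces the per-subpopulation up/down/total table and the dataset means
#' (rounded half away from zero for reporting). Accepts either a named list
#' of `de_table`s or a pre-tabulated data.frame with columns
#' `subpopulation`, `n_up`, `n_down` (e.g. a published summary table).
#'
#' @param x List of `de_table`s or a data.frame of counts.
#' @return `list(table, mean_up, mean_down, mean_total)` of class
#'   `deg_summary`; `table` has columns `subpopulation`, `n_up`, `n_down`,
#'   `n_total`.
#' @export
summarize_degs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subpopulation", "n_up", "n_down") %in% colnames(x)))
    tab <- data.frame(subpopulation = as.character(x$subpopulation),
                      n_up = as.integer(x$n_up), n_down = as.integer(x$n_down),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      subpopulation = names(x),
      n_up = vapply(x, function(d) sum(d$direction == "up"), integer(1)),
      n_down = vapply(x, function(d) sum(d$direction == "down"), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab$n_total <- tab$n_up + tab$n_down
  round_half_away <- function(v) sign(v) * floor(abs(v) + 0.5)
  out <- list(table = tab,
              mean_up = round_half_away(mean(tab$n_up)),
              mean_down = round_half_away(mean(tab$n_down)),
              mean_total = round_half_away(mean(tab$n_total)))
  class(out) <- "deg_summary"
  out
}

#' @export
print.deg_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("mean up: %d   mean down: %d   mean total: %d\n",
              x$mean_up, x$mean_down, x$mean_total))
  invisible(x)
}

#' Write a DE table as TSV
#'
#' @param de A `de_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
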