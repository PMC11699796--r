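#' Synthetic-dataset generator configuration
#'
#' Defaults emulate the study design the analysis assumes: 23 samples in six
#' subpopulations (sizes 3,4,4,4,4,4), ~5000 genes with log-normal baseline
#' means, NB dispersion 0.05, spiked one-vs-rest fold-changes, a
#' phenotype-linked (QTT) gene module on the log2 mean scale, one hidden
#' batch factor, and end-point metabolites drawn from a Gaussian copula
#' hitting the configured rank-correlation targets (lactic-glycerol -0.85,
#' glycerol-ethanol 0.66). Lactic acid group means are 1.0 g/L for the
#' (3-sample) Asia-like group, 3.5 g/L for the three intermediate groups,
#' and 7.5 g/L for the two high-producer groups.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Samples per subpopulation (all >= 2).
#' @param subpopulations Subpopulation labels (same length as
#'   `group_sizes`).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters (natural
#'   log) of baseline expression means.
#' @param dispersion NB dispersion phi (variance `mu + phi mu^2`); 0 gives
#'   Poisson counts.
#' @param n_de_per_group Spiked DE genes per subpopulation.
#' @param de_lfc_range Range of spiked |log2FC| (uniform).
#' @param de_down_prob Probability a spike is downregulated.
#' @param size_factor_sdlog Log-normal spread of true size factors
#'   (geometric mean fixed at 1).
#' @param qtt_n Number of phenotype-linked genes.
#' @param qtt_alpha Magnitude of the true per-g/L log2 expression slope.
#' @param qtt_positive_prob Probability a QTT slope is positive.
#' @param qtt_la_scale Divisor applied to the centered phenotype before
#'   injection (default 1, slopes are per g/L).
#' @param n_hidden Number of hidden batch factors.
#' @param hidden_affected_fraction Fraction of genes loading on each hidden
#'   factor.
#' @param hidden_loading_sd SD of nonzero hidden-factor loadings (log2
#'   units).
#' @param hidden_la_cor Correlation of hidden-factor scores with the
#'   phenotype (0 = unconfounded; used to study confounding).
#' @param la_group_means Phenotype means per subpopulation (g/L).
#' @param la_within_sd Within-subpopulation phenotype SD (g/L).
#' @param lactic_glycerol_rho,glycerol_ethanol_rho Spearman targets of the
#'   metabolite copula.
#' @param seed Default seed used when [simulate_dataset()] is called without
#'   one.
#' @param profile `"study"` (default) or `"large_n"` (group sizes x4, for
#'   power checks).
#' @return Validated list of class `generator_config`.
#' @export
simulator_config <- function(n_genes = 5000,
                             group_sizes = c(3, 4, 4, 4, 4, 4),
                             subpopulations = c("Asia", "Americas",
                                                "Canada_trees",
                                                "Europe_Domestic_1",
                                                "Europe_Domestic_2",
                                                "Europe_Mix"),
                             baseline_meanlog = 4, baseline_sdlog = 1.5,
                             dispersion = 0.05,
                             n_de_per_group = 100, de_lfc_range = c(1, 4),
                             de_down_prob = 0.7,
                             size_factor_sdlog = 0.15,
                             qtt_n = 250, qtt_alpha = 1,
                             qtt_positive_prob = 0.5, qtt_la_scale = 1,
                             n_hidden = 1, hidden_affected_fraction = 0.3,
                             hidden_loading_sd = 0.5, hidden_la_cor = 0,
                             la_group_means = c(1.0, 3.5, 3.5, 3.5, 7.5, 7.5),
                             la_within_sd = 0.75,
                             lactic_glycerol_rho = -0.85,
                             glycerol_ethanol_rho = 0.66,
                             seed = 1, profile = c("study", "large_n")) {
  profile <- match.arg(profile)
  if (profile == "large_n") group_sizes <- group_sizes * 4
  cfg <- list(n_genes = n_genes, group_sizes = group_sizes,
              subpopulations = subpopulations,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, dispersion = dispersion,
              n_de_per_group = n_de_per_group, de_lfc_range = de_lfc_range,
              de_down_prob = de_down_prob,
              size_factor_sdlog = size_factor_sdlog, qtt_n = qtt_n,
              qtt_alpha = qtt_alpha, qtt_positive_prob = qtt_positive_prob,
              qtt_la_scale = qtt_la_scale, n_hidden = n_hidden,
              hidden_affected_fraction = hidden_affected_fraction,
              hidden_loading_sd = hidden_loading_sd,
              hidden_la_cor = hidden_la_cor,
              la_group_means = la_group_means, la_within_sd = la_within_sd,
              lactic_glycerol_rho = lactic_glycerol_rho,
              glycerol_ethanol_rho = glycerol_ethanol_rho,
              seed = seed, profile = profile)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 10)
  if (any(cfg$group_sizes < 2)) {
    stop("every subpopulation needs >= 2 samples", call. = FALSE)
  }
  if (length(cfg$subpopulations) != length(cfg$group_sizes)) {
    stop("subpopulations and group_sizes lengths differ", call. = FALSE)
  }
  if (length(cfg$la_group_means) != length(cfg$group_sizes)) {
    stop("la_group_means must match the number of subpopulations",
         call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$baseline_sdlog <= 0 || cfg$la_within_sd <= 0) {
    stop("baseline_sdlog and la_within_sd must be > 0", call. = FALSE)
  }
  if (cfg$size_factor_sdlog < 0 || cfg$hidden_loading_sd < 0) {
    stop("spread parameters must be >= 0", call. = FALSE)
  }
  if (abs(cfg$lactic_glycerol_rho) > 1 || abs(cfg$glycerol_ethanol_rho) > 1 ||
      abs(cfg$hidden_la_cor) > 1) {
    stop("correlation targets must lie in [-1, 1]", call. = FALSE)
  }
  tot_planted <- length(cfg$group_sizes) * cfg$n_de_per_group + cfg$qtt_n
  if (tot_planted > cfg$n_genes) {
    stop("planted DE + QTT genes exceed n_genes", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# Spearman target -> Pearson correlation of the Gaussian copula latents
copula_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a subpopulation-structured RNA-seq dataset with ground truth
#'
#' Counts are NB(mean = `s_j * q_ij`, dispersion phi) with
#' `log2 q_ij = log2 baseline_i + spike_i,g(j) + alpha_i (LA_j - mean LA) /
#' scale + sum_k loading_ik HF_kj`. The phenotype is drawn per group, the
#' hidden-factor scores are standard normal (optionally correlated with the
#' phenotype), and end-point metabolites come from a Gaussian copula whose
#' latent correlations are chosen to hit the configured Spearman targets.
#' All randomness flows from the single seed in a fixed order.
#'
#' @param config A `generator_config` (default: [simulator_config()]).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return `list` of class `synthetic_dataset`: `counts` (genes x samples
#'   integer matrix), `samples` (sample table with phenotype and
#'   metabolites), `truth` (`de_genes`, `qtt_genes`, `hidden`,
#'   `size_factors`, `config`), `rng` (generator algorithm metadata).
#' @export
simulate_dataset <- function(config = simulator_config(), seed = NULL) {
  cfg <- validate_generator_config(unclass(config))
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)

  n <- sum(cfg$group_sizes)
  G <- cfg$n_genes
  n_group <- length(cfg$group_sizes)
  group <- rep(cfg$subpopulations, cfg$group_sizes)
  sample_ids <- sprintf("S%02d", seq_len(n))
  gene_ids <- sprintf("GENE%05d", seq_len(G))

  # phenotype (lactic acid at sampling time, g/L)
  la <- stats::rnorm(n, mean = rep(cfg$la_group_means, cfg$group_sizes),
                     sd = cfg$la_within_sd)
  la <- pmax(la, 0.05)

  # baseline means and true size factors
  log2_base <- stats::rnorm(G, cfg$baseline_meanlog,
                            cfg$baseline_sdlog) / log(2)
  sf <- exp(stats::rnorm(n, 0, cfg$size_factor_sdlog))
  sf <- sf / exp(mean(log(sf)))

  # planted gene modules: disjoint DE and QTT sets
  n_de_total <- n_group * cfg$n_de_per_group
  planted <- sample.int(G, n_de_total + cfg$qtt_n)
  de_idx <- matrix(planted[seq_len(n_de_total)], ncol = n_group)
  qtt_idx <- planted[n_de_total + seq_len(cfg$qtt_n)]

  log2q <- matrix(log2_base, G, n)

  de_rows <- list()
  for (g in if (cfg$n_de_per_group > 0) seq_len(n_group) else integer(0)) {
    idx <- de_idx[, g]
    mag <- stats::runif(cfg$n_de_per_group, cfg$de_lfc_range[1],
                        cfg$de_lfc_range[2])
    sign_ <- ifelse(stats::runif(cfg$n_de_per_group) < cfg$de_down_prob,
                    -1, 1)
    lfc <- mag * sign_
    in_group <- group == cfg$subpopulations[g]
    log2q[idx, in_group] <- log2q[idx, in_group] + lfc
    de_rows[[g]] <- data.frame(gene_id = gene_ids[idx],
                               subpopulation = cfg$subpopulations[g],
                               true_log2fc = lfc, stringsAsFactors = FALSE)
  }

  alpha <- numeric(0)
  if (cfg$qtt_n > 0) {
    alpha <- cfg$qtt_alpha *
      ifelse(stats::runif(cfg$qtt_n) < cfg$qtt_positive_prob, 1, -1)
    la_c <- (la - mean(la)) / cfg$qtt_la_scale
    log2q[qtt_idx, ] <- log2q[qtt_idx, ] + outer(alpha, la_c)
  }

  hidden_scores <- matrix(numeric(0), n, 0)
  hidden_loadings <- matrix(numeric(0), G, 0)
  if (cfg$n_hidden > 0) {
    la_std <- as.numeric(scale(la))
    hidden_scores <- matrix(0, n, cfg$n_hidden)
    hidden_loadings <- matrix(0, G, cfg$n_hidden)
    free <- setdiff(seq_len(G), planted)
    n_affected <- round(cfg$hidden_affected_fraction * G)
    for (h in seq_len(cfg$n_hidden)) {
      z <- stats::rnorm(n)
      r <- cfg$hidden_la_cor
      hidden_scores[, h] <- r * la_std + sqrt(1 - r^2) * z
      affected <- sample(free, min(n_affected, length(free)))
      hidden_loadings[affected, h] <- stats::rnorm(length(affected), 0,
                                                   cfg$hidden_loading_sd)
    }
    log2q <- log2q + hidden_loadings %*% t(hidden_scores)
  }

  mu <- sweep(2^log2q, 2, sf, `*`)
  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg$dispersion), G, n)
  } else {
    matrix(stats::rpois(G * n, lambda = mu), G, n)
  }
  dimnames(counts) <- list(gene_ids, sample_ids)

  # end-point metabolites via Gaussian copula on the phenotype's normal scores
  z_la <- stats::qnorm(rank(la, ties.method = "average") / (n + 1))
  z_la <- as.numeric(scale(z_la))
  r1 <- copula_pearson(cfg$lactic_glycerol_rho)
  z_gly <- r1 * z_la + sqrt(1 - r1^2) * stats::rnorm(n)
  r2 <- copula_pearson(cfg$glycerol_ethanol_rho)
  z_eth <- r2 * z_gly + sqrt(1 - r2^2) * stats::rnorm(n)
  glycerol <- pmax(6.5 + 1.0 * z_gly, 0.5)
  ethanol <- pmax(10 + 1.0 * z_eth, 1)
  samples <- data.frame(
    sample_id = sample_ids,
    strain = sprintf("strain_%02d", seq_len(n)),
    subpopulation = group,
    lactic_acid_30h = la,
    residual_sugars = pmax(25 + 12 * stats::rnorm(n), 0.5),
    glycerol = glycerol,
    ethanol = ethanol,
    acetic_acid = pmax(0.3 + 0.08 * stats::rnorm(n), 0.01),
    pH = 3.4 - 0.02 * (la - mean(la)) + 0.05 * stats::rnorm(n),
    total_acidity = pmax(3.5 + 0.55 * la + 0.3 * stats::rnorm(n), 0.5),
    PAN = pmax(20 + 5 * stats::rnorm(n), 1),
    ammonia = pmax(8 + 2 * stats::rnorm(n), 0.5),
    stringsAsFactors = FALSE)

  empty_de <- data.frame(gene_id = character(0), subpopulation = character(0),
                         true_log2fc = numeric(0), stringsAsFactors = FALSE)
  truth <- list(
    de_genes = if (length(de_rows)) do.call(rbind, de_rows) else empty_de,
    qtt_genes = data.frame(gene_id = gene_ids[qtt_idx], true_alpha = alpha,
                           stringsAsFactors = FALSE),
    hidden = list(scores = hidden_scores, loadings = hidden_loadings),
    size_factors = stats::setNames(sf, sample_ids),
    config = cfg, seed = seed)

  out <- list(counts = counts, samples = samples, truth = truth,
              rng = list(kind = RNGkind()[1], seed = seed))
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d genes x %d samples, %d subpopulations\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$subpopulation))))
  cat(sprintf("planted: %d DE genes, %d QTT genes, %d hidden factor(s)\n",
              nrow(x$truth$de_genes), nrow(x$truth$qtt_genes),
              ncol(x$truth$hidden$scores)))
  invisible(x)
}

#' Empirical diagnostics of a synthetic dataset
#'
#' Reports the realized mean-variance relationship (median method-of-moments
#' dispersion over well-expressed genes, against the configured value),
#' realized phenotype group means, and realized metabolite rank
#' correlations against their copula targets.
#'
#' @param dataset A `synthetic_dataset`.
#' @param min_mean Minimum normalized mean for a gene to enter the
#'   dispersion summary (default 5; low-count genes have unstable
#'   moment estimates).
#' @return `list(dispersion, phenotype_group_means, metabolite_rho)`.
#' @export
empirical_diagnostics <- function(dataset, min_mean = 5) {
  cfg <- dataset$truth$config
  norm <- sweep(dataset$counts, 2, dataset$truth$size_factors, `/`)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  keep <- mu >= min_mean
  phi_hat <- (v[keep] - mu[keep]) / mu[keep]^2
  sm <- dataset$samples
  gm <- tapply(sm$lactic_acid_30h, sm$subpopulation, mean)
  gm <- stats::setNames(as.numeric(gm[cfg$subpopulations]),
                        cfg$subpopulations)
  list(
    dispersion = list(configured = cfg$dispersion,
                      median_mom = stats::median(phi_hat),
                      n_genes = sum(keep)),
    phenotype_group_means = gm,
    metabolite_rho = list(
      lactic_glycerol = list(
        target = cfg$lactic_glycerol_rho,
        realized = spearman_cor(sm$lactic_acid_30h, sm$glycerol)$rho),
      glycerol_ethanol = list(
        target = cfg$glycerol_ethanol_rho,
        realized = spearman_cor(sm$glycerol, sm$ethanol)$rho)))
}

#' Write a synthetic dataset to disk
#'
#' Writes the counts TSV, sample table TSV, and the ground truth as JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_matrix(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$hidden$scores <- as.data.frame(truth$hidden$scores)
  truth$hidden$loadings <- NULL   # bulky diagnostics; regenerate via seed
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
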