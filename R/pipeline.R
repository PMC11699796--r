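#' Default analysis configuration
#'
#' All thresholds of the pipeline with their documented defaults: DEG rule
#' `padj < 0.05` and `|log2FC| > 1`; CSS rule `|log2FC| > 1.6` with padj
#' rank in the top half per direction; QTT rule `padj <= 0.001`; network
#' edges `p < 0.05` (unadjusted); enrichment `padj < 0.05`; 3 expression
#' PCs; 100 SVA permutations.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    count_dialect = "plain_tsv",
    phenotype_col = "lactic_acid_30h",
    de_alpha = 0.05, de_lfc = 1,
    css_lfc_min = 1.6, css_rank_fraction = 0.5, css_rank_scope = "direction",
    qtt_alpha = 0.001, n_pcs = 3, pc_source = "metabolome", sva = TRUE,
    sva_permutations = 100,
    network_p = 0.05, enrichment_alpha = 0.05,
    accumulated_fc_scope = "degs",
    pca_mode = "cpm_log2", qtt_mode = "mor_log2",
    focal_genes = NULL, gene_sets = NULL, seed = 1)
  ovr <- list(...)
  unknown <- setdiff(names(ovr), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, ovr)
}

stage_entry <- function(stage, outputs, n_rows) {
  list(stage = stage, outputs = as.list(outputs), n_rows = n_rows,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages on files: read/validate -> normalization and global
#' overview (PCA, sample correlations) -> one-vs-rest DE per subpopulation
#' -> gene-set enrichment and accumulated fold-changes -> CSS calling ->
#' focal-gene correlations and significant-edge network -> QTT regression
#' -> end-point metabolite correlations. Every stage writes TSV outputs
#' under `outdir` and is recorded in a JSON run manifest. Stages whose
#' inputs are absent (no gene sets, no focal genes, no phenotype column, no
#' metabolite columns) are skipped and marked as such in the manifest.
#'
#' @param counts_path Path to the count matrix file.
#' @param samples_path Path to the sample table TSV.
#' @param outdir Output directory.
#' @param config [analysis_config()] list; `config$gene_sets` is an optional
#'   GMT path and `config$focal_genes` an optional character vector of focal
#'   gene IDs (e.g. LDH genes).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(counts_path, samples_path, outdir,
                         config = analysis_config()) {
  set.seed(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  current_stage <- "read_inputs"
  on_fail <- function(e) {
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    counts <- read_counts(counts_path, config$count_dialect)
    samples <- read_sample_table(samples_path)
    vd <- validate_dataset(counts, samples)
    counts <- drop_all_zero_genes(vd$counts)
    samples <- vd$samples
    stages$read_inputs <- stage_entry("read_inputs",
                                      c(counts = counts_path,
                                        samples = samples_path),
                                      nrow(counts))

    current_stage <- "normalize_overview"
    sf <- size_factors_median_ratios(counts)
    cpm <- normalize_counts(counts, config$pca_mode)
    pca <- pca_overview(cpm, n_components = min(3, ncol(counts) - 1))
    pca_df <- data.frame(sample_id = colnames(counts), pca$scores,
                         stringsAsFactors = FALSE)
    p_pca <- file.path(outdir, "pca_scores.tsv")
    utils::write.table(pca_df, p_pca, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sc <- sample_correlation_matrix(cpm, "spearman")
    p_sc <- file.path(outdir, "sample_correlations.tsv")
    utils::write.table(data.frame(sample_id = rownames(sc), sc,
                                  check.names = FALSE), p_sc, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p_sf <- file.path(outdir, "size_factors.tsv")
    utils::write.table(data.frame(sample_id = names(sf), size_factor = sf),
                       p_sf, sep = "\t", quote = FALSE, row.names = FALSE)
    stages$normalize_overview <-
      stage_entry("normalize_overview", c(pca = p_pca, correlations = p_sc,
                                          size_factors = p_sf), ncol(counts))

    current_stage <- "differential_expression"
    de_tables <- de_all_contrasts(counts, samples, alpha = config$de_alpha,
                                  lfc_threshold = config$de_lfc)
    de_paths <- character(0)
    for (sp in names(de_tables)) {
      p <- file.path(outdir, paste0("de_", sp, ".tsv"))
      write_de_table(de_tables[[sp]], p)
      de_paths[sp] <- p
    }
    summ <- summarize_degs(de_tables)
    p_summ <- file.path(outdir, "deg_summary.tsv")
    utils::write.table(summ$table, p_summ, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf("DE: %d contrasts; mean up %d, mean down %d",
                    length(de_tables), summ$mean_up, summ$mean_down))
    stages$differential_expression <-
      stage_entry("differential_expression", c(de_paths, summary = p_summ),
                  sum(summ$table$n_total))

    current_stage <- "enrichment"
    if (!is.null(config$gene_sets)) {
      gene_sets <- read_gene_sets(config$gene_sets)
      universe <- rownames(counts)
      enr <- list()
      for (sp in names(de_tables)) {
        de <- de_tables[[sp]]
        degs <- de$gene_id[de$direction != "ns"]
        e <- enrich_gene_sets(degs, universe, gene_sets,
                              alpha = config$enrichment_alpha)
        e$subpopulation <- sp
        enr[[sp]] <- e
      }
      enr <- do.call(rbind, enr)
      p_enr <- file.path(outdir, "enrichment.tsv")
      utils::write.table(enr, p_enr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      afc <- accumulated_fc_table(de_tables, gene_sets,
                                  scope = config$accumulated_fc_scope)
      p_afc <- file.path(outdir, "accumulated_fc.tsv")
      utils::write.table(afc, p_afc, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      stages$enrichment <- stage_entry("enrichment",
                                       c(enrichment = p_enr,
                                         accumulated_fc = p_afc), nrow(enr))
    } else {
      stages$enrichment <- list(stage = "enrichment", skipped = "no gene sets")
    }

    current_stage <- "css"
    cands <- css_candidates(de_tables, lfc_min = config$css_lfc_min,
                            rank_fraction = config$css_rank_fraction,
                            rank_scope = config$css_rank_scope)
    css <- unique_css(cands)
    p_css <- file.path(outdir, "css.tsv")
    write_css(css, p_css)
    message(sprintf("CSS: %d candidates, %d unique", nrow(css$candidates),
                    css$total))
    stages$css <- stage_entry("css", c(css = p_css), nrow(css$candidates))

    current_stage <- "focal_correlations"
    expr_q <- normalize_counts(counts, config$qtt_mode, size_factors = sf)
    if (!is.null(config$focal_genes)) {
      fc <- focal_gene_correlations(expr_q, config$focal_genes)
      net <- build_network(fc, p_threshold = config$network_p)
      p_edges <- file.path(outdir, "network_edges.tsv")
      p_gml <- file.path(outdir, "network.graphml")
      write_network(net, p_edges, p_gml)
      p_fc <- file.path(outdir, "focal_correlations.tsv")
      utils::write.table(fc, p_fc, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      stages$focal_correlations <-
        stage_entry("focal_correlations",
                    c(correlations = p_fc, edges = p_edges, graphml = p_gml),
                    igraph::ecount(net))
    } else {
      stages$focal_correlations <- list(stage = "focal_correlations",
                                        skipped = "no focal genes")
    }

    current_stage <- "qtt"
    if (config$phenotype_col %in% colnames(samples) &&
        !anyNA(samples[[config$phenotype_col]])) {
      qa <- qtt_analysis(counts, samples,
                         phenotype_col = config$phenotype_col,
                         K = config$n_pcs, pc_source = config$pc_source,
                         sva = config$sva,
                         B = config$sva_permutations,
                         alpha = config$qtt_alpha, mode = config$qtt_mode,
                         seed = config$seed)
      p_qtt <- file.path(outdir, "qtt.tsv")
      utils::write.table(as.data.frame(qa$qtt), p_qtt, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p_pcs <- file.path(outdir, "qtt_pcs.tsv")
      utils::write.table(data.frame(sample_id = colnames(counts), qa$pcs),
                         p_pcs, sep = "\t", quote = FALSE, row.names = FALSE)
      p_hfs <- file.path(outdir, "qtt_hidden_factors.tsv")
      hf_df <- data.frame(sample_id = colnames(counts))
      if (!is.null(qa$hfs) && ncol(qa$hfs) > 0) hf_df <- cbind(hf_df, qa$hfs)
      utils::write.table(hf_df, p_hfs, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      n_qtt <- sum(qa$qtt$qtt_class != "none")
      message(sprintf("QTT: %d genes at padj <= %g (%d hidden factors)",
                      n_qtt, config$qtt_alpha,
                      if (is.null(qa$hfs)) 0L else ncol(qa$hfs)))
      stages$qtt <- stage_entry("qtt", c(qtt = p_qtt, pcs = p_pcs,
                                         hidden_factors = p_hfs), n_qtt)
    } else {
      stages$qtt <- list(stage = "qtt",
                         skipped = paste0("phenotype column '",
                                          config$phenotype_col,
                                          "' absent or incomplete"))
    }

    current_stage <- "metabolite_correlations"
    metab_cols <- intersect(c("lactic_acid_30h", "residual_sugars",
                              "glycerol", "ethanol", "acetic_acid", "pH",
                              "total_acidity", "PAN", "ammonia"),
                            colnames(samples))
    if (length(metab_cols) >= 2) {
      mc <- metabolite_correlations(samples[, metab_cols, drop = FALSE])
      p_rho <- file.path(outdir, "metabolite_rho.tsv")
      p_p <- file.path(outdir, "metabolite_pvalues.tsv")
      utils::write.table(data.frame(metabolite = rownames(mc$rho), mc$rho,
                                    check.names = FALSE), p_rho, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(metabolite = rownames(mc$pvalue),
                                    mc$pvalue, check.names = FALSE), p_p,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stages$metabolite_correlations <-
        stage_entry("metabolite_correlations", c(rho = p_rho, pvalues = p_p),
                    length(metab_cols))
    } else {
      stages$metabolite_correlations <-
        list(stage = "metabolite_correlations",
             skipped = "fewer than two metabolite columns")
    }
  }, error = on_fail)

  manifest <- list(
    tool = "fermtrans",
    version = as.character(utils::packageVersion("fermtrans")),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    inputs = list(counts = counts_path, samples = samples_path),
    stages = stages,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
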