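# Small fixtures built in code at test time.

toy_counts <- function() {
  matrix(c(2L, 4L, 3L, 6L, 10L, 20L), nrow = 3, byrow = TRUE,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

write_plain_counts <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_featurecounts <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(Geneid = rownames(m), Chr = "chr1",
                   Start = seq_len(nrow(m)) * 1000,
                   End = seq_len(nrow(m)) * 1000 + 500,
                   Strand = "+", Length = 501L, m, check.names = FALSE)
  con <- file(path, "w")
  writeLines("# Program:featureCounts-like fixture", con)
  close(con)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  path
}

# sample table matching the study layout: 23 samples, six groups (one of 3)
study_sample_table <- function() {
  subpops <- c("Asia", "Americas", "Canada_trees", "Europe_Domestic_1",
               "Europe_Domestic_2", "Europe_Mix")
  sizes <- c(3, 4, 4, 4, 4, 4)
  data.frame(sample_id = sprintf("S%02d", 1:23),
             strain = sprintf("strain_%02d", 1:23),
             subpopulation = rep(subpops, sizes),
             lactic_acid_30h = rep(c(1, 3.5, 3.5, 3.5, 7.5, 7.5), sizes),
             stringsAsFactors = FALSE)
}

write_sample_table_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# NB count matrix with one focal group and optional spiked genes
nb_two_group_counts <- function(n_genes, focal_size = 4, rest_size = 19,
                                phi = 0.05, spiked = integer(0),
                                lfc = 3, meanlog = 4, sdlog = 1.5) {
  n <- focal_size + rest_size
  mu <- exp(stats::rnorm(n_genes, meanlog, sdlog))
  lq <- matrix(log2(mu), n_genes, n)
  if (length(spiked) > 0) {
    lq[spiked, seq_len(focal_size)] <- lq[spiked, seq_len(focal_size)] + lfc
  }
  m <- matrix(stats::rnbinom(n_genes * n, mu = 2^lq, size = 1 / phi),
              n_genes, n,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  m
}

two_group_samples <- function(focal_size = 4, rest_size = 19) {
  data.frame(sample_id = sprintf("s%02d", seq_len(focal_size + rest_size)),
             subpopulation = rep(c("focal", "rest"),
                                 c(focal_size, rest_size)),
             stringsAsFactors = FALSE)
}

# lactic acid vector with the generator's group spread
study_la <- function(within_sd = 0.75) {
  rep(c(1, 3.5, 3.5, 3.5, 7.5, 7.5), c(3, 4, 4, 4, 4, 4)) +
    stats::rnorm(23, 0, within_sd)
}
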