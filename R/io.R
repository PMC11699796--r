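#' Read a gene-level count matrix
#'
#' Parses either a plain TSV (first column gene IDs, one column per sample)
#' or the output of a featureCounts-style counting step (optional leading
#' `#` comment lines, then `Geneid, Chr, Start, End, Strand, Length` followed
#' by one column per sample; the annotation columns are dropped).
#'
#' @param path Path to the count file.
#' @param dialect `"plain_tsv"` or `"featurecounts"`.
#' @return An integer matrix, genes x samples, with gene IDs as row names and
#'   sample IDs as column names, validated by [validate_counts()].
#' @export
read_counts <- function(path, dialect = c("plain_tsv", "featurecounts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("count file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("count file must have a gene-ID column plus at least one sample column: ",
         path, call. = FALSE)
  }
  if (dialect == "featurecounts") {
    ann <- c("Chr", "Start", "End", "Strand", "Length")
    missing_ann <- setdiff(ann, colnames(df))
    if (length(missing_ann) > 0) {
      stop("featurecounts dialect expects annotation columns; missing: ",
           paste(missing_ann, collapse = ", "), call. = FALSE)
    }
    df <- df[, setdiff(colnames(df), ann), drop = FALSE]
  }
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m, context = path)
}

#' Validate a count matrix
#'
#' Enforces the count-matrix contract: unique gene and sample IDs, and
#' non-negative integral values. Offending cells are named in the error.
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param context Optional string (e.g. a file path) prefixed to errors.
#' @return The validated matrix with integer storage mode.
#' @export
validate_counts <- function(m, context = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(context, ": gene and sample IDs are required (dimnames)", call. = FALSE)
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g) > 0) {
    stop(context, ": duplicate gene IDs: ",
         paste(utils::head(dup_g, 5), collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s) > 0) {
    stop(context, ": duplicate sample IDs: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(context, ": invalid count ", format(m[i, j]), " at gene '",
         rownames(m)[i], "', sample '", colnames(m)[j],
         "' (counts must be non-negative integers)", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as plain TSV
#'
#' @param m Count matrix (genes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Requires `sample_id` and `subpopulation` columns; `strain`,
#' `lactic_acid_30h` and any end-point metabolite columns (e.g.
#' `residual_sugars`, `glycerol`, `ethanol`, `acetic_acid`, `pH`,
#' `total_acidity`, `PAN`, `ammonia`) are optional. Metabolite columns are
#' parsed as numeric; missing values are allowed and propagated.
#'
#' @param path Path to a TSV with a header row.
#' @return A `data.frame` with character `sample_id`/`subpopulation` and
#'   numeric phenotype columns.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df, context = path)
}

#' Validate a sample table
#'
#' @param df Data frame of per-sample metadata.
#' @param context Optional string prefixed to error messages.
#' @return The validated data frame.
#' @export
validate_sample_table <- function(df, context = "sample table") {
  required <- c("sample_id", "subpopulation")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop(context, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$subpopulation <- as.character(df$subpopulation)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop(context, ": duplicate sample IDs: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(colnames(df), c("sample_id", "subpopulation", "strain"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    non_numeric <- !is.na(df[[cl]]) & df[[cl]] != "" & is.na(v)
    if (any(non_numeric)) {
      stop(context, ": column '", cl, "' has non-numeric value '",
           df[[cl]][which(non_numeric)[1]], "'", call. = FALSE)
    }
    df[[cl]] <- v
  }
  if ("lactic_acid_30h" %in% colnames(df)) {
    la <- df$lactic_acid_30h
    if (any(!is.na(la) & la < 0)) {
      stop(context, ": lactic_acid_30h must be >= 0", call. = FALSE)
    }
  }
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' member gene IDs. Members are de-duplicated within each set.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set) with a
#'   `"descriptions"` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(path, ": line ", k,
           ": GMT lines need set_id, description and at least one member",
           call. = FALSE)
    }
    id <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(path, ": line ", k, ": set '", id, "' has no members", call. = FALSE)
    }
    sets[[id]] <- members
    descriptions[[id]] <- fields[2]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Match a count matrix against a sample table
#'
#' Checks that the sample IDs agree as sets and reorders count columns to the
#' sample-table order (the table is the sample-order authority for all
#' downstream design matrices).
#'
#' @param counts Count matrix (genes x samples).
#' @param samples Sample table (see [read_sample_table()]).
#' @param verbose Emit a one-line dataset summary via `message()`.
#' @return `list(counts=, samples=)` with aligned sample order.
#' @export
validate_dataset <- function(counts, samples, verbose = FALSE) {
  cs <- colnames(counts)
  ss <- samples$sample_id
  extra <- setdiff(cs, ss)
  missing <- setdiff(ss, cs)
  if (length(extra) > 0 || length(missing) > 0) {
    stop("sample ID mismatch between counts and sample table; only in counts: [",
         paste(extra, collapse = ", "), "]; only in table: [",
         paste(missing, collapse = ", "), "]", call. = FALSE)
  }
  counts <- counts[, ss, drop = FALSE]
  if (verbose) {
    message(sprintf("dataset: %d genes x %d samples, %d subpopulations",
                    nrow(counts), ncol(counts),
                    length(unique(samples$subpopulation))))
  }
  list(counts = counts, samples = samples)
}

#' Drop genes with zero counts in every sample
#'
#' All-zero genes have undefined dispersion and fold-change statistics and
#' are removed before any model fitting; they are also excluded from the
#' number of tests used by the BH adjustment.
#'
#' @param counts Count matrix.
#' @return The filtered matrix.
#' @export
drop_all_zero_genes <- function(counts) {
  counts[rowSums(counts) > 0, , drop = FALSE]
}
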