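#' Taxon-by-sample count table with sample metadata
#'
#' The central container of the count-level pipeline: a taxon x sample matrix
#' of reads plus per-sample metadata (sequencing run, expected sample coverage
#' planned a priori for that run, negative-control flag, and -- for training
#' data -- the true CFU values). Counts are non-negative integers when raw and
#' non-negative reals once normalized across runs.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   dimnames.
#' @param meta data.frame with one row per sample and columns `sample`, `run`,
#'   `expected_coverage`, `is_control`; optionally `true_total_cfu`.
#' @param true_taxon_cfu optional taxa x samples matrix of true per-taxon CFU.
#' @param normalized logical; whether counts have been rescaled by run size
#'   factors.
#' @param taxon_params optional data.frame of per-taxon response parameters
#'   recorded by the synthetic generator.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, meta, true_taxon_cfu = NULL,
                        normalized = FALSE, taxon_params = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample", "run", "expected_coverage", "is_control")
  if (!all(req %in% names(meta)))
    stop("meta must contain columns: ", paste(req, collapse = ", "))
  if (!identical(as.character(meta$sample), colnames(counts)))
    stop("meta$sample must match counts column names in order")
  if (any(!is.finite(meta$expected_coverage)) || any(meta$expected_coverage <= 0))
    stop("expected_coverage must be positive for every sample's run")
  if (!is.null(true_taxon_cfu)) {
    true_taxon_cfu <- as.matrix(true_taxon_cfu)
    stopifnot(identical(dim(true_taxon_cfu), dim(counts)))
  }
  structure(list(counts = counts, meta = meta,
                 true_taxon_cfu = true_taxon_cfu,
                 normalized = isTRUE(normalized),
                 taxon_params = taxon_params),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table>", nrow(x$counts), "taxa x", ncol(x$counts), "samples;",
      sum(x$meta$is_control), "controls;",
      if (x$normalized) "normalized" else "raw", "counts\n")
  invisible(x)
}

#' Per-sample library sizes
#'
#' Column sums of the taxon counts: the total number of reads per sample, the
#' predictor of the total-microbial-load model.
#'
#' @param table a [count_table()].
#' @return named numeric vector, one entry per sample.
#' @export
library_sizes <- function(table) {
  stopifnot(inherits(table, "count_table"))
  colSums(table$counts)
}

#' Write / read a count table as TSV
#'
#' Two plain-text files: the counts matrix (taxa in rows, first column `taxon`)
#' and the sample metadata. True per-taxon CFU, when present, is stored in the
#' counts file as extra rows prefixed `#cfu:` -- kept simple and diff-able.
#'
#' @param table a [count_table()].
#' @param counts_file,meta_file output/input paths.
#' @return `write_count_table` returns the paths invisibly; `read_count_table`
#'   returns a [count_table()].
#' @export
write_count_table <- function(table, counts_file, meta_file) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(table$true_taxon_cfu)) {
    cf <- data.frame(taxon = paste0("#cfu:", rownames(table$counts)),
                     table$true_taxon_cfu, check.names = FALSE)
    utils::write.table(cf, counts_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  }
  meta <- table$meta
  meta$normalized <- table$normalized
  utils::write.table(meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, meta_file))
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_file, meta_file) {
  raw <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cfu_rows <- grepl("^#cfu:", raw$taxon)
  counts <- as.matrix(raw[!cfu_rows, -1, drop = FALSE])
  rownames(counts) <- raw$taxon[!cfu_rows]
  true_taxon_cfu <- NULL
  if (any(cfu_rows)) {
    true_taxon_cfu <- as.matrix(raw[cfu_rows, -1, drop = FALSE])
    rownames(true_taxon_cfu) <- sub("^#cfu:", "", raw$taxon[cfu_rows])
    true_taxon_cfu <- true_taxon_cfu[rownames(counts), , drop = FALSE]
  }
  meta <- utils::read.delim(meta_file, check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta$sample <- as.character(meta$sample)
  normalized <- isTRUE(all(meta$normalized))
  meta$normalized <- NULL
  count_table(counts, meta, true_taxon_cfu = true_taxon_cfu,
              normalized = normalized)
}
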