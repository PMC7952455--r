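#' Within-sample frequency filter
#'
#' Zeroes, within each sample, every taxon whose count is below the frequency
#' cutoff (default 0.2%) of that sample's total reads. "Below" is strict: a
#' taxon sitting exactly at the cutoff is kept. Idempotent.
#'
#' @param table a raw [count_table()].
#' @param cutoff fraction in `[0, 1)`.
#' @return the filtered [count_table()].
#' @export
frequency_filter <- function(table, cutoff = 0.002) {
  stopifnot(inherits(table, "count_table"))
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  if (table$normalized) stop("frequency filter applies to raw counts")
  totals <- colSums(table$counts)
  frac <- sweep(table$counts, 2, pmax(totals, 1), "/")
  table$counts[frac < cutoff & totals[col(table$counts)] > 0] <- 0
  table
}

#' Negative-control decontamination filter
#'
#' For every taxon detected in any negative control, the taxon is zeroed in
#' each non-control sample whose count is no greater than `multiplier` times
#' the taxon's maximum count across controls (the conservative aggregation
#' when several controls are present). Controls are then dropped from the
#' table. With no control samples the table is returned unchanged with a
#' warning.
#'
#' @param table a [count_table()] containing control samples.
#' @param multiplier removal threshold multiplier (default 2).
#' @return the decontaminated [count_table()], controls removed.
#' @export
negative_control_filter <- function(table, multiplier = 2) {
  stopifnot(inherits(table, "count_table"))
  ctrl <- table$meta$is_control
  if (!any(ctrl)) {
    warning("no control samples present; table returned unchanged")
    return(table)
  }
  ctrl_max <- apply(table$counts[, ctrl, drop = FALSE], 1, max)
  for (j in which(ctrl_max > 0)) {
    smp <- !ctrl
    low <- table$counts[j, smp] <= multiplier * ctrl_max[j]
    table$counts[j, which(smp)[low]] <- 0
  }
  table$counts <- table$counts[, !ctrl, drop = FALSE]
  if (!is.null(table$true_taxon_cfu))
    table$true_taxon_cfu <- table$true_taxon_cfu[, !ctrl, drop = FALSE]
  table$meta <- table$meta[!ctrl, , drop = FALSE]
  table
}

#' Cross-run size factors
#'
#' One factor per sequencing run: the run's expected sample coverage (reads
#' per sample planned a priori) divided by the maximum expected coverage over
#' all runs in the table. The best-covered run gets factor 1; factors lie in
#' (0, 1].
#'
#' @param table a [count_table()].
#' @return named numeric vector of per-run factors, class `size_factors`.
#' @export
size_factors <- function(table) {
  stopifnot(inherits(table, "count_table"))
  cov <- tapply(table$meta$expected_coverage, table$meta$run, unique)
  if (any(vapply(cov, length, integer(1)) != 1L))
    stop("expected_coverage must be constant within a run")
  cov <- vapply(cov, identity, numeric(1))
  if (any(!is.finite(cov)) || any(cov <= 0))
    stop("missing or invalid expected coverage for a present run")
  structure(cov / max(cov), class = "size_factors")
}

#' Cross-run normalization
#'
#' Divides every count by its sample's run size factor, shifting counts up for
#' runs sequenced at lower expected coverage; the run at maximal coverage is
#' untouched. Normalized counts are kept as reals. Normalizing an already
#' normalized table errors.
#'
#' @param table a raw [count_table()].
#' @param factors per-run [size_factors()]; computed from the table when
#'   omitted.
#' @return the normalized [count_table()] (`normalized = TRUE`).
#' @export
normalize_counts <- function(table, factors = size_factors(table)) {
  stopifnot(inherits(table, "count_table"))
  if (table$normalized) stop("table is already normalized")
  miss <- setdiff(unique(table$meta$run), names(factors))
  if (length(miss)) stop("missing size factor for run(s): ",
                         paste(miss, collapse = ", "))
  s <- unclass(factors)[table$meta$run]
  table$counts <- sweep(table$counts, 2, s, "/")
  table$normalized <- TRUE
  table
}

#' Build the total-microbial-load model frame
#'
#' One row per non-control sample: the library size (total reads, the
#' predictor) and the true total CFU when recorded.
#'
#' @param table a [count_table()] (normalized or single-run raw).
#' @return data.frame with columns `sample`, `reads`, `cfu`.
#' @export
total_load_frame <- function(table) {
  stopifnot(inherits(table, "count_table"))
  keep <- !table$meta$is_control
  data.frame(sample = table$meta$sample[keep],
             reads = colSums(table$counts[, keep, drop = FALSE]),
             cfu = if ("true_total_cfu" %in% names(table$meta))
               table$meta$true_total_cfu[keep] else NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the taxon-level model frame
#'
#' One row per (taxon, non-control sample): per-taxon read counts and true
#' per-taxon CFU when recorded.
#'
#' @param table a [count_table()].
#' @return data.frame with columns `taxon`, `sample`, `reads`, `cfu`.
#' @export
taxon_frame <- function(table) {
  stopifnot(inherits(table, "count_table"))
  keep <- !table$meta$is_control
  cnt <- table$counts[, keep, drop = FALSE]
  cfu <- if (!is.null(table$true_taxon_cfu))
    table$true_taxon_cfu[, keep, drop = FALSE] else cnt * NA_real_
  data.frame(taxon = rep(rownames(cnt), times = ncol(cnt)),
             sample = rep(colnames(cnt), each = nrow(cnt)),
             reads = as.vector(cnt), cfu = as.vector(cfu),
             stringsAsFactors = FALSE, row.names = NULL)
}
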