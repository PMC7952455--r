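#' Per-read accumulated error
#'
#' Mean per-base error probability of a read: each Phred score is converted to
#' an error probability \eqn{e_i = 10^{-Q_i/10}} and averaged over the read
#' length, \eqn{E = (1/L) \sum e_i}.
#'
#' @param qualities non-empty vector of Phred scores (integers >= 0).
#' @return the accumulated error, a fraction in (0, 1].
#' @examples
#' accumulated_error(rep(20, 10)) # 0.01
#' @export
accumulated_error <- function(qualities) {
  if (length(qualities) == 0) stop("empty quality vector")
  if (any(qualities < 0)) stop("Phred scores must be >= 0")
  mean(10^(-qualities / 10))
}

#' Accumulated-error quality filter
#'
#' A read is discarded iff its accumulated error exceeds the threshold
#' (strictly): the default 0.0035 corresponds to the 0.35% cutoff applied
#' after primer trimming. A read sitting exactly at the threshold survives.
#'
#' @param qualities Phred scores of one (trimmed) read.
#' @param threshold maximum tolerated accumulated error.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
quality_filter <- function(qualities, threshold = 0.0035) {
  accumulated_error(qualities) <= threshold
}

# number of Hamming mismatches between each read prefix and the primer;
# IUPAC degenerate codes in the primer match any of their expansions.
# NA for reads shorter than the primer.
primer_mismatches <- function(sequences, primer) {
  pl <- nchar(primer)
  pr <- strsplit(toupper(primer), "")[[1]]
  allowed <- lapply(pr, function(b) {
    code <- Biostrings::IUPAC_CODE_MAP[[b]]
    if (is.null(code)) stop("invalid primer base: ", b)
    strsplit(code, "")[[1]]
  })
  vapply(sequences, function(s) {
    if (nchar(s) < pl) return(NA_integer_)
    ch <- strsplit(toupper(substr(s, 1, pl)), "")[[1]]
    sum(vapply(seq_len(pl), function(i) !(ch[i] %in% allowed[[i]]),
               logical(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Forward-primer check and trim
#'
#' The forward primer must be present at the beginning of the read with at
#' most one mismatch (Hamming distance over the primer-length prefix;
#' degenerate IUPAC codes in the primer match their expansions). Passing reads
#' are returned with primer bases and qualities removed; failing reads are
#' rejected whole. Reads shorter than the primer are rejected with a distinct
#' reason.
#'
#' @param bases read sequence (character scalar).
#' @param qualities integer Phred scores, same length as the read.
#' @param primer primer sequence (may contain IUPAC degenerate codes).
#' @param max_mismatch maximum tolerated mismatches (default 1).
#' @return a list with `status` (`"kept"`, `"primer_mismatch"` or
#'   `"too_short"`) and, when kept, trimmed `bases` and `qualities`.
#' @export
primer_check_trim <- function(bases, qualities, primer, max_mismatch = 1) {
  if (nchar(primer) == 0) stop("primer must be non-empty")
  stopifnot(nchar(bases) == length(qualities))
  mm <- primer_mismatches(bases, primer)
  if (is.na(mm)) return(list(status = "too_short"))
  if (mm > max_mismatch) return(list(status = "primer_mismatch"))
  pl <- nchar(primer)
  if (nchar(bases) == pl) return(list(status = "too_short"))
  list(status = "kept",
       bases = substr(bases, pl + 1, nchar(bases)),
       qualities = qualities[-seq_len(pl)])
}

#' Filter a FASTQ file: primer check/trim then quality filter
#'
#' Applies [primer_check_trim()] and, on the trimmed read, the accumulated
#' error filter ([quality_filter()]). Surviving reads are written to
#' `output`; the report reconciles exactly with the input read count
#' (`input = primer_failures + quality_failures + surviving`). Phred scores
#' are parsed with the Sanger offset (33).
#'
#' @param input,output FASTQ paths (`output = NULL` skips writing).
#' @param primer forward primer sequence.
#' @param max_error accumulated-error threshold (default 0.0035).
#' @param report optional path; the filter report is written there as JSON.
#' @return a `filter_report` list: `input_reads`, `primer_failures`,
#'   `quality_failures`, `surviving_reads`.
#' @export
filter_fastq <- function(input, output = NULL, primer = "CCTACGGGRSGCAGCAG",
                         max_error = 0.0035, report = NULL) {
  # Biostrings warns about its own temporary metadata columns on FASTQ read
  rq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input))
  seqs <- as.character(rq)
  quals <- as(Biostrings::quality(rq), "IntegerList")
  n <- length(rq)
  pl <- nchar(primer)
  mm <- primer_mismatches(seqs, primer)
  primer_fail <- is.na(mm) | mm > 1 | nchar(seqs) <= pl
  qual_fail <- logical(n)
  for (i in which(!primer_fail)) {
    q <- quals[[i]][-seq_len(pl)]
    qual_fail[i] <- !quality_filter(q, max_error)
  }
  keep <- !primer_fail & !qual_fail
  if (!is.null(output)) {
    kseq <- Biostrings::DNAStringSet(substring(seqs[keep], pl + 1))
    names(kseq) <- names(rq)[keep]
    kqual <- Biostrings::PhredQuality(
      substring(as.character(Biostrings::quality(rq))[keep], pl + 1))
    # writeXStringSet warns about dropping its own temporary metadata column
    suppressWarnings(Biostrings::writeXStringSet(kseq, output,
                                                 format = "fastq",
                                                 qualities = kqual))
  }
  rep <- structure(list(input_reads = n,
                        primer_failures = sum(primer_fail),
                        quality_failures = sum(qual_fail),
                        surviving_reads = sum(keep)),
                   class = "filter_report")
  if (!is.null(report))
    jsonlite::write_json(unclass(rep), report, auto_unbox = TRUE)
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> input:", x$input_reads,
      "| primer failures:", x$primer_failures,
      "| quality failures:", x$quality_failures,
      "| surviving:", x$surviving_reads, "\n")
  invisible(x)
}
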