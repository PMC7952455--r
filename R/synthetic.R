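#' Response-curve parameters for the synthetic generator
#'
#' The generator emulates the saturating relationship between input abundance
#' and sequencing output seen in equivolumetric 16S experiments: expected
#' log10 reads follow a 4-parameter logistic curve in log10 CFU, with a
#' detection floor at low input and a PCR/coverage saturation ceiling at high
#' input. Each taxon gets its own midpoint and steepness drawn around the
#' community defaults, which is exactly the taxon-to-taxon variation the
#' hierarchical model is built to absorb. Count noise is negative-binomial.
#'
#' @param floor log10 expected reads at zero input (default 0, i.e. ~1 stray
#'   read: cross-talk/index-hopping level background).
#' @param ceiling log10 expected reads at saturation (default 4.5).
#' @param midpoint log10 CFU at half-rise of the curve (default 3.5).
#' @param steepness slope of the rise, > 0 (default 1.6).
#' @param dispersion negative-binomial size parameter, > 0 (default 5);
#'   `Inf` gives deterministic rounded means (the no-noise limit).
#' @param taxon_sd named vector with the SD of per-taxon `midpoint` and
#'   `steepness` around the defaults (defaults 0.3 and 0.2).
#' @return an object of class `response_params`.
#' @export
response_params <- function(floor = 0, ceiling = 4.5, midpoint = 3.5,
                            steepness = 1.6, dispersion = 5,
                            taxon_sd = c(midpoint = 0.3, steepness = 0.2)) {
  if (ceiling <= floor) stop("ceiling must exceed floor")
  if (steepness <= 0) stop("steepness must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(floor = floor, ceiling = ceiling, midpoint = midpoint,
                 steepness = steepness, dispersion = dispersion,
                 taxon_sd = taxon_sd),
            class = "response_params")
}

#' Logistic read-response curve
#'
#' Expected log10 reads as a function of log10 CFU for one taxon.
#'
#' @param log10_cfu numeric; `-Inf` (zero input) returns the floor.
#' @param params a [response_params()] (taxon-specific values already
#'   substituted where needed).
#' @param midpoint,steepness optional per-taxon overrides.
#' @return expected log10 read counts.
#' @export
response_curve <- function(log10_cfu, params, midpoint = params$midpoint,
                           steepness = params$steepness) {
  rise <- ifelse(is.infinite(log10_cfu) & log10_cfu < 0, 0,
                 stats::plogis(steepness * (log10_cfu - midpoint)))
  params$floor + (params$ceiling - params$floor) * rise
}

#' Mock serial-dilution experimental design
#'
#' Describes the layout the generator realizes: an even mock community of
#' `taxa` diluted across ordered abundance classes, with `replicates_per_class`
#' samples per dilution level, samples assigned across sequencing `runs` of
#' differing expected coverage, plus negative controls.
#'
#' Two modes reflect the two experiments being emulated:
#' \describe{
#'   \item{`"taxon"`}{every taxon in a sample sits at `taxon_classes[level]`
#'     CFU (the taxon-specific dilution series, K = 4 classes by default).}
#'   \item{`"total"`}{the sample total load is `total_classes[level]` CFU,
#'     split evenly across taxa (the total-load dilution series, K = 5
#'     classes by default).}
#' }
#'
#' @param taxa character taxon labels (default: six mock-community species).
#' @param taxon_classes ordered per-taxon CFU classes.
#' @param total_classes ordered total-load CFU classes.
#' @param replicates_per_class samples per dilution level, >= 1.
#' @param runs data.frame with columns `run` and `expected_coverage` (reads per
#'   sample planned a priori for each sequencing run).
#' @param control_samples number of negative controls (zero input CFU).
#' @param mode `"taxon"` or `"total"`, see Details.
#' @param seed RNG seed; all generator draws flow from it.
#' @return an object of class `dilution_design`.
#' @export
dilution_design <- function(taxa = c("L_monocytogenes", "S_enterica",
                                     "B_cereus", "S_epidermidis",
                                     "E_faecalis", "S_aureus"),
                            taxon_classes = 2 * 10^(2:5),
                            total_classes = 0.84 * 10^(2:6),
                            replicates_per_class = 15,
                            runs = data.frame(
                              run = c("run1", "run2"),
                              expected_coverage = c(60000, 30000),
                              stringsAsFactors = FALSE),
                            control_samples = 2,
                            mode = c("taxon", "total"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (replicates_per_class < 1) stop("replicates_per_class must be >= 1")
  if (any(diff(taxon_classes) <= 0) || any(diff(total_classes) <= 0))
    stop("class values must be strictly increasing")
  if (control_samples < 0) stop("control_samples must be >= 0")
  stopifnot(all(c("run", "expected_coverage") %in% names(runs)),
            all(runs$expected_coverage > 0))
  structure(list(taxa = taxa, taxon_classes = as.numeric(taxon_classes),
                 total_classes = as.numeric(total_classes),
                 replicates_per_class = as.integer(replicates_per_class),
                 runs = runs, control_samples = as.integer(control_samples),
                 mode = mode, seed = as.integer(seed)),
            class = "dilution_design")
}

#' Simulate a mock-dilution count table
#'
#' Realizes a [dilution_design()]: per-taxon expected log10 reads follow the
#' taxon's logistic response curve at its true log10 CFU, expected counts are
#' scaled by the sample's run coverage relative to the maximum coverage (so
#' the cross-run normalization inverts the run effect exactly), and observed
#' counts are negative-binomial around the scaled mean. Negative controls are
#' simulated at zero input, so they carry floor-level background counts.
#' Fully reproducible given the design seed.
#'
#' @param design a [dilution_design()].
#' @param params a [response_params()].
#' @return a [count_table()] whose metadata records run, expected coverage,
#'   control flag, dilution level and true total CFU; true per-taxon CFU is in
#'   `$true_taxon_cfu` and realized per-taxon curve parameters in
#'   `$taxon_params`.
#' @export
simulate_counts <- function(design, params = response_params()) {
  stopifnot(inherits(design, "dilution_design"),
            inherits(params, "response_params"))
  set.seed(design$seed)
  J <- length(design$taxa)
  levels_cfu <- switch(design$mode,
    taxon = design$taxon_classes,
    total = design$total_classes / J)
  L <- length(levels_cfu)
  n_samp <- L * design$replicates_per_class
  n_tot <- n_samp + design$control_samples

  # per-taxon curve parameters around the community defaults
  mid <- stats::rnorm(J, params$midpoint, params$taxon_sd[["midpoint"]])
  stp <- abs(stats::rnorm(J, params$steepness, params$taxon_sd[["steepness"]]))
  stp[stp < 1e-3] <- 1e-3
  taxon_params <- data.frame(taxon = design$taxa, midpoint = mid,
                             steepness = stp, stringsAsFactors = FALSE)

  level <- c(rep(seq_len(L), each = design$replicates_per_class),
             rep(NA_integer_, design$control_samples))
  sample_id <- c(sprintf("s%03d", seq_len(n_samp)),
                 if (design$control_samples > 0)
                   sprintf("ctrl%02d", seq_len(design$control_samples)))
  # balanced run assignment across levels (round robin), controls too
  run_idx <- rep_len(seq_len(nrow(design$runs)), n_tot)
  run <- design$runs$run[run_idx]
  coverage <- design$runs$expected_coverage[run_idx]
  sfac <- coverage / max(design$runs$expected_coverage)

  cfu <- matrix(0, nrow = J, ncol = n_tot,
                dimnames = list(design$taxa, sample_id))
  for (s in seq_len(n_samp)) cfu[, s] <- levels_cfu[level[s]]

  counts <- matrix(0L, nrow = J, ncol = n_tot,
                   dimnames = list(design$taxa, sample_id))
  for (j in seq_len(J)) {
    lg <- ifelse(cfu[j, ] > 0, log10(cfu[j, ]), -Inf)
    mu <- 10^response_curve(lg, params, midpoint = mid[j],
                            steepness = stp[j]) * sfac
    if (is.infinite(params$dispersion)) {
      counts[j, ] <- round(mu)
    } else {
      counts[j, ] <- stats::rnbinom(n_tot, size = params$dispersion, mu = mu)
    }
  }

  total_cfu <- colSums(cfu)
  meta <- data.frame(sample = sample_id, run = run,
                     expected_coverage = coverage,
                     is_control = is.na(level),
                     level = level,
                     true_total_cfu = ifelse(is.na(level), 0, total_cfu),
                     stringsAsFactors = FALSE)
  if (design$mode == "total")
    meta$true_total_cfu[!meta$is_control] <-
      design$total_classes[level[!is.na(level)]]
  count_table(counts, meta, true_taxon_cfu = cfu,
              taxon_params = taxon_params)
}

#' Simulate ordinal outcomes from a cumulative probability model
#'
#' Draws categorical outcomes whose class probabilities follow the
#' cumulative-logit construction \eqn{logit[Pr(Y \le c_k)] = \alpha_k - \beta x}
#' at each supplied predictor value. Used as the generator in
#' parameter-recovery tests of [fit_cpm()].
#'
#' @param n number of outcomes; `x_values` is recycled to length `n`.
#' @param cutpoints non-decreasing cutpoints \eqn{\alpha_1..\alpha_{K-1}}.
#' @param slope slope \eqn{\beta}.
#' @param x_values predictor values (already on the model scale).
#' @param scale an [abundance_scale()] with `K = length(cutpoints) + 1`.
#' @param seed optional RNG seed.
#' @return data.frame with columns `x`, `class` (index) and `cfu`.
#' @export
simulate_from_cpm <- function(n, cutpoints, slope, x_values, scale,
                              seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.unsorted(cutpoints)) stop("cutpoints must be non-decreasing")
  stopifnot(inherits(scale, "abundance_scale"),
            scale$K == length(cutpoints) + 1)
  if (!is.null(seed)) set.seed(seed)
  x <- rep_len(x_values, n)
  probs <- cumulative_class_probs(cutpoints, slope, x)
  cls <- vapply(seq_len(n),
                function(i) sample.int(scale$K, 1, prob = probs[i, ]),
                integer(1))
  data.frame(x = x, class = cls, cfu = scale$classes[cls])
}

#' Spike a contaminant taxon into a count table
#'
#' Test fixture for the negative-control filter: sets a taxon's counts to
#' fixed levels in all control and all non-control samples. The taxon is added
#' if absent.
#'
#' @param table a [count_table()] with at least one control when
#'   `control_level > 0`.
#' @param taxon taxon label.
#' @param control_level,sample_level non-negative counts to place in controls
#'   and samples respectively.
#' @return the modified [count_table()].
#' @export
spike_contamination <- function(table, taxon, control_level, sample_level) {
  stopifnot(inherits(table, "count_table"))
  if (control_level < 0 || sample_level < 0) stop("levels must be >= 0")
  if (!taxon %in% rownames(table$counts)) {
    table$counts <- rbind(table$counts,
                          matrix(0, 1, ncol(table$counts),
                                 dimnames = list(taxon, colnames(table$counts))))
    if (!is.null(table$true_taxon_cfu))
      table$true_taxon_cfu <- rbind(table$true_taxon_cfu,
                                    matrix(0, 1, ncol(table$counts),
                                           dimnames = list(taxon, NULL)))
  }
  table$counts[taxon, table$meta$is_control] <- control_level
  table$counts[taxon, !table$meta$is_control] <- sample_level
  table
}

#' Emit a toy FASTQ file
#'
#' Fixed-length reads with chosen primer prefixes and quality strings, for
#' exercising the read-level filters without real sequencing data.
#'
#' @param path output FASTQ path.
#' @param n number of reads.
#' @param primer primer prefix to prepend (possibly with injected mismatches).
#' @param read_length total read length including the primer.
#' @param quality integer Phred score recycled across cycles, or a vector of
#'   per-read mean scores.
#' @param mismatches integer vector (recycled) of substitutions to inject into
#'   each read's primer prefix.
#' @param seed RNG seed.
#' @return the path, invisibly.
#' @export
simulate_fastq <- function(path, n = 50, primer = "CCTACGGGRSGCAGCAG",
                           read_length = 120, quality = 30, mismatches = 0,
                           seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mismatches <- rep_len(as.integer(mismatches), n)
  quality <- rep_len(as.integer(quality), n)
  primer_concrete <- disambiguate_primer(primer)
  pl <- nchar(primer_concrete)
  # injected mismatches must not accidentally match a degenerate primer code
  allowed <- lapply(strsplit(toupper(primer), "")[[1]], function(b)
    strsplit(Biostrings::IUPAC_CODE_MAP[[b]], "")[[1]])
  recs <- character(4L * n)
  for (i in seq_len(n)) {
    insert <- paste(sample(bases, read_length - pl, replace = TRUE),
                    collapse = "")
    pr <- strsplit(primer_concrete, "")[[1]]
    if (mismatches[i] > 0) {
      eligible <- which(lengths(allowed) < 4)  # N positions can't mismatch
      pos <- sample(eligible, mismatches[i])
      for (p in pos)
        pr[p] <- sample(setdiff(bases, allowed[[p]]), 1)
    }
    seqs <- paste0(paste(pr, collapse = ""), insert)
    q <- pmin(pmax(quality[i] + sample(-2:2, read_length, replace = TRUE), 2), 41)
    recs[4 * i - 3] <- paste0("@read", i)
    recs[4 * i - 2] <- seqs
    recs[4 * i - 1] <- "+"
    recs[4 * i] <- rawToChar(as.raw(q + 33L))
  }
  writeLines(recs, path)
  invisible(path)
}

# one concrete expansion of a degenerate IUPAC primer
disambiguate_primer <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(primer, "")[[1]]
  paste(vapply(ch, function(b) substr(map[[b]], 1, 1), character(1)),
        collapse = "")
}
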