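---
title: "Estimating absolute bacterial abundance from equivolumetric 16S amplicon counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating absolute bacterial abundance from equivolumetric 16S amplicon counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Standard 16S rRNA amplicon workflows normalize DNA input and amplicon
concentration at several points, so the total read count of a sample (its
*library size*) carries no information about how much bacterial biomass went
in: only relative abundances survive. Under an *equivolumetric* protocol —
fixed volumes rather than fixed concentrations at every pooling step — library
sizes track input DNA, and read counts become usable predictors of absolute
bacterial abundance in colony-forming units (CFU).

Two features of such data rule out ordinary regression of CFU on reads:

* calibration experiments observe CFU only on a coarse grid of serial
  dilutions (orders of magnitude apart), not on a continuum;
* the read response saturates: a PCR plateau caps counts at high input, and a
  detection floor censors them at low input, so the reads-vs-CFU relation is
  sigmoid on log–log axes and extrapolation beyond the observed range is
  meaningless.

`microload` therefore treats estimation as **ordinal regression**: the
outcome is the dilution class \(c_1 < \dots < c_K\) (CFU values), and a
Bayesian cumulative probability model (CPM, proportional-odds logit) maps
reads to a full posterior distribution over classes.

## Models

**Total microbial load** (single level). For sample \(i\) with library size
\(x_i\),

\[
Y_i \sim \mathrm{Categorical}(p_i), \qquad
\mathrm{logit}\,\Pr(Y_i \le c_k) = \alpha_k - \beta\,\tilde x_i ,
\]

with \(K - 1\) ordered cutpoints \(\alpha_k\) and one slope \(\beta\)
(positive values push mass toward higher classes). Priors are weakly
informative: \(\alpha_k \sim \mathcal N(0, 5)\),
\(\beta \sim \mathcal N(0, 5)\) (standard deviations). The default scale is
the five-class total-load grid \(\{0.84\times10^2, \dots, 0.84\times10^6\}\)
CFU.

**Taxon-specific abundance** (hierarchical). For observation \(i\) of taxon
\(j\) with per-taxon read count \(x_{ij}\), each taxon receives its own
cutpoints and slope, partially pooled around population values:

\[
\mathrm{logit}\,\Pr(Y_{ij} \le c_k) = \alpha_{kj} - \beta_j\,\tilde x_{ij},
\qquad
(\alpha_{1j},\dots,\alpha_{K-1,j},\beta_j)^\top \sim
\mathcal N_K\!\big((\alpha_1,\dots,\alpha_{K-1},\beta)^\top,\ \Sigma\big),
\]

\(\Sigma = \mathrm{diag}(\sigma)\,\mathcal R\,\mathrm{diag}(\sigma)\) with
\(\sigma_{\alpha_k}, \sigma_\beta \sim \mathrm{Exponential}(1)\) and
\(\mathcal R \sim \mathrm{LKJ}(2)\). Population locations have
\(\mathcal N(0, 2.5)\) priors. The taxon scale is the four-class grid
\(\{2\times10^2, \dots, 2\times10^5\}\) CFU. The per-taxon effect vector is
modeled as one joint \(K\)-dimensional multivariate normal (3 cutpoint
offsets + 1 slope offset) with a full correlation matrix — the standard
varying-intercepts/varying-slopes structure; the source describes the
covariance per cutpoint–slope pair, and the joint form is the natural
multivariate completion of that description. Random effects are sampled
non-centered.

**Predictor transform.** Both models use \(\tilde x =\) standardized
\(\log_{10}(x + 1)\). The pseudocount keeps zero counts finite; the log scale
matches the orders-of-magnitude spread of amplicon counts; standardization
(mean/SD of the *training* predictor, frozen into the fit and reused verbatim
at prediction time) stabilizes sampling. The source never states the
predictor transform for the linear predictor explicitly; this choice follows
its log10 axes and pseudocount convention and is flagged as an
interpretation.

**Derived quantities.** From the posterior draws, `predict()` and
`predict_taxon()` return per observation: posterior-mean class probabilities;
cumulative and tail probabilities \(\Pr(Y \ge c_k)\) (with
\(\Pr(Y \ge c_1) \equiv 1\)); the conditional expectation
\(\sum_k c_k p_{ik}\) per draw, summarized by mean and central 95% credible
interval; the class of highest probability (CHP), with ties broken toward the
lower class (conservative for contamination claims); and a 95% predictive
class interval grown contiguously from the CHP by repeatedly absorbing the
higher-mass neighbor until it holds at least 0.95 posterior-mean mass. The
interval construction is not specified in the source; this greedy contiguous
rule reproduces the interval bands its figures show. Expectation and CHP are
bounded within \([c_1, c_K]\) by construction. `predict_unseen()` predicts a
taxon never seen in training by drawing, for each posterior draw, a new
effect vector from that draw's population distribution (rebuilding
\(\Sigma\) from \(\sigma\) and \(\mathcal R\)), so its intervals include
between-taxon variation; effect draws with unordered cutpoints — a
zero-density region of the model — are redrawn.

## Preprocessing

Read-level filters (`filter_fastq`): the forward primer must sit at the read
start with at most one mismatch (Hamming distance over the prefix; IUPAC
degenerate codes in the primer match their expansions — treating them as
mismatches would reject every read, since the V3/V4 primers contain R, S, H,
V, W); the primer is then trimmed and the read discarded if its accumulated
error \(E = \tfrac1L \sum_i 10^{-Q_i/10}\) exceeds 0.35% *strictly* (a read
exactly at the threshold survives — literal reading of "above"). The error
filter sees the *trimmed* read; the source does not state the order, and this
interpretation is flagged. Phred scores are parsed at the Sanger offset 33.

Count-level filters: within each sample, taxa strictly below 0.2% of the
sample total are zeroed; taxa detected in negative controls are zeroed in
every sample where their count is no greater than twice the taxon's maximum
count across controls (the per-taxon maximum is the conservative aggregation
when several controls exist), after which controls are dropped. The removal
sentence in the source is grammatically ambiguous about which count is
compared to twice which; `sample <= 2 x control` is the only reading that
removes contamination, and is what is implemented. Filters run in the listed
order, before normalization; both are idempotent.

Cross-run normalization: each run's size factor is its expected sample
coverage (reads per sample planned a priori) divided by the maximum expected
coverage over runs; counts are divided by the factor, so counts are only ever
shifted *up* and the best-covered run is untouched. With a single run (or
equal coverages) normalization is the identity. Normalized counts stay real
valued. This is deliberately not a DESeq2/edgeR median-of-ratios factor:
those remove biomass signal, which is exactly what must be preserved here.

## Synthetic mock-dilution generator

The generator (`dilution_design` + `simulate_counts`) emulates the
calibration experiment so the entire pipeline is testable offline:

* expected log10 reads for a taxon follow a 4-parameter logistic curve in
  log10 CFU — floor 0 (about one stray background read at zero input),
  ceiling 4.5, midpoint 3.5, steepness 1.6 — reproducing the detection
  floor / saturation shape of the calibration figures. The source reports the
  sigmoid shape but not fitted curve parameters, so these defaults are
  calibrated qualitatively, once;
* per-taxon midpoints and steepness are drawn
  \(\mathcal N(3.5, 0.3^2)\) / \(\mathcal N(1.6, 0.2^2)\) (truncated
  positive): the taxon-to-taxon variation the hierarchical model must absorb;
* counts are negative-binomial with dispersion 5 (overdispersed, integer,
  non-negative); `dispersion = Inf` gives the deterministic no-noise limit
  used by tests;
* expected counts in each sequencing run are scaled by
  coverage/max-coverage, so the size-factor normalization inverts the run
  effect *exactly* — giving the normalization test a known ground truth. The
  default design uses two runs at 60,000 and 30,000 expected reads;
* negative controls are simulated at zero input (floor-level background
  counts only); heavier contamination fixtures are made explicitly with
  `spike_contamination()`.

Two design modes mirror the two experiments: `"total"` (5 total-load classes,
the total split evenly across taxa; default 20 replicates per class) and
`"taxon"` (every taxon at the same per-taxon class; 4 classes, default 15
replicates). What the generator does **not** emulate: chimeras, base-level
sequencing error, uneven community compositions, taxonomy misassignment. A
green test therefore establishes correctness of the statistical machinery on
data with the assumed structure — not robustness to the full messiness of
real amplicon data.

## Computation

The models are fitted by Hamiltonian Monte Carlo implemented in the package
(Rcpp): no external probabilistic-programming framework is required. Cutpoint
ordering is enforced by an increment parametrization (first cutpoint free,
log gaps); scales are sampled on the log scale; the correlation matrix
through tanh canonical partial correlations of its Cholesky factor (the LKJ
prior and all transform Jacobians included in the target density). Gradients
are analytic except for the six partial-correlation coordinates, which are
differenced through a cheap \(4\times4\) construction. Warmup adapts the step
size by dual averaging (target acceptance 0.95) and a diagonal mass matrix
over two windows; trajectory lengths are jittered uniformly up to 64 leapfrog
steps. Chains run sequentially, seeded `seed + chain`, through R's RNG — fits
are bit-reproducible given a seed.

Convergence is summarized by split-chain \(\widehat R\) and effective sample
size for every parameter; a fit with any \(\widehat R \ge 1.01\) is flagged
and `predict()` refuses it by default. Defaults are 4 chains, 1000 warmup,
1000 kept draws (2000 kept for the hierarchical model, whose posterior —
strongly separated classes, near-boundary scales — needs the extra draws to
clear the 1.01 threshold reliably). Cross-validation refits
(`run_cv`) default to 500+500 draws per chain since dozens of fits are
needed; a fold refit whose \(\widehat R\) is marginal warns rather than
aborting, because fold-level summaries average over refits and the
acceptance-grade diagnostics are enforced on the primary fits.

## Validation machinery

`run_cv()` supports stratified 10-fold CV (stratified by outcome class, and
by taxon-class for the hierarchical model — small per-class counts make
unstratified folds degenerate; the source does not state whether its CV was
stratified), a 10% stratified holdout, and leave-one-group-out CV in which
each taxon is held out entirely and predicted via `predict_unseen()`. Metrics
are computed for CHP-based (classification) and expectation-based
(regression) predictions: MALR
\(= \tfrac1n \sum |\log_{10}(\hat y_i / y_i)|\) (error in orders of
magnitude), MAEr \(= \tfrac1n \sum |\hat y_i - y_i| / y_i\) (error relative
to truth), classification accuracy, Spearman rank correlation, Somers'
\(D_{xy}\) (pairs tied on the observed class excluded from the denominator,
pairs tied on predictions included — the convention is fixed here because the
source names the metric without a formula), and observed coverage of the 95%
intervals (predictive class interval for CHP, credible interval of the
expectation otherwise; expectation-based classification metrics map the
expectation to the nearest class in log10 space).

## Known limitations

* The generator's response-curve defaults are qualitative; absolute metric
  values on synthetic data are indicative, not a reproduction of the original
  measurements (which require the deposited sequencing data).
* The expectation is dominated by the largest classes whenever upper-class
  probabilities are not vanishingly small — an inherent property of averaging
  CFU values that span four orders of magnitude. Expectation-based relative
  errors (MAEr) at the lowest dilution are therefore large in the synthetic
  world even when classification is nearly perfect; the CHP is the better
  point prediction at the extremes of the scale.
* Prior selection via approximate leave-one-out model comparison is not
  re-run; priors are taken as stated.
* With six taxa the population-level scales and correlations are weakly
  identified; unseen-taxon intervals are wide by construction.
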