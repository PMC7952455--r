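# shared fixtures; heavyweight fits are memoized so several test files can
# assert against the same posterior without refitting

quick_ctl <- function(chains = 2, warmup = 300, iter = 300)
  mcmc_control(chains = chains, warmup = warmup, iter = iter)

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# small total-load dataset + single-level fit
total_fixture <- function() {
  memo("total_fixture", {
    d <- dilution_design(mode = "total", replicates_per_class = 10, seed = 4)
    tab <- normalize_counts(simulate_counts(d))
    df <- total_load_frame(tab)
    fit <- fit_cpm(df$reads, df$cfu, total_scale(),
                   control = quick_ctl(warmup = 400, iter = 400), seed = 1)
    list(tab = tab, df = df, fit = fit)
  })
}

# small taxon-level dataset + hierarchical fit
hier_fixture <- function() {
  memo("hier_fixture", {
    d <- dilution_design(mode = "taxon", replicates_per_class = 8, seed = 2)
    tab <- normalize_counts(simulate_counts(d))
    df <- taxon_frame(tab)
    fit <- fit_cpm_hier(df$reads, df$cfu, df$taxon, taxon_scale(),
                        control = quick_ctl(warmup = 500, iter = 600), seed = 1)
    list(tab = tab, df = df, fit = fit)
  })
}

# hand-built single-level fit with an (almost) point-mass posterior, for
# deterministic prediction assertions
degenerate_cpm_fit <- function(cutpoints = c(30, 40, 50, 60), slope = 0,
                               scale = total_scale()) {
  draws <- rbind(c(cutpoints, slope), c(cutpoints, slope))
  colnames(draws) <- c(paste0("alpha", seq_len(scale$K - 1)), "beta")
  structure(list(draws = draws, chains = 1,
                 diagnostics = list(rhat = rep(1, ncol(draws)),
                                    ess = rep(2, ncol(draws))),
                 transform = identity_transform(), scale = scale,
                 priors = list(cutpoint_sd = 5, slope_sd = 5),
                 seed = 1, converged = TRUE),
            class = "cpm_fit")
}

# hand-built hierarchical fit whose between-taxon scales are ~0 and whose
# taxon effects equal the population values
degenerate_hier_fit <- function(alpha = c(-2, 0, 2), beta = 3,
                                taxa = c("tA", "tB"),
                                scale = taxon_scale()) {
  K <- scale$K
  m <- K
  eff <- c(paste0("alpha", seq_len(K - 1)), "beta")
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  nm <- c(eff, paste0("sigma_", eff),
          paste0("R_", eff[pairs[, 1]], "_", eff[pairs[, 2]]),
          as.vector(t(outer(taxa, eff, paste, sep = "."))))
  row <- c(alpha, beta, rep(1e-10, m), rep(0, nrow(pairs)),
           rep(c(alpha, beta), length(taxa)))
  draws <- rbind(row, row)
  colnames(draws) <- nm
  structure(list(draws = draws, chains = 1,
                 diagnostics = list(rhat = rep(1, ncol(draws)),
                                    ess = rep(2, ncol(draws))),
                 transform = identity_transform(), scale = scale,
                 taxa = taxa,
                 priors = list(pop_sd = 2.5, scale_rate = 1, lkj_eta = 2),
                 seed = 1, converged = TRUE),
            class = "cpm_hier_fit")
}

# exhaustive O(n^2) pair enumeration oracle for Somers' Dxy
somers_brute <- function(pred, obs) {
  conc <- disc <- tiex <- 0
  n <- length(pred)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (obs[i] == obs[j]) next
    s <- sign(pred[i] - pred[j]) * sign(obs[i] - obs[j])
    if (s > 0) conc <- conc + 1
    else if (s < 0) disc <- disc + 1
    else tiex <- tiex + 1
  }
  (conc - disc) / (conc + disc + tiex)
}
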