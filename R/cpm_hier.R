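#' Fit the hierarchical cumulative probability model
#'
#' Multilevel proportional-odds regression for taxon-specific abundance:
#' every taxon gets its own cutpoints and slope, drawn around the
#' population-level parameters from one joint multivariate normal over the
#' effect vector (K-1 cutpoint offsets + slope offset). The covariance is
#' built from per-parameter scales with Exponential(`scale_rate`) priors and a
#' correlation matrix with an LKJ(`lkj_eta`) prior; population cutpoints and
#' slope carry Normal(0, `pop_sd`) priors. Random effects are sampled
#' non-centered. Prediction for taxa seen in training uses their posterior
#' effects ([predict_taxon()]); unseen taxa are predicted by integrating over
#' the population distribution ([predict_unseen()]).
#'
#' @param x predictor: per-taxon read counts (raw unless `transform` is the
#'   identity). The transform (standardized `log10(x+1)`) is shared across
#'   taxa and frozen at fit time.
#' @param y observed per-taxon CFU classes (values from `scale`).
#' @param taxon taxon label per observation; at least 2 distinct taxa.
#' @param scale an [abundance_scale()] (K = 4 for the mock dilution design).
#' @param priors list with `pop_sd` (2.5), `scale_rate` (1), `lkj_eta` (2).
#' @param control an [mcmc_control()].
#' @param seed integer seed; chain c uses `seed + c`.
#' @param transform predictor transform, default frozen from pooled `x`.
#' @return an object of class `cpm_hier_fit` with the posterior draw matrix
#'   (population parameters, scales, correlations, per-taxon effects),
#'   diagnostics, transform, scale and taxon labels.
#' @export
fit_cpm_hier <- function(x, y, taxon, scale,
                         priors = list(pop_sd = 2.5, scale_rate = 1,
                                       lkj_eta = 2),
                         control = mcmc_control(iter = 2000), seed = 1L,
                         transform = make_transform(x)) {
  stopifnot(inherits(scale, "abundance_scale"),
            length(x) == length(y), length(x) == length(taxon))
  taxa <- sort(unique(as.character(taxon)))
  J <- length(taxa)
  if (J < 2)
    stop("hierarchical model needs >= 2 taxa; use fit_cpm for a single group")
  k <- class_index(y, scale)
  if (length(unique(k)) < 2)
    stop("need at least 2 distinct observed classes")
  K <- scale$K
  m <- K  # effect dimension: (K-1) cutpoints + slope
  xt <- apply_transform(x, transform)
  tax0 <- match(as.character(taxon), taxa) - 1L

  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  eff_names <- c(paste0("alpha", seq_len(K - 1)), "beta")
  par_names <- c(eff_names,
                 paste0("sigma_", eff_names),
                 paste0("R_", eff_names[pairs[, 1]], "_",
                        eff_names[pairs[, 2]]),
                 as.vector(t(outer(taxa, eff_names, paste, sep = "."))))

  emp <- cumsum(tabulate(k, K))[seq_len(K - 1)] / length(k)
  emp <- pmin(pmax(emp, 0.02), 0.98)
  a0 <- cummax(stats::qlogis(emp) + seq_len(K - 1) * 1e-3)
  init0 <- c(a0[1], if (K > 2) log(pmax(diff(a0), 1e-2)), 0,
             rep(log(0.3), m), rep(0, m * (m - 1) / 2), rep(0, J * m))

  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(seed + ch)
    init <- init0 + stats::runif(length(init0), -0.1, 0.1)
    chains[[ch]] <- cpp_hier_chain(xt, k, tax0, K, J, priors$pop_sd,
                                   priors$scale_rate, priors$lkj_eta,
                                   control$warmup, control$iter,
                                   control$max_leapfrog, init,
                                   control$target_accept)
  }
  npar <- length(par_names)
  arr <- array(NA_real_, dim = c(control$iter, control$chains, npar))
  for (ch in seq_len(control$chains)) arr[, ch, ] <- chains[[ch]]$draws
  diag <- mcmc_diagnostics(arr, par_names)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- par_names
  structure(list(draws = draws, chains = control$chains, diagnostics = diag,
                 transform = transform, scale = scale, taxa = taxa,
                 priors = priors, control = control, seed = seed,
                 converged = all(diag$rhat < control$rhat_threshold),
                 accept_rates = vapply(chains, `[[`, numeric(1),
                                       "accept_rate"),
                 divergences = vapply(chains, `[[`, numeric(1),
                                      "divergences")),
            class = "cpm_hier_fit")
}

#' @export
print.cpm_hier_fit <- function(x, ...) {
  cat("<cpm_hier_fit>", length(x$taxa), "taxa,", x$scale$K, "classes,",
      nrow(x$draws), "draws;",
      if (x$converged) "converged" else
        paste0("NOT converged (max Rhat = ",
               round(max(x$diagnostics$rhat), 3), ")"), "\n")
  pop <- seq_len(x$scale$K + x$scale$K)  # population params + scales
  s <- rbind(mean = colMeans(x$draws[, pop, drop = FALSE]),
             sd = apply(x$draws[, pop, drop = FALSE], 2, stats::sd),
             rhat = x$diagnostics$rhat[pop])
  print(round(t(s), 3))
  invisible(x)
}

# draw matrices of a taxon's effects
taxon_effect_draws <- function(fit, taxon) {
  K <- fit$scale$K
  cols <- paste0(taxon, ".", c(paste0("alpha", seq_len(K - 1)), "beta"))
  fit$draws[, cols, drop = FALSE]
}

#' Predict abundance classes for a taxon seen in training
#'
#' Applies [prediction_set] machinery with the taxon's own posterior cutpoint
#' and slope draws on the taxon abundance scale.
#'
#' @param fit a `cpm_hier_fit`.
#' @param taxon one taxon label present in the fit.
#' @param x_new new per-taxon read counts.
#' @param level predictive mass (default 0.95).
#' @param check_convergence refuse to predict from a non-converged fit.
#' @return a [prediction_set].
#' @export
predict_taxon <- function(fit, taxon, x_new, level = 0.95,
                          check_convergence = TRUE) {
  stopifnot(inherits(fit, "cpm_hier_fit"))
  if (check_convergence && !fit$converged)
    stop("fit has not converged; pass check_convergence = FALSE to override")
  if (!taxon %in% fit$taxa)
    stop("taxon '", taxon, "' was not seen during fitting; use predict_unseen")
  if (any(!is.finite(x_new))) stop("x_new must be finite")
  K <- fit$scale$K
  eff <- taxon_effect_draws(fit, taxon)
  xt <- apply_transform(x_new, fit$transform)
  prediction_from_draws(eff[, seq_len(K - 1), drop = FALSE], eff[, K],
                        xt, fit$scale, level)
}

#' Predict abundance classes for a previously unseen taxon
#'
#' For each posterior draw, a new taxon's effect vector is drawn from that
#' draw's population distribution (mean = population cutpoints and slope,
#' covariance rebuilt from the scales and the correlation matrix), then class
#' probabilities are computed with those effects. Predictive uncertainty
#' therefore includes between-taxon variation, so intervals are wider than for
#' taxa seen in training. Effect draws whose cutpoints come out unordered are
#' redrawn (the model itself has zero density there).
#'
#' @param fit a `cpm_hier_fit`.
#' @param x_new new per-taxon read counts.
#' @param level predictive mass (default 0.95).
#' @param seed RNG seed for the population draws.
#' @param check_convergence refuse to predict from a non-converged fit.
#' @return a [prediction_set].
#' @export
predict_unseen <- function(fit, x_new, level = 0.95, seed = 1L,
                           check_convergence = TRUE) {
  stopifnot(inherits(fit, "cpm_hier_fit"))
  if (check_convergence && !fit$converged)
    stop("fit has not converged; pass check_convergence = FALSE to override")
  if (any(!is.finite(x_new))) stop("x_new must be finite")
  set.seed(seed)
  K <- fit$scale$K
  m <- K
  ndraw <- nrow(fit$draws)
  eff_names <- c(paste0("alpha", seq_len(K - 1)), "beta")
  mu <- fit$draws[, eff_names, drop = FALSE]
  sig <- fit$draws[, paste0("sigma_", eff_names), drop = FALSE]
  rcols <- grep("^R_", colnames(fit$draws))
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  alpha_new <- matrix(0, ndraw, K - 1)
  beta_new <- numeric(ndraw)
  for (d in seq_len(ndraw)) {
    R <- diag(m)
    R[pairs] <- fit$draws[d, rcols]
    R[pairs[, c(2, 1), drop = FALSE]] <- fit$draws[d, rcols]
    Sg <- diag(sig[d, ]) %*% R %*% diag(sig[d, ])
    Lc <- tryCatch(t(chol(Sg)), error = function(e) {
      ev <- eigen(Sg, symmetric = TRUE)
      t(chol(ev$vectors %*% diag(pmax(ev$values, 1e-10)) %*% t(ev$vectors)))
    })
    for (try in 1:100) {
      u <- mu[d, ] + as.vector(Lc %*% stats::rnorm(m))
      if (!is.unsorted(u[seq_len(K - 1)])) break
    }
    u[seq_len(K - 1)] <- sort(u[seq_len(K - 1)])
    alpha_new[d, ] <- u[seq_len(K - 1)]
    beta_new[d] <- u[m]
  }
  xt <- apply_transform(x_new, fit$transform)
  prediction_from_draws(alpha_new, beta_new, xt, fit$scale, level)
}
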