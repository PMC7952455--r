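#' Cumulative-logit class probabilities
#'
#' The proportional-odds construction: \eqn{Pr(Y \le c_k) =
#' \mathrm{logistic}(\alpha_k - \beta \tilde x)} for \eqn{k < K}, with class
#' probabilities obtained by differencing adjacent cumulative probabilities
#' (\eqn{p_1} is the first cumulative probability and \eqn{p_K} the complement
#' of the last).
#'
#' @param params list with `cutpoints` (non-decreasing, length K-1), `slope`,
#'   and optionally `transform` (see [make_transform()]); without a transform
#'   `x` is used as-is.
#' @param x predictor values.
#' @param scale an [abundance_scale()] with K classes.
#' @return matrix of class probabilities, one row per `x`, columns named by
#'   class CFU.
#' @export
class_probabilities <- function(params, x, scale) {
  stopifnot(inherits(scale, "abundance_scale"))
  if (is.unsorted(params$cutpoints)) stop("cutpoints must be non-decreasing")
  if (length(params$cutpoints) != scale$K - 1)
    stop("need K - 1 cutpoints for a K-class scale")
  xt <- if (!is.null(params$transform)) apply_transform(x, params$transform)
        else x
  p <- cumulative_class_probs(params$cutpoints, params$slope, xt)
  colnames(p) <- format(scale$classes, trim = TRUE, scientific = FALSE)
  p
}

# class probability matrix (n x K) from cutpoints/slope at predictor values
cumulative_class_probs <- function(cutpoints, slope, x) {
  K <- length(cutpoints) + 1
  cum <- vapply(seq_len(K - 1),
                function(k) stats::plogis(cutpoints[k] - slope * x),
                numeric(length(x)))
  cum <- matrix(cum, nrow = length(x))
  p <- cbind(cum, 1) - cbind(0, cum)
  pmax(p, 0)
}

#' Ordinal log likelihood
#'
#' Sum of log class probabilities of the realized outcomes under the
#' cumulative-logit model; the empty-data log likelihood is 0.
#'
#' @inheritParams class_probabilities
#' @param y observed CFU values, each a class of `scale`.
#' @return the log likelihood (scalar).
#' @export
cpm_log_likelihood <- function(params, x, y, scale) {
  if (length(y) == 0) return(0)
  stopifnot(length(x) == length(y))
  k <- class_index(y, scale)
  p <- class_probabilities(params, x, scale)
  sum(log(p[cbind(seq_along(k), k)]))
}

#' Fit the single-level cumulative probability model
#'
#' Bayesian proportional-odds regression of an ordered CFU outcome on (by
#' default) the standardized log10 library size, with independent
#' Normal(0, `cutpoint_sd`) priors on each cutpoint value and
#' Normal(0, `slope_sd`) on the slope. Cutpoint ordering is enforced by an
#' increment parametrization (first cutpoint free, positive gaps). Sampling is
#' Hamiltonian Monte Carlo; split-chain Rhat and effective sample sizes are
#' computed for every parameter and the fit is flagged non-converged when any
#' Rhat exceeds the control threshold.
#'
#' @param x predictor: raw read counts (library sizes), or model-scale values
#'   when `transform = identity_transform()`.
#' @param y observed CFU classes (values from `scale`).
#' @param scale an [abundance_scale()].
#' @param priors list with `cutpoint_sd` and `slope_sd` (defaults 5 and 5).
#' @param control an [mcmc_control()].
#' @param seed integer seed; chain c uses `seed + c`.
#' @param transform predictor transform; default frozen from `x` via
#'   [make_transform()].
#' @return an object of class `cpm_fit`: `draws` (posterior draws of cutpoints
#'   and slope), `diagnostics`, `transform`, `scale`, `converged`, `seed`.
#' @export
fit_cpm <- function(x, y, scale, priors = list(cutpoint_sd = 5, slope_sd = 5),
                    control = mcmc_control(), seed = 1L,
                    transform = make_transform(x)) {
  stopifnot(inherits(scale, "abundance_scale"), length(x) == length(y))
  k <- class_index(y, scale)
  if (length(unique(k)) < 2)
    stop("need at least 2 distinct observed classes")
  xt <- apply_transform(x, transform)
  K <- scale$K
  par_names <- c(paste0("alpha", seq_len(K - 1)), "beta")

  # data-informed starting cutpoints from empirical cumulative frequencies
  emp <- cumsum(tabulate(k, K))[seq_len(K - 1)] / length(k)
  emp <- pmin(pmax(emp, 0.02), 0.98)
  a0 <- stats::qlogis(emp)
  a0 <- cummax(a0 + seq_len(K - 1) * 1e-3)
  init0 <- c(a0[1], if (K > 2) log(pmax(diff(a0), 1e-2)), 0)

  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(seed + ch)
    init <- init0 + stats::runif(length(init0), -0.2, 0.2)
    chains[[ch]] <- cpp_cpm_chain(xt, k, K, priors$cutpoint_sd,
                                  priors$slope_sd, control$warmup,
                                  control$iter, control$max_leapfrog, init,
                                  control$target_accept)
  }
  arr <- array(NA_real_, dim = c(control$iter, control$chains, K))
  for (ch in seq_len(control$chains)) arr[, ch, ] <- chains[[ch]]$draws
  diag <- mcmc_diagnostics(arr, par_names)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- par_names
  structure(list(draws = draws, chains = control$chains,
                 diagnostics = diag, transform = transform, scale = scale,
                 priors = priors, control = control, seed = seed,
                 converged = all(diag$rhat < control$rhat_threshold),
                 accept_rates = vapply(chains, `[[`, numeric(1),
                                       "accept_rate"),
                 divergences = vapply(chains, `[[`, numeric(1),
                                      "divergences")),
            class = "cpm_fit")
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("<cpm_fit>", x$scale$K, "classes,", nrow(x$draws), "draws from",
      x$chains, "chains;",
      if (x$converged) "converged" else
        paste0("NOT converged (max Rhat = ",
               round(max(x$diagnostics$rhat), 3), ")"), "\n")
  s <- rbind(mean = colMeans(x$draws), sd = apply(x$draws, 2, stats::sd),
             rhat = x$diagnostics$rhat, ess = x$diagnostics$ess)
  print(round(t(s), 3))
  invisible(x)
}

#' Predict from a fitted single-level CPM
#'
#' For each new observation, class probabilities are computed per posterior
#' draw and averaged; the conditional expectation is the per-draw weighted
#' average of class CFU values (summarized by its posterior mean and central
#' 95% credible interval); the class of highest probability (CHP) is the mode
#' of the posterior-mean class probabilities (ties broken toward the lower
#' class); tail probabilities give \eqn{Pr(Y \ge c_k)} with
#' \eqn{Pr(Y \ge c_1) = 1}; and the 95% predictive class interval is the
#' smallest contiguous class set containing the CHP with at least 0.95
#' posterior-mean mass.
#'
#' @param object a `cpm_fit`.
#' @param newdata new predictor values (same scale as `x` at fit time: raw
#'   reads unless the fit used an identity transform).
#' @param level credible/predictive mass (default 0.95).
#' @param check_convergence refuse to predict from a non-converged fit
#'   (default TRUE).
#' @param ... unused.
#' @return a `prediction_set`; see [prediction_set()].
#' @export
predict.cpm_fit <- function(object, newdata, level = 0.95,
                            check_convergence = TRUE, ...) {
  if (check_convergence && !object$converged)
    stop("fit has not converged (max Rhat = ",
         round(max(object$diagnostics$rhat), 3),
         "); pass check_convergence = FALSE to override")
  if (any(!is.finite(newdata))) stop("newdata must be finite")
  xt <- apply_transform(newdata, object$transform)
  K <- object$scale$K
  alpha <- object$draws[, seq_len(K - 1), drop = FALSE]
  beta <- object$draws[, K]
  prediction_from_draws(alpha, beta, xt, object$scale, level)
}

#' Posterior predictive check for class frequencies
#'
#' For each retained posterior draw, replicated outcomes are simulated at the
#' observed predictor values and summarized as class frequencies, to be
#' compared with the observed class frequencies.
#'
#' @param fit a converged `cpm_fit`.
#' @param x,y observed data used in the fit (CFU classes for `y`).
#' @param n_rep number of posterior draws to use (thinned evenly).
#' @param seed RNG seed for the replication draws.
#' @return list with `replicated` (n_rep x K matrix of class frequencies),
#'   `observed` (length-K frequencies) and the scale.
#' @export
posterior_predictive_check <- function(fit, x, y, n_rep = 500, seed = 1L) {
  stopifnot(inherits(fit, "cpm_fit"))
  set.seed(seed)
  K <- fit$scale$K
  k_obs <- class_index(y, fit$scale)
  xt <- apply_transform(x, fit$transform)
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = n_rep)))
  reps <- matrix(0, length(idx), K)
  for (r in seq_along(idx)) {
    d <- idx[r]
    p <- cumulative_class_probs(fit$draws[d, seq_len(K - 1)],
                                fit$draws[d, K], xt)
    cls <- vapply(seq_along(xt),
                  function(i) sample.int(K, 1, prob = p[i, ]), integer(1))
    reps[r, ] <- tabulate(cls, K) / length(cls)
  }
  list(replicated = reps, observed = tabulate(k_obs, K) / length(k_obs),
       scale = fit$scale)
}

#' Serialize / restore a fit as JSON
#'
#' Stores the raw draw matrix, transform constants, scale, diagnostics and
#' seed in a single JSON document; `read_fit_json` reconstructs the fit object
#' (single-level or hierarchical).
#'
#' @param fit a `cpm_fit` or `cpm_hier_fit`.
#' @param path output path.
#' @return `path`, invisibly; `read_fit_json` returns the fit.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(type = class(fit)[1],
              draws = unclass(fit$draws),
              par_names = colnames(fit$draws),
              chains = fit$chains,
              diagnostics = fit$diagnostics,
              transform = fit$transform,
              scale = fit$scale$classes,
              priors = fit$priors,
              seed = fit$seed,
              converged = fit$converged,
              taxa = fit$taxa)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  draws <- as.matrix(obj$draws)
  colnames(draws) <- obj$par_names
  fit <- list(draws = draws, chains = obj$chains,
              diagnostics = list(rhat = unlist(obj$diagnostics$rhat),
                                 ess = unlist(obj$diagnostics$ess)),
              transform = obj$transform,
              scale = abundance_scale(obj$scale),
              priors = obj$priors, seed = obj$seed,
              converged = obj$converged)
  if (!is.null(obj$taxa)) fit$taxa <- obj$taxa
  class(fit) <- obj$type
  fit
}
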