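#' MCMC sampler settings
#'
#' Defaults follow common practice for gradient-based samplers: 4 chains,
#' 1000 warmup and 1000 kept iterations per chain, and a split-chain
#' convergence threshold of 1.01. Reduced settings (e.g. `warmup = 500, iter =
#' 500`) are used for cross-validation refits, where many fits are needed.
#'
#' @param chains number of chains (run sequentially, seeded from the fit seed).
#' @param warmup warmup iterations per chain (step size and diagonal mass
#'   matrix adapted here, then discarded).
#' @param iter kept iterations per chain.
#' @param max_leapfrog upper bound of the uniformly jittered leapfrog step
#'   count per trajectory.
#' @param target_accept dual-averaging acceptance target.
#' @param rhat_threshold split-chain Rhat above which a fit is flagged as
#'   non-converged.
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000,
                         max_leapfrog = 64, target_accept = 0.95,
                         rhat_threshold = 1.01) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 10)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter),
                 max_leapfrog = as.integer(max_leapfrog),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

# split-chain Rhat (Gelman et al.); x: iterations x chains
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size with Geyer's initial positive-pair truncation
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  if (W <= 0) return(n * m)
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + (if (m > 1) B / n else 0)
  max_lag <- min(n - 1, 500)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # sum consecutive pairs while positive
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  max(1, min(ess, m * n))
}

# assemble diagnostics for a draws array (iter x chains x params)
mcmc_diagnostics <- function(arr, par_names) {
  rhat <- apply(arr, 3, split_rhat)
  ess <- apply(arr, 3, ess_basic)
  names(rhat) <- names(ess) <- par_names
  list(rhat = rhat, ess = ess)
}

#' Predictor transform
#'
#' The predictor pipeline of both models: reads are mapped through
#' [model_scale()] (`log10(x + 1)`) and standardized using constants frozen at
#' fit time, so prediction reuses the training-time transform verbatim.
#' `identity_transform()` bypasses the pipeline (used when the predictor is
#' already on the model scale, e.g. in parameter-recovery simulations).
#'
#' @param reads training read counts.
#' @return a list with `center`, `scale` and `log` flag.
#' @export
make_transform <- function(reads) {
  lx <- model_scale(reads)
  s <- stats::sd(lx)
  list(center = mean(lx), scale = if (is.finite(s) && s > 0) s else 1,
       log = TRUE)
}

#' @rdname make_transform
#' @export
identity_transform <- function() list(center = 0, scale = 1, log = FALSE)

apply_transform <- function(x, transform) {
  if (isTRUE(transform$log)) x <- model_scale(x)
  (x - transform$center) / transform$scale
}
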