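#' Prediction set
#'
#' Per-observation derived quantities of a cumulative probability model,
#' averaged over posterior draws:
#' \describe{
#'   \item{class_probs}{posterior-mean class probabilities (rows sum to 1).}
#'   \item{cumulative_probs}{posterior-mean \eqn{Pr(Y \le c_k)}, non-decreasing
#'     in k.}
#'   \item{tail_probs}{\eqn{Pr(Y \ge c_k)}, non-increasing, first column 1.}
#'   \item{expectation}{per-draw \eqn{\sum_k c_k p_{ik}} summarized by mean and
#'     central credible interval; always inside `[c_1, c_K]`.}
#'   \item{chp}{class of highest (posterior-mean) probability, ties broken
#'     toward the lower class; with its contiguous predictive class interval
#'     of at least `level` posterior-mean mass.}
#' }
#' Constructed by [predict.cpm_fit()], [predict_taxon()] and
#' [predict_unseen()]; not called directly.
#'
#' @name prediction_set
NULL

# core prediction machinery shared by all model variants.
# alpha: ndraw x (K-1) cutpoint draws; beta: ndraw slopes (or matrices of
# per-observation draws when effects differ by observation); xt: transformed
# predictor values.
prediction_from_draws <- function(alpha, beta, xt, scale, level = 0.95) {
  K <- scale$K
  n <- length(xt)
  ndraw <- nrow(alpha)
  pbar <- matrix(0, n, K)
  cumbar <- matrix(0, n, K)
  expdraw <- matrix(0, ndraw, n)
  for (i in seq_len(n)) {
    cum <- stats::plogis(alpha - beta * xt[i])   # ndraw x (K-1)
    p <- cbind(cum, 1) - cbind(0, cum)
    p <- pmax(p, 0)
    pbar[i, ] <- colMeans(p)
    cumbar[i, ] <- colMeans(cbind(cum, 1))
    expdraw[, i] <- p %*% scale$classes
  }
  pbar <- pbar / rowSums(pbar)
  tail <- cbind(1, 1 - cumbar[, -K, drop = FALSE])
  chp <- apply(pbar, 1, which.max)  # which.max takes the lowest on ties
  qs <- apply(expdraw, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  expectation <- data.frame(mean = colMeans(expdraw),
                            lower = qs[1, ], upper = qs[2, ])
  interval <- t(vapply(seq_len(n),
                       function(i) chp_interval(pbar[i, ], chp[i], level),
                       numeric(2)))
  structure(list(class_probs = pbar, cumulative_probs = cumbar,
                 tail_probs = tail, expectation = expectation,
                 chp = chp, chp_cfu = scale$classes[chp],
                 chp_interval = interval,
                 chp_interval_cfu = cbind(scale$classes[interval[, 1]],
                                          scale$classes[interval[, 2]]),
                 scale = scale, level = level),
            class = "prediction_set")
}

# smallest contiguous class set containing the CHP with >= level mass, grown
# by adding the higher-mass neighbor (ties toward the lower class)
chp_interval <- function(p, chp, level = 0.95) {
  lo <- hi <- chp
  mass <- p[chp]
  K <- length(p)
  while (mass < level && (lo > 1 || hi < K)) {
    pl <- if (lo > 1) p[lo - 1] else -Inf
    ph <- if (hi < K) p[hi + 1] else -Inf
    if (pl >= ph) {
      lo <- lo - 1
      mass <- mass + pl
    } else {
      hi <- hi + 1
      mass <- mass + ph
    }
  }
  c(lo, hi)
}

#' @export
print.prediction_set <- function(x, ...) {
  n <- length(x$chp)
  cat("<prediction_set>", n, "observations on a", x$scale$K, "class scale\n")
  df <- data.frame(chp_cfu = x$chp_cfu,
                   expectation = round(x$expectation$mean, 1),
                   exp_lower = round(x$expectation$lower, 1),
                   exp_upper = round(x$expectation$upper, 1),
                   interval = paste0("[", x$chp_interval_cfu[, 1], ", ",
                                     x$chp_interval_cfu[, 2], "]"))
  print(utils::head(df, 10))
  if (n > 10) cat("... and", n - 10, "more rows\n")
  invisible(x)
}
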