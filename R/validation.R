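#' Mean absolute log10 ratio (MALR)
#'
#' \eqn{MALR = (1/n) \sum |log10(\hat y_i / y_i)|}: the average prediction
#' error in orders of magnitude. Zero iff predictions equal observations
#' elementwise; invariant to common positive rescaling of both arguments.
#'
#' @param predicted,observed positive CFU values of equal length.
#' @return non-negative scalar.
#' @export
malr <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (any(predicted <= 0) || any(observed <= 0))
    stop("values must be positive")
  mean(abs(log10(predicted / observed)))
}

#' Mean absolute error relative to the true value (MAEr)
#'
#' \eqn{MAEr = (1/n) \sum |\hat y_i - y_i| / y_i}: absolute error as a
#' proportion of the true value.
#'
#' @inheritParams malr
#' @return non-negative scalar.
#' @export
maer <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (any(observed <= 0)) stop("observed values must be positive")
  mean(abs(predicted - observed) / observed)
}

#' Somers' Dxy ordinal association
#'
#' Over all pairs with distinct observed classes:
#' \eqn{(C - D) / (C + D + T_x)} where C, D count concordant and discordant
#' pairs and \eqn{T_x} the pairs tied on the predictions; pairs tied on the
#' observed class are excluded from the denominator. Computed via
#' `survival::concordance` (Dxy = 2C - 1 under exactly this convention).
#'
#' @param predicted numeric prediction scores.
#' @param observed ordinal observed values (numeric class values or indices).
#' @return Dxy in `[-1, 1]`.
#' @export
somers_dxy <- function(predicted, observed) {
  if (length(predicted) < 2) stop("need at least 2 observations")
  if (length(unique(observed)) < 2) stop("all observed values are identical")
  cf <- survival::concordance(observed ~ predicted)
  unname(2 * cf$concordance - 1)
}

#' Observed coverage of predictive intervals
#'
#' Fraction of observations falling inside their (closed) interval.
#'
#' @param intervals two-column matrix or data.frame, `lower <= upper` per row.
#' @param observed values to check, one per row.
#' @return fraction in `[0, 1]`.
#' @export
interval_coverage <- function(intervals, observed) {
  intervals <- as.matrix(intervals)
  stopifnot(ncol(intervals) == 2, nrow(intervals) == length(observed))
  if (any(intervals[, 1] > intervals[, 2])) stop("malformed intervals")
  mean(observed >= intervals[, 1] & observed <= intervals[, 2])
}

#' Cross-validation split plan
#'
#' @param scheme `"kfold"` (stratified by outcome class, and by taxon when
#'   present), `"holdout"` (one stratified test split) or `"logo"`
#'   (leave-one-group-out; each taxon is one fold).
#' @param k number of folds for `"kfold"`.
#' @param holdout_fraction test fraction for `"holdout"` (default 0.10).
#' @param seed seed for the stratified shuffling.
#' @return a list of class `split_plan`.
#' @export
split_plan <- function(scheme = c("kfold", "holdout", "logo"), k = 10,
                       holdout_fraction = 0.10, seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Fold assignment under a split plan
#'
#' Stratified assignment: within each stratum, observations are shuffled
#' (seeded) and dealt round-robin across folds, so every class (and
#' taxon-class combination) is represented in folds wherever counts permit.
#' `"holdout"` returns fold 1 = test, fold 0 = train. `"logo"` assigns each
#' taxon its own fold.
#'
#' @param data data.frame with column `cfu` (and `taxon` for grouped schemes).
#' @param plan a [split_plan()].
#' @return integer fold id per row.
#' @export
make_folds <- function(data, plan) {
  stopifnot(inherits(plan, "split_plan"))
  n <- nrow(data)
  if (plan$scheme == "logo") {
    if (is.null(data$taxon)) stop("logo scheme needs a taxon column")
    return(as.integer(factor(data$taxon)))
  }
  strata <- if (!is.null(data$taxon))
    interaction(data$taxon, data$cfu, drop = TRUE)
  else factor(data$cfu)
  fold <- integer(n)
  set.seed(plan$seed)
  if (plan$scheme == "kfold") {
    offset <- 0L
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      # rotate the starting fold across strata so fold sizes stay balanced
      fold[idx] <- 1L + (seq_along(idx) - 1L + offset) %% plan$k
      offset <- offset + length(idx)
    }
  } else {
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      n_test <- round(length(idx) * plan$holdout_fraction)
      fold[idx] <- c(rep(1L, n_test), rep(0L, length(idx) - n_test))
    }
  }
  fold
}

# metrics for one prediction table (chp or expectation based)
prediction_metrics <- function(pred_cfu, true_cfu, intervals, scale,
                               which = c("chp", "expectation")) {
  which <- match.arg(which)
  true_k <- class_index(true_cfu, scale)
  pred_k <- if (which == "chp") class_index(pred_cfu, scale)
            else nearest_class(pred_cfu, scale)
  out <- c(
    malr = malr(pred_cfu, true_cfu),
    maer = maer(pred_cfu, true_cfu),
    accuracy = mean(pred_k == true_k),
    spearman = if (length(unique(true_k)) > 1 &&
                   stats::sd(pred_cfu) > 0)
      stats::cor(pred_cfu, true_cfu, method = "spearman") else NA_real_,
    somers_dxy = if (length(unique(true_k)) > 1)
      somers_dxy(pred_cfu, true_cfu) else NA_real_,
    coverage = interval_coverage(intervals, true_cfu)
  )
  out
}

#' Cross-validated model assessment
#'
#' Runs the requested split plan, refitting the model on each training portion
#' and predicting the held-out portion, then computes the full metric suite
#' (MALR, MAEr, accuracy, Spearman, Somers' Dxy, interval coverage) separately
#' for CHP-based (classification) and expectation-based (regression)
#' predictions, per fold and pooled. Coverage uses the 95% predictive class
#' interval for CHP and the 95% credible interval of the expectation.
#'
#' Under `"logo"`, each taxon is held out in turn and predicted via
#' [predict_unseen()] from a model fitted on the remaining taxa.
#'
#' A fold whose training portion contains a single outcome class is skipped
#' with a warning. Fold refits use the supplied (typically reduced)
#' [mcmc_control()]; marginal convergence in a single fold refit warns rather
#' than aborting the whole assessment.
#'
#' @param data data.frame with columns `reads`, `cfu`, and `taxon` for the
#'   hierarchical model.
#' @param scale an [abundance_scale()].
#' @param model `"cpm"` (total load, predictor = library size) or `"hier"`
#'   (taxon-specific, predictor = per-taxon reads).
#' @param plan a [split_plan()].
#' @param control [mcmc_control()] for the per-fold refits.
#' @param priors optional prior list passed to the fitting function.
#' @param seed base seed; fold f is fitted with `seed + 100 * f`.
#' @return list with `predictions` (pooled held-out prediction table),
#'   `fold_metrics` (long data.frame: fold x prediction type x metric),
#'   `pooled` (metrics on pooled predictions) and the fold assignment.
#' @export
run_cv <- function(data, scale, model = c("cpm", "hier"), plan = split_plan(),
                   control = mcmc_control(warmup = 500, iter = 500),
                   priors = NULL, seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(c("reads", "cfu") %in% names(data)))
  if (model == "hier" && is.null(data$taxon))
    stop("hierarchical CV needs a taxon column")
  fold <- make_folds(data, plan)
  folds <- sort(unique(fold[fold > 0]))
  preds <- NULL
  fold_rows <- list()
  for (f in folds) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (nrow(test) == 0) next
    if (length(unique(train$cfu)) < 2) {
      warning("fold ", f, " skipped: single outcome class in training")
      next
    }
    fit_seed <- seed + 100L * f
    if (model == "cpm") {
      fit <- if (is.null(priors))
        fit_cpm(train$reads, train$cfu, scale, control = control,
                seed = fit_seed)
      else fit_cpm(train$reads, train$cfu, scale, priors = priors,
                   control = control, seed = fit_seed)
      if (!fit$converged)
        warning("fold ", f, " fit marginal: max Rhat = ",
                round(max(fit$diagnostics$rhat), 3))
      ps <- predict(fit, test$reads, check_convergence = FALSE)
      test_pred <- fold_predictions(ps, test, f)
    } else {
      fit <- if (is.null(priors))
        fit_cpm_hier(train$reads, train$cfu, train$taxon, scale,
                     control = control, seed = fit_seed)
      else fit_cpm_hier(train$reads, train$cfu, train$taxon, scale,
                        priors = priors, control = control, seed = fit_seed)
      if (!fit$converged)
        warning("fold ", f, " fit marginal: max Rhat = ",
                round(max(fit$diagnostics$rhat), 3))
      test_pred <- NULL
      for (tx in unique(test$taxon)) {
        rows <- test[test$taxon == tx, , drop = FALSE]
        ps <- if (plan$scheme == "logo" || !(tx %in% fit$taxa))
          predict_unseen(fit, rows$reads, seed = fit_seed + 1L,
                         check_convergence = FALSE)
        else predict_taxon(fit, tx, rows$reads, check_convergence = FALSE)
        test_pred <- rbind(test_pred, fold_predictions(ps, rows, f))
      }
    }
    preds <- rbind(preds, test_pred)
    for (w in c("chp", "expectation"))
      fold_rows[[paste(f, w)]] <- data.frame(
        fold = f, type = w,
        t(metrics_from_table(test_pred, scale, w)))
  }
  if (is.null(preds)) stop("no usable folds")
  fold_metrics <- do.call(rbind, fold_rows)
  rownames(fold_metrics) <- NULL
  pooled <- rbind(
    data.frame(type = "chp", t(metrics_from_table(preds, scale, "chp"))),
    data.frame(type = "expectation",
               t(metrics_from_table(preds, scale, "expectation"))))
  list(predictions = preds, fold_metrics = fold_metrics, pooled = pooled,
       fold = fold, plan = plan, model = model, scale = scale)
}

# flatten a prediction_set against its test rows
fold_predictions <- function(ps, test, f) {
  data.frame(fold = f,
             taxon = if (!is.null(test$taxon)) test$taxon else NA_character_,
             reads = test$reads, true_cfu = test$cfu,
             chp_cfu = ps$chp_cfu,
             expectation = ps$expectation$mean,
             exp_lower = ps$expectation$lower,
             exp_upper = ps$expectation$upper,
             int_lower = ps$chp_interval_cfu[, 1],
             int_upper = ps$chp_interval_cfu[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

metrics_from_table <- function(tab, scale, which) {
  if (which == "chp")
    prediction_metrics(tab$chp_cfu, tab$true_cfu,
                       tab[, c("int_lower", "int_upper")], scale, "chp")
  else
    prediction_metrics(tab$expectation, tab$true_cfu,
                       tab[, c("exp_lower", "exp_upper")], scale,
                       "expectation")
}
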