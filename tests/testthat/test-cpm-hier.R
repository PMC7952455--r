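test_that("hierarchical fit enforces its preconditions", {
  sc <- taxon_scale()
  expect_error(fit_cpm_hier(c(1, 2), c(200, 2000), c("a", "a"), sc),
               "use fit_cpm")
  expect_error(fit_cpm_hier(c(1, 2), c(200, 200), c("a", "b"), sc),
               "2 distinct")
})

test_that("per-draw taxon cutpoints stay ordered and Sigma is PSD", {
  fx <- hier_fixture()
  fit <- fx$fit
  K <- fit$scale$K
  eff <- c(paste0("alpha", seq_len(K - 1)), "beta")
  for (tx in fit$taxa) {
    a <- fit$draws[, paste0(tx, ".", paste0("alpha", seq_len(K - 1)))]
    expect_true(all(a[, 1] <= a[, 2] & a[, 2] <= a[, 3]))
  }
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  rcols <- grep("^R_", colnames(fit$draws))
  idx <- round(seq(1, nrow(fit$draws), length.out = 50))
  for (d in idx) {
    R <- diag(K)
    R[pairs] <- fit$draws[d, rcols]
    R[pairs[, c(2, 1)]] <- fit$draws[d, rcols]
    sig <- fit$draws[d, paste0("sigma_", eff)]
    Sg <- diag(sig) %*% R %*% diag(sig)
    expect_equal(Sg, t(Sg))
    expect_true(all(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-10))
    expect_true(all(abs(R[pairs]) <= 1))
  }
})

test_that("taxon predictions are monotone in reads for every taxon", {
  fx <- hier_fixture()
  grid <- 10^seq(0, 4.6, length.out = 25)
  for (tx in fx$fit$taxa) {
    ps <- predict_taxon(fx$fit, tx, grid, check_convergence = FALSE)
    expect_true(all(diff(ps$chp) >= 0), label = tx)
    expect_true(all(diff(ps$expectation$mean) >= -1e-9), label = tx)
    expect_equal(rowSums(ps$class_probs), rep(1, length(grid)),
                 tolerance = 1e-9)
  }
  expect_error(predict_taxon(fx$fit, "nonexistent_taxon", 100,
                             check_convergence = FALSE), "predict_unseen")
})

test_that("partial pooling shrinks taxon slopes toward the population", {
  fx <- hier_fixture()
  fit <- fx$fit
  pop <- mean(fit$draws[, "beta"])
  for (tx in fit$taxa[1:3]) {
    rows <- fx$df[fx$df$taxon == tx, ]
    solo <- fit_cpm(rows$reads, rows$cfu, fit$scale,
                    priors = list(cutpoint_sd = 2.5, slope_sd = 2.5),
                    control = quick_ctl(chains = 2, warmup = 300, iter = 300),
                    seed = 3, transform = fit$transform)
    b_solo <- mean(solo$draws[, "beta"])
    b_hier <- mean(fit$draws[, paste0(tx, ".beta")])
    # hierarchical estimate no farther from the population than no pooling,
    # with slack for Monte Carlo error
    expect_lte(abs(b_hier - pop), abs(b_solo - pop) + 0.35, label = tx)
  }
})

test_that("zero between-taxon variance collapses onto population predictions", {
  fit <- degenerate_hier_fit(alpha = c(-2, 0, 2), beta = 3)
  x <- c(-1, 0, 1.5)
  seen <- predict_taxon(fit, "tA", x)
  unseen <- predict_unseen(fit, x, seed = 9)
  pop <- class_probabilities(list(cutpoints = c(-2, 0, 2), slope = 3),
                             x, fit$scale)
  expect_equal(seen$class_probs, unname(pop), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unseen$class_probs, unname(pop), tolerance = 1e-4,
               ignore_attr = TRUE)
  # degenerate posterior with all mass below the first cutpoint
  lowfit <- degenerate_hier_fit(alpha = c(40, 50, 60), beta = 0)
  ps <- predict_taxon(lowfit, "tA", 0)
  expect_equal(ps$expectation$mean, 200)
  expect_equal(ps$chp_cfu, 200)
})

test_that("unseen-taxon predictions are reproducible and wider than seen", {
  fx <- hier_fixture()
  x <- c(20, 400, 8000)
  u1 <- predict_unseen(fx$fit, x, seed = 4, check_convergence = FALSE)
  u2 <- predict_unseen(fx$fit, x, seed = 4, check_convergence = FALSE)
  expect_identical(u1$class_probs, u2$class_probs)
  width <- function(ps) mean(ps$chp_interval[, 2] - ps$chp_interval[, 1])
  seen_w <- vapply(fx$fit$taxa, function(tx)
    width(predict_taxon(fx$fit, tx, x, check_convergence = FALSE)),
    numeric(1))
  expect_gte(width(u1) + 1e-9, mean(seen_w))
})

test_that("hierarchical fits are deterministic under a fixed seed", {
  fx <- hier_fixture()
  sub <- fx$df[fx$df$taxon %in% fx$fit$taxa[1:3], ]
  ctl <- quick_ctl(chains = 2, warmup = 200, iter = 100)
  f1 <- fit_cpm_hier(sub$reads, sub$cfu, sub$taxon, taxon_scale(),
                     control = ctl, seed = 11)
  f2 <- fit_cpm_hier(sub$reads, sub$cfu, sub$taxon, taxon_scale(),
                     control = ctl, seed = 11)
  expect_identical(f1$draws, f2$draws)
})
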