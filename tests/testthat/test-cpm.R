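test_that("class probabilities match logistic CDF differences", {
  sc <- total_scale()
  p <- class_probabilities(list(cutpoints = c(-2, -1, 1, 2), slope = 0),
                           x = 123, sc)
  expect_equal(unname(round(p[1, ], 4)),
               c(0.1192, 0.1497, 0.4621, 0.1497, 0.1192))
  expect_equal(sum(p), 1)
  # psi = 0 for some k: cumulative probability 0.5
  p2 <- class_probabilities(list(cutpoints = c(0, 1, 2, 3), slope = 1),
                            x = 0, sc)
  expect_equal(unname(p2[1, 1]), 0.5)
  # positive slope, x -> +inf: all mass on the top class
  p3 <- class_probabilities(list(cutpoints = c(-2, -1, 1, 2), slope = 2),
                            x = 1e4, sc)
  expect_equal(unname(p3[1, ]), c(0, 0, 0, 0, 1))
  expect_error(class_probabilities(list(cutpoints = c(1, 0, 2, 3), slope = 1),
                                   0, sc), "non-decreasing")
})

test_that("proportional odds: cumulative logit differences are constant in k", {
  sc <- taxon_scale()
  par <- list(cutpoints = c(-1.3, 0.2, 2.1), slope = 1.7)
  for (pair in list(c(-1, 0.5), c(0, 2), c(-2.5, 1.3))) {
    p1 <- class_probabilities(par, pair[1], sc)
    p2 <- class_probabilities(par, pair[2], sc)
    lg <- function(p) qlogis(pmin(cumsum(p[1, ])[1:(sc$K - 1)], 1 - 1e-12))
    diffs <- lg(p1) - lg(p2)
    expect_equal(diffs, rep(par$slope * (pair[2] - pair[1]), sc$K - 1),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("ordinal log likelihood sums realized log probabilities", {
  sc <- total_scale()
  par <- list(cutpoints = c(0, 1, 2, 3), slope = 1)
  # single observation in class 1 at x = 0: p = 0.5
  expect_equal(cpm_log_likelihood(par, 0, 84, sc), log(0.5))
  expect_equal(cpm_log_likelihood(par, numeric(0), numeric(0), sc), 0)
  # additivity
  ll2 <- cpm_log_likelihood(par, c(0, 1), c(84, 8400), sc)
  expect_equal(ll2, cpm_log_likelihood(par, 0, 84, sc) +
                 cpm_log_likelihood(par, 1, 8400, sc))
  expect_error(cpm_log_likelihood(par, 0, 123, sc), "not a class")
})

test_that("fit_cpm is deterministic under a fixed seed", {
  sc <- taxon_scale()
  set.seed(5)
  d <- simulate_from_cpm(120, c(-2, 0, 2), 1.5, rnorm(120), sc, seed = 5)
  ctl <- quick_ctl(chains = 2, warmup = 150, iter = 100)
  f1 <- fit_cpm(d$x, d$cfu, sc, control = ctl, seed = 42,
                transform = identity_transform())
  f2 <- fit_cpm(d$x, d$cfu, sc, control = ctl, seed = 42,
                transform = identity_transform())
  expect_identical(f1$draws, f2$draws)
  expect_error(fit_cpm(d$x, rep(200, 120), sc), "2 distinct")
})

test_that("prediction sets satisfy the probability invariants", {
  fx <- total_fixture()
  ps <- predict(fx$fit, c(5, 50, 500, 5000, 50000),
                check_convergence = FALSE)
  expect_equal(rowSums(ps$class_probs), rep(1, 5), tolerance = 1e-9)
  for (i in 1:5) {
    expect_true(all(diff(ps$cumulative_probs[i, ]) >= -1e-12))
    expect_true(all(diff(ps$tail_probs[i, ]) <= 1e-12))
  }
  expect_equal(ps$tail_probs[, 1], rep(1, 5))
  sc <- fx$fit$scale
  expect_true(all(ps$expectation$mean >= sc$classes[1] &
                    ps$expectation$mean <= sc$classes[sc$K]))
  expect_true(all(ps$chp_cfu %in% sc$classes))
  # monotonicity of expectation and CHP in x
  grid <- 10^seq(0, 5.5, length.out = 30)
  pg <- predict(fx$fit, grid, check_convergence = FALSE)
  expect_true(all(diff(pg$expectation$mean) >= -1e-9))
  expect_true(all(diff(pg$chp) >= 0))
})

test_that("degenerate point-mass posterior yields the lowest class", {
  fit <- degenerate_cpm_fit(cutpoints = c(30, 40, 50, 60), slope = 0)
  ps <- predict(fit, 0)
  expect_equal(unname(ps$class_probs[1, ]), c(1, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(ps$expectation$mean, 84)
  expect_equal(ps$chp_cfu, 84)
  expect_equal(unname(ps$chp_interval[1, ]), c(1, 1))
})

test_that("uniform class probabilities give the mean of the class values", {
  sc <- total_scale()
  # cutpoints at qlogis(k/5), slope 0 -> exactly uniform probabilities
  fit <- degenerate_cpm_fit(cutpoints = qlogis((1:4) / 5), slope = 0)
  ps <- predict(fit, 0)
  expect_equal(unname(ps$class_probs[1, ]), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(ps$expectation$mean, mean(sc$classes))
})

test_that("CHP ties break toward the lower class and intervals grow greedily", {
  p <- c(0.3, 0.3, 0.2, 0.1, 0.1)
  expect_equal(which.max(p), 1L)
  expect_equal(microload:::chp_interval(c(0.5, 0.3, 0.1, 0.06, 0.04), 1),
               c(1, 4))
  expect_equal(microload:::chp_interval(c(0.01, 0.02, 0.95, 0.01, 0.01), 3),
               c(3, 3))
  # neighbor with higher mass absorbed first; stops at exactly 0.95 mass
  expect_equal(microload:::chp_interval(c(0.05, 0.55, 0.4, 0, 0), 2),
               c(2, 3))
  # ties between neighbors resolve toward the lower class
  expect_equal(microload:::chp_interval(c(0.3, 0.4, 0.3, 0, 0), 2),
               c(1, 3))
})

test_that("non-converged fits refuse to predict by default", {
  fit <- degenerate_cpm_fit()
  fit$converged <- FALSE
  expect_error(predict(fit, 10), "not converged")
  expect_s3_class(predict(fit, 10, check_convergence = FALSE),
                  "prediction_set")
  expect_error(predict(degenerate_cpm_fit(), c(1, NA)), "finite")
})

test_that("posterior predictive replications cover the observed frequencies", {
  fx <- total_fixture()
  ppc <- posterior_predictive_check(fx$fit, fx$df$reads, fx$df$cfu,
                                    n_rep = 200, seed = 3)
  lo <- apply(ppc$replicated, 2, quantile, 0.025)
  hi <- apply(ppc$replicated, 2, quantile, 0.975)
  expect_true(all(ppc$observed >= lo - 1e-9 & ppc$observed <= hi + 1e-9))
  ppc2 <- posterior_predictive_check(fx$fit, fx$df$reads, fx$df$cfu,
                                     n_rep = 200, seed = 3)
  expect_identical(ppc$replicated, ppc2$replicated)
})

test_that("fits serialize to JSON and back", {
  fx <- total_fixture()
  f <- tempfile(fileext = ".json")
  write_fit_json(fx$fit, f)
  back <- read_fit_json(f)
  expect_s3_class(back, "cpm_fit")
  expect_equal(back$draws, fx$fit$draws)
  expect_equal(back$transform$center, fx$fit$transform$center)
  ps1 <- predict(fx$fit, c(100, 10000), check_convergence = FALSE)
  ps2 <- predict(back, c(100, 10000), check_convergence = FALSE)
  expect_equal(ps1$class_probs, ps2$class_probs)
})
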