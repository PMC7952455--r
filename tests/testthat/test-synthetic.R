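test_that("identical (design, params, seed) give bit-identical tables", {
  d <- dilution_design(mode = "taxon", replicates_per_class = 3, seed = 7)
  t1 <- simulate_counts(d)
  t2 <- simulate_counts(d)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$meta, t2$meta)
  expect_identical(t1$taxon_params, t2$taxon_params)
})

test_that("noise-free counts increase strictly with CFU class for every taxon", {
  d <- dilution_design(mode = "taxon", replicates_per_class = 1,
                       runs = data.frame(run = "r1", expected_coverage = 30000),
                       control_samples = 0, seed = 3)
  tab <- simulate_counts(d, response_params(dispersion = Inf))
  for (j in seq_len(nrow(tab$counts)))
    expect_true(all(diff(tab$counts[j, ]) > 0), label = rownames(tab$counts)[j])
})

test_that("response curve saturates: 10x CFU far above midpoint gives << 10x reads", {
  p <- response_params()
  # independent evaluation of the 4PL curve at midpoint + 2 and + 3
  lo <- p$floor + (p$ceiling - p$floor) / (1 + exp(-p$steepness * 2))
  hi <- p$floor + (p$ceiling - p$floor) / (1 + exp(-p$steepness * 3))
  expect_equal(response_curve(p$midpoint + 2, p), lo)
  expect_equal(response_curve(p$midpoint + 3, p), hi)
  ratio <- 10^hi / 10^lo
  expect_lt(ratio, 2)  # far less than the 10x input ratio
})

test_that("library sizes equal column sums; raw counts are non-negative integers", {
  d <- dilution_design(mode = "total", replicates_per_class = 4, seed = 5)
  tab <- simulate_counts(d)
  expect_equal(library_sizes(tab), colSums(tab$counts))
  expect_true(all(tab$counts >= 0))
  expect_true(all(tab$counts == round(tab$counts)))
})

test_that("run effect scales expected counts and normalization inverts it", {
  runs <- data.frame(run = c("a", "b"), expected_coverage = c(30000, 60000))
  d <- dilution_design(mode = "taxon", replicates_per_class = 4, runs = runs,
                       control_samples = 0, seed = 9)
  tab <- simulate_counts(d, response_params(dispersion = Inf))
  sf <- size_factors(tab)
  expect_equal(unclass(sf), c(a = 0.5, b = 1.0))
  norm <- normalize_counts(tab, sf)
  # noise-free: normalized counts match the unscaled curve mean within rounding
  d1 <- dilution_design(mode = "taxon", replicates_per_class = 4,
                        runs = data.frame(run = "a", expected_coverage = 60000),
                        control_samples = 0, seed = 9)
  ref <- simulate_counts(d1, response_params(dispersion = Inf))
  expect_true(all(abs(norm$counts - ref$counts) <= 1))
})

test_that("simulate_from_cpm reproduces hand-computed class frequencies", {
  sc <- total_scale()
  # cutpoints (-2,-1,1,2), slope 0: logistic CDF differences
  expected <- c(plogis(-2), plogis(-1) - plogis(-2), plogis(1) - plogis(-1),
                plogis(2) - plogis(1), 1 - plogis(2))
  expect_equal(round(expected, 4), c(0.1192, 0.1497, 0.4621, 0.1497, 0.1192))
  d <- simulate_from_cpm(20000, c(-2, -1, 1, 2), 0, 0, sc, seed = 1)
  freq <- tabulate(d$class, 5) / nrow(d)
  expect_true(all(abs(freq - expected) < 0.015))
})

test_that("simulate_from_cpm limits and errors", {
  sc <- total_scale()
  # slope -> +inf with x spread across classes: outcomes ordered by x
  d <- simulate_from_cpm(100, c(-200, -100, 100, 200), 100,
                         seq(-3, 3, length.out = 100), sc, seed = 2)
  expect_true(all(diff(d$class[order(d$x)]) >= 0))
  # symmetric cutpoints, slope 0: symmetric frequencies
  d2 <- simulate_from_cpm(40000, c(-1.5, -0.5, 0.5, 1.5), 0, 0, sc, seed = 3)
  freq <- tabulate(d2$class, 5) / nrow(d2)
  expect_true(all(abs(freq - rev(freq)) < 0.02))
  expect_identical(simulate_from_cpm(50, c(-1, 0, 1, 2), 1, 0, sc, seed = 4),
                   simulate_from_cpm(50, c(-1, 0, 1, 2), 1, 0, sc, seed = 4))
  expect_error(simulate_from_cpm(10, c(1, 0, -1, 2), 1, 0, sc), "non-decreasing")
  expect_error(simulate_from_cpm(0, c(-1, 0, 1, 2), 1, 0, sc), "n must be")
})

test_that("spike_contamination places counts as requested", {
  d <- dilution_design(mode = "taxon", replicates_per_class = 2, seed = 1)
  tab <- simulate_counts(d)
  ctrl <- tab$meta$is_control
  sp <- spike_contamination(tab, "contamX", control_level = 0,
                            sample_level = 10)
  expect_true(all(sp$counts["contamX", ctrl] == 0))
  expect_true(all(sp$counts["contamX", !ctrl] == 10))
  # non-spiked rows untouched
  expect_identical(sp$counts[rownames(tab$counts), ], tab$counts)
  expect_error(spike_contamination(tab, "x", -1, 5), ">= 0")
})

test_that("design validation catches bad layouts", {
  expect_error(dilution_design(replicates_per_class = 0), ">= 1")
  expect_error(dilution_design(taxon_classes = c(200, 200, 2000)),
               "strictly increasing")
  expect_error(dilution_design(total_classes = c(100, 10)),
               "strictly increasing")
})
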