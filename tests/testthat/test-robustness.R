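test_that("the CV formula is exact on hand-computed cases", {
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(9, 10, 11)), 10)  # sample sd 1, mean 10
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("CV is scale invariant", {
  set.seed(10)
  for (i in 1:20) {
    x <- stats::rlnorm(sample(2:6, 1), 3, 0.4)
    k <- stats::runif(1, 0.01, 100)
    expect_equal(cv(k * x), cv(x), tolerance = 1e-10)
  }
})

test_that("the validity filter excludes populations under 100 events", {
  expect_false(validity_filter(matrix(c(99, 150, 200), 1)))
  expect_true(validity_filter(matrix(c(100, 100, 100), 1)))
  expect_false(validity_filter(matrix(c(0, 0, 0), 1)))
  # mean rule is more permissive
  expect_true(validity_filter(matrix(c(99, 150, 200), 1), rule = "mean"))
  m <- rbind(c(99, 150, 200), c(120, 130, 140))
  expect_identical(validity_filter(m), c(FALSE, TRUE))
})

test_that("CV binning follows the documented boundary convention", {
  s <- cv_summary(c(1, 2, 3, 7, 12, 16))
  expect_equal(s$pct_lt5, 50)
  expect_equal(s$pct_lt10, 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(s$n_10_15, 1)
  expect_equal(s$n_ge15, 1)
  expect_equal(cv_summary(rep(0, 5))$pct_lt5, 100)
  # a CV of exactly 5 belongs to the 5-10 band, not below 5
  s5 <- cv_summary(c(5))
  expect_equal(s5$pct_lt5, 0)
  expect_equal(s5$pct_lt10, 100)
  expect_error(cv_summary(numeric()), "at least one")
  # the four bands always account for every valid population
  expect_equal(s$pct_lt10 + 100 * (s$n_10_15 + s$n_ge15) / s$n, 100)
})

test_that("identical replicates give all-zero CVs", {
  r <- replicate_experiment(n_replicates = 2, n_events = 4000,
                            freq_sdlog = 0, seed = 3,
                            replicate_seeds = c(3, 3),
                            schemas = diob_schemas[c("P08", "P09", "P12")])
  p <- r$populations
  expect_true(all(p$cv[p$valid] == 0))
})

test_that("a replicate run enumerates every reported population", {
  r <- replicate_experiment(n_replicates = 2, n_events = 3000,
                            freq_sdlog = 0.02, seed = 4)
  expect_equal(r$n_total, 208)
  expect_equal(r$n_excluded + r$n_valid, r$n_total)
  full <- list_reported_populations(diob_schemas)
  expect_identical(paste(r$populations$panel, r$populations$population),
                   paste(full$panel, full$population))
})

test_that("counting-noise CVs shrink for larger populations", {
  r <- replicate_experiment(n_replicates = 3, n_events = 20000,
                            freq_sdlog = 0, seed = 5,
                            schemas = diob_schemas[c("P01", "P04", "P08", "P12")])
  p <- r$populations
  sel <- p$valid & p$source == "gate"
  rho <- stats::cor(log(p$mean[sel]), log(p$cv[sel] + 1e-6),
                    method = "spearman")
  expect_lt(rho, -0.5)
})
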