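test_that("logicle maps the top of scale to display 1", {
  lp <- logicle_params()
  expect_equal(to_logicle(lp$T, lp), 1, tolerance = 1e-9)
  expect_equal(from_logicle(1, lp), lp$T, tolerance = 1e-9)
})

test_that("forward and inverse logicle are a tight round trip", {
  lp <- logicle_params()
  set.seed(42)
  x <- c(-10^4, -100, 0, 1, 50, 1000, 1048576,
         stats::runif(1000, -1e4, lp$T))
  y <- to_logicle(x, lp)
  back <- from_logicle(y, lp)
  expect_lt(max(abs(back - x) / pmax(abs(x), 1)), 1e-6)
})

test_that("logicle is strictly increasing over its whole domain", {
  for (lp in list(logicle_params(), logicle_params(W = 0, A = 0),
                  logicle_params(M = 5, W = 1, A = 0.5))) {
    set.seed(7)
    x <- sort(c(stats::runif(500, -5e4, lp$T), 0))
    y <- to_logicle(x, lp)
    expect_true(all(diff(y) > 0))
  }
})

test_that("with W=0 and A=0 the high range follows a pure log10 scale", {
  lp <- logicle_params(W = 0, A = 0)
  x <- 10^seq(3, log10(lp$T), length.out = 200)
  expected <- 1 + log10(x / lp$T) / lp$M
  expect_lt(max(abs(to_logicle(x, lp) - expected)), 1e-3)
})

test_that("invalid logicle parameters are rejected", {
  expect_error(logicle_params(T = -1), "T must be")
  expect_error(logicle_params(M = 0), "M must be")
  expect_error(logicle_params(W = 3, M = 4.5), "W <= M/2")
  expect_error(logicle_params(A = -0.1), "A must be")
})
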