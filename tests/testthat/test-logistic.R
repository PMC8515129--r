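test_that("Newton fit matches glm coefficients and standard errors", {
  set.seed(7)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.2 * d$x1 - 0.7 * d$x2))
  fit <- logistic_fit(d, "y", c("x1", "x2"), mode = "multivariate")
  ref <- glm(y ~ x1 + x2, family = binomial, data = d)
  expect_equal(fit$coef, unname(coef(ref)[2:3]), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))[2:3]),
               tolerance = 1e-4)
  expect_equal(fit$wald, fit$coef / fit$se)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$wald)))
})

test_that("univariate mode fits each predictor separately", {
  set.seed(8)
  n <- 300
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.8 * d$a))
  fit <- logistic_fit(d, "y", c("a", "b"), mode = "univariate")
  expect_equal(fit$variable, c("a", "b"))
  ref_a <- glm(y ~ a, family = binomial, data = d)
  ref_b <- glm(y ~ b, family = binomial, data = d)
  expect_equal(fit$coef, unname(c(coef(ref_a)[2], coef(ref_b)[2])),
               tolerance = 1e-6)
})

test_that("complete separation is detected, not silently diverged", {
  d <- data.frame(x = c(1, 2, 8, 9), y = c(0, 0, 1, 1))
  expect_error(logistic_fit(d, "y", "x"), "separation detected")
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- data.frame(x = rnorm(10), y = rep(1, 10))
  expect_error(logistic_fit(d, "y", "x"), "both classes")
  d2 <- data.frame(x = rnorm(10), y = rep(c(0.5, 1), 5))
  expect_error(logistic_fit(d2, "y", "x"), "binary")
  d3 <- data.frame(x = 1:3, y = c(0, 1, 0))
  expect_error(logistic_fit(d3, "y", c("x", "x")),
               "more observations than parameters")
})

test_that("coefficient bias vanishes as the sample grows", {
  truth <- 1.0
  bias_at <- function(n, seeds = 3) {
    mean(vapply(seeds * 100 + seq_len(seeds), function(s) {
      set.seed(s)
      d <- data.frame(x = rnorm(n))
      d$y <- rbinom(n, 1, plogis(-0.3 + truth * d$x))
      logistic_fit(d, "y", "x")$coef - truth
    }, numeric(1)))
  }
  b <- vapply(c(500, 2000, 8000), bias_at, numeric(1))
  expect_lt(abs(b[3]), 0.1)
  expect_lt(abs(b[3]), abs(b[1]) + 0.05)
})

test_that("null Wald tests reject at close to the nominal rate", {
  set.seed(99)
  n <- 200
  rejections <- vapply(1:400, function(i) {
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, 0.5)
    logistic_fit(d, "y", "x")$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})
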