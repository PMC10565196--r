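test_that("balanced null design gives a zero slope and unit odds ratio", {
  d <- tibble::tibble(y = c(0, 1, 0, 1), x = c(0, 0, 1, 1))
  f <- fit_glm(d, y ~ x)
  row <- f$coefficients[f$coefficients$term == "x", ]
  expect_equal(row$estimate, 0, tolerance = 1e-8)
  expect_equal(row$odds.ratio, 1, tolerance = 1e-8)
})

test_that("saturated 2x2 logistic slope equals the contingency log odds ratio", {
  # exposed: 10 of 15 positive; unexposed: 4 of 24 positive -> OR = 10
  d <- tibble::tibble(
    y = c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 20)),
    exposed = c(rep(1, 15), rep(0, 24))
  )
  f <- fit_glm(d, y ~ exposed)
  b <- f$coefficients$estimate[f$coefficients$term == "exposed"]
  expect_equal(b, log(10), tolerance = 1e-7)
  expect_equal(b, 2.302585, tolerance = 1e-6)
})

test_that("IRLS matches stats::glm and a generic optimizer on random data", {
  set.seed(17)
  for (rep in 1:4) {
    n <- 50
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    beta <- c(-0.3, 0.8, -0.5)
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
    d <- tibble::tibble(y = y, x1 = X[, 2], x2 = X[, 3])
    f <- fit_glm(d, y ~ x1 + x2)
    ref <- glm(y ~ x1 + x2, data = d, family = binomial())
    expect_equal(f$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(f$coefficients$std.error,
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
    expect_equal(f$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_equal(f$aic, AIC(ref), tolerance = 1e-6)
    # independent numerical maximizer
    expect_equal(f$coefficients$estimate, unname(optim_logit(X, y)),
                 tolerance = 1e-6)
  }
})

test_that("model-fit invariants hold: OR, CI, AIC, df, intercept score", {
  set.seed(23)
  d <- tibble::tibble(y = rbinom(80, 1, 0.4), x = rnorm(80))
  f <- fit_glm(d, y ~ x)
  co <- f$coefficients
  expect_equal(co$odds.ratio, exp(co$estimate), tolerance = 1e-9)
  expect_equal(co$or.low, exp(co$estimate - qnorm(0.975) * co$std.error),
               tolerance = 1e-9)
  expect_equal(f$aic, 2 * f$k - 2 * f$logLik)
  expect_equal(f$df.residual, f$n - 2)
  # score equation for the intercept: fitted mean equals observed mean
  expect_equal(mean(f$fitted), mean(d$y), tolerance = 1e-8)
})

test_that("gaussian fit equals closed-form OLS exactly", {
  set.seed(29)
  d <- tibble::tibble(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  f <- fit_glm(d, y ~ x1 + x2, family = "gaussian")
  ref <- lm(y ~ x1 + x2, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ref)), tolerance = 1e-12)
  expect_equal(f$coefficients$std.error,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(f$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("pathological designs raise informative errors", {
  sep <- tibble::tibble(y = c(rep(0, 10), rep(1, 10)),
                        x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_error(fit_glm(sep, y ~ x), "eparation")
  onecls <- tibble::tibble(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_glm(onecls, y ~ x), "single class")
  rankdef <- tibble::tibble(y = rbinom(10, 1, 0.5), x = rnorm(10))
  rankdef$x2 <- 2 * rankdef$x
  expect_error(fit_glm(rankdef, y ~ x + x2), "rank")
})

test_that("likelihood-ratio test identities and nesting checks", {
  set.seed(37)
  d <- tibble::tibble(y = rbinom(100, 1, 0.5), x1 = rnorm(100),
                      x2 = rnorm(100))
  full <- fit_glm(d, y ~ x1 + x2)
  red <- fit_glm(d, y ~ x1)
  out <- likelihood_ratio_test(full, red)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  # statistic equals difference of independently computed deviances
  expect_equal(out$statistic, red$deviance - full$deviance, tolerance = 1e-6)
  # identical models -> statistic 0, p = 1
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # non-nested rejection
  other <- fit_glm(tibble::tibble(y = d$y[1:50], x1 = d$x1[1:50]), y ~ x1)
  expect_error(likelihood_ratio_test(full, other), "different numbers")
})

test_that("caption line has the documented format and round-trips", {
  d <- tibble::tibble(
    y = c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 20)),
    exposed = c(rep(1, 15), rep(0, 24))
  )
  f <- fit_glm(d, y ~ exposed)
  line <- summarize_fit_line(f)
  expect_match(line, "^N = 39, β = 2\\.30")
  expect_match(line, "OR = 10\\.0")
  expect_match(line, "d\\.f\\. = 37")
  # parse the line back and compare at printed precision
  nums <- regmatches(line, gregexpr("-?[0-9]+\\.?[0-9]*", line))[[1]]
  expect_equal(as.numeric(nums[1]), f$n)
  expect_equal(as.numeric(nums[2]),
               signif(f$coefficients$estimate[2], 3), tolerance = 1e-9)
  expect_equal(as.numeric(nums[length(nums)]), round(f$aic, 2))
  # balanced null prints beta 0, OR 1
  d0 <- tibble::tibble(y = c(0, 1, 0, 1), x = c(0, 0, 1, 1))
  expect_match(summarize_fit_line(fit_glm(d0, y ~ x)),
               "β = 0\\.000.*OR = 1\\.00")
})
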