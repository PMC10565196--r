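test_that("spatial GLMM with zero variance components reproduces the GLM", {
  w <- build_world(scenario_tone_humidity(n = 80, seed = 41))
  naive <- fit_glm(w$data, outcome ~ env)
  sp <- fit_spatial_glmm(w$data, outcome ~ env,
                         fix = list(sigma2_s = 0, tau2 = 0, range = 1000))
  expect_equal(sp$coefficients$estimate, naive$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(sp$logLik, naive$logLik, tolerance = 1e-8)
  expect_equal(unname(sp$u), rep(0, 80))
})

test_that("gaussian spatial model equals the closed-form GLS oracle", {
  spec <- scenario_spec(n = 50, outcome = list(family = "gaussian",
                                               beta0 = 0.5, beta_env = 1,
                                               sigma2_s = 1, range_km = 1200,
                                               tau2 = 0.1, sigma2_e = 0.5),
                        seed = 43)
  w <- build_world(spec)
  th <- list(sigma2_s = 0.8, range = 900, tau2 = 0.2, sigma2_e = 0.6)
  fg <- fit_spatial_glmm(w$data, outcome ~ env, family = "gaussian",
                         fix = th)
  V <- spatial_covariance(w$D, kernel_spec("exponential",
                                           sigma2 = th$sigma2_s,
                                           range = th$range,
                                           nugget = th$tau2)) +
    diag(th$sigma2_e, 50)
  X <- cbind(1, w$data$env)
  y <- w$data$outcome
  Vi <- solve(V)
  b_gls <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
  expect_equal(fg$coefficients$estimate, b_gls, tolerance = 1e-6)
  res <- y - drop(X %*% b_gls)
  ll_gls <- -0.5 * (determinant(V)$modulus[1] +
                      drop(t(res) %*% Vi %*% res) + 50 * log(2 * pi))
  expect_equal(fg$logLik, ll_gls, tolerance = 1e-6)
  # Wald covariance matches (X' V^-1 X)^-1
  expect_equal(fg$coefficients$std.error,
               sqrt(diag(solve(t(X) %*% Vi %*% X))), tolerance = 1e-6)
})

test_that("Laplace likelihood is invariant to row order", {
  w <- build_world(scenario_tone_humidity(n = 40, seed = 47))
  th <- list(sigma2_s = 1, range = 1000, tau2 = 0.1)
  f1 <- fit_spatial_glmm(w$data, outcome ~ env, fix = th)
  set.seed(1)
  idx <- sample(40)
  f2 <- fit_spatial_glmm(w$data[idx, ], outcome ~ env, fix = th)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("vanishing spatial variance degrades continuously to the GLM", {
  w <- build_world(scenario_tone_humidity(n = 60, seed = 53))
  naive <- fit_glm(w$data, outcome ~ env)
  beta_naive <- naive$coefficients$estimate
  prev <- Inf
  for (s2 in c(0.5, 0.05, 0.005)) {
    f <- fit_spatial_glmm(w$data, outcome ~ env,
                          fix = list(sigma2_s = s2, range = 1000,
                                     tau2 = 1e-6))
    gap <- max(abs(f$coefficients$estimate - beta_naive))
    expect_lt(gap, prev + 1e-8)
    prev <- gap
  }
  expect_lt(prev, 0.05)
})

test_that("AIC counts fixed effects plus free variance parameters", {
  w <- build_world(scenario_tone_humidity(n = 60, seed = 59))
  f <- fit_spatial_glmm(w$data, outcome ~ env)
  expect_equal(f$k, 2 + 3) # beta0, beta_env + sigma2_s, range, tau2
  expect_equal(f$aic, 2 * f$k - 2 * f$logLik)
  f2 <- fit_spatial_glmm(w$data, outcome ~ env,
                         fix = list(range = 1000, tau2 = 0.1))
  expect_equal(f2$k, 2 + 1)
})

test_that("conditional modes recover the latent field direction", {
  spec <- scenario_spec(n = 150, points = list(process = "clustered"),
                        outcome = list(beta0 = 0, beta_env = 0,
                                       sigma2_s = 2, range_km = 1500,
                                       tau2 = 0.1),
                        seed = 61)
  w <- build_world(spec)
  f <- fit_spatial_glmm(w$data, outcome ~ env)
  expect_gt(cor(f$u, w$data$.u), 0.3)
})

test_that("model comparison verdicts follow the two p values", {
  w <- build_world(scenario_tone_humidity(n = 80, seed = 67))
  naive <- fit_glm(w$data, outcome ~ env)
  sp <- fit_spatial_glmm(w$data, outcome ~ env)
  cmp <- compare_models(naive, sp)
  expect_true(cmp$verdict %in% c("spatially_robust", "explained_by_space",
                                 "space_revealed", "no_association"))
  expect_equal(cmp$delta_aic, naive$aic - sp$aic)
  want <- if (cmp$p_naive < 0.05 && cmp$p_spatial >= 0.05)
    "explained_by_space"
  else if (cmp$p_naive < 0.05 && cmp$p_spatial < 0.05) "spatially_robust"
  else if (cmp$p_naive >= 0.05 && cmp$p_spatial < 0.05) "space_revealed"
  else "no_association"
  expect_equal(cmp$verdict, want)
  # mismatched fits refuse to compare
  w2 <- build_world(scenario_tone_humidity(n = 60, seed = 68))
  naive2 <- fit_glm(w2$data, outcome ~ env)
  expect_error(compare_models(naive2, sp), "different numbers")
})

test_that("spatial LRT is available as a secondary significance assessment", {
  spec <- scenario_spec(n = 60, points = list(process = "uniform_box"),
                        outcome = list(beta0 = 0, beta_env = 1.2,
                                       sigma2_s = 0.3, range_km = 800,
                                       tau2 = 0.1),
                        seed = 71)
  w <- build_world(spec)
  f <- fit_spatial_glmm(w$data, outcome ~ env)
  lrt <- spatial_lrt(f, "env")
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p.value, 0.2) # strong true effect should not look null
})

test_that("phylospatial fit accepts a tree and estimates a phylo component", {
  set.seed(73)
  spec <- scenario_spec(n = 40, outcome = list(beta0 = 0, beta_env = 0,
                                               sigma2_s = 0.5,
                                               range_km = 1000, tau2 = 0.2,
                                               sigma2_p = 1),
                        seed = 73)
  w <- build_world(spec)
  f <- fit_spatial_glmm(w$data, outcome ~ env, phylo = w$tree)
  expect_true("sigma2_p" %in% f$varcomp$component)
  expect_gte(f$varcomp$estimate[f$varcomp$component == "sigma2_p"], 0)
})
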