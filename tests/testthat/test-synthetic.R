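test_that("generators are pure functions of (spec, seed)", {
  spec <- scenario_tone_humidity(n = 60, seed = 91)
  w1 <- build_world(spec)
  w2 <- build_world(spec)
  expect_identical(w1$data, w2$data)
  spec2 <- scenario_tone_humidity(n = 60, seed = 92)
  expect_false(identical(build_world(spec2)$data$outcome, w1$data$outcome))
  # minimal case
  tiny <- scenario_spec(n = 2, seed = 1)
  expect_equal(nrow(sample_points(tiny)), 2)
})

test_that("clustered point process packs points tighter than uniform", {
  nnd <- function(pts) {
    D <- distance_matrix(pts)
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  set.seed(1)
  ratio <- replicate(40, {
    s <- sample.int(1e6, 1)
    cl <- sample_points(scenario_spec(n = 100, points = list(
      process = "clustered", parents = 5, dispersion_km = 300), seed = s))
    un <- sample_points(scenario_spec(n = 100, points = list(
      process = "uniform_box"), seed = s))
    nnd(cl) / nnd(un)
  })
  expect_lt(mean(ratio), 1)
  expect_gt(mean(ratio < 1), 0.9)
})

test_that("GRF with pure nugget is iid: Moran's I centred on -1/(n-1)", {
  n <- 60
  pts <- sample_points(scenario_spec(n = n, points = list(
    process = "uniform_box"), seed = 3))
  D <- distance_matrix(pts)
  W <- spatial_weights(D)
  ks <- kernel_spec("exponential", sigma2 = 0, range = 1000, nugget = 1)
  I_vals <- vapply(1:300, function(s) {
    morans_i(simulate_grf(D, ks, seed = s), W)$statistic
  }, numeric(1))
  se <- sd(I_vals) / sqrt(300)
  expect_lt(abs(mean(I_vals) - (-1 / (n - 1))), 4 * se + 1e-3)
})

test_that("GRF empirical covariance tracks the exponential kernel", {
  n <- 80
  pts <- sample_points(scenario_spec(n = n, points = list(
    process = "uniform_box", lon_range = c(0, 60), lat_range = c(-30, 30)),
    seed = 5))
  D <- distance_matrix(pts)
  ks <- kernel_spec("exponential", sigma2 = 1, range = 1000)
  U <- vapply(1:400, function(s) simulate_grf(D, ks, seed = s),
              numeric(n))
  C_emp <- tcrossprod(U - rowMeans(U)) / (400 - 1)
  bins <- cut(D[lower.tri(D)], breaks = c(0, 500, 1000, 2000, 4000, 21000))
  emp <- tapply(C_emp[lower.tri(C_emp)], bins, mean)
  theo <- tapply(exp(-D[lower.tri(D)] / 1000), bins, mean)
  expect_lt(max(abs(emp - theo), na.rm = TRUE), 0.12)
  # determinism
  expect_identical(simulate_grf(D, ks, seed = 9), simulate_grf(D, ks, seed = 9))
})

test_that("Brownian traits respect tree structure", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  X <- t(vapply(1:300, function(s) simulate_phylo_trait(star, 1, seed = s),
                numeric(5)))
  C <- cor(X)
  expect_lt(max(abs(C[upper.tri(C)])), 0.2)
  # comb tree: sisters with long shared stems more similar than distant tips
  comb <- ape::read.tree(text = "((A:0.1,B:0.1):1.9,(C:0.1,D:0.1):1.9);")
  sis <- vapply(1:200, function(s) {
    tr <- simulate_phylo_trait(comb, 1, seed = s)
    abs(tr["A"] - tr["B"]) < abs(tr["A"] - tr["C"])
  }, logical(1))
  expect_gt(mean(sis), 0.7)
  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(simulate_phylo_trait(zero, 1, seed = 1), "Zero-depth")
})

test_that("worlds store their truths and keep them out of model formulas", {
  w <- build_world(scenario_tone_humidity(n = 50, seed = 97))
  expect_true(all(c(".u", ".eta", ".env_gradient", ".env_spatial",
                    ".env_noise") %in% names(w$data)))
  f <- fit_glm(w$data, outcome ~ env)
  expect_setequal(f$coefficients$term, c("(Intercept)", "env"))
})

test_that("degenerate binary outcomes trigger one rescue then an error", {
  # beta0 = 12 makes every outcome 1 almost surely; rescue shifts it back
  spec <- scenario_spec(n = 30, outcome = list(beta0 = 12, beta_env = 0,
                                               sigma2_s = 0.1,
                                               range_km = 500, tau2 = 0.1),
                        seed = 101)
  w <- build_world(spec)
  expect_true(all(c(0, 1) %in% w$data$outcome))
})

test_that("worlds round-trip through the CSV schema the readers expect", {
  w <- build_world(scenario_tone_humidity(n = 30, seed = 103))
  pre <- file.path(tempdir(), "world_rt")
  paths <- write_world(w, pre)
  tb <- read_geo_table(paste0(pre, ".csv"), required = c("outcome", "env"))
  expect_equal(nrow(tb), 30)
  expect_equal(tb$outcome, w$data$outcome)
  truth <- jsonlite::fromJSON(paste0(pre, "_truth.json"))
  expect_equal(unname(unlist(truth$truth$.u)), unname(w$data$.u),
               tolerance = 1e-9)
})

test_that("the tone-humidity mimic reproduces the diagnostic signature", {
  # majority of seeds: naive-significant env effect despite beta_env = 0,
  # with clearly autocorrelated residuals
  hits <- vapply(1:15, function(s) {
    w <- build_world(scenario_tone_humidity(n = 300, seed = 200 + s))
    f <- fit_glm(w$data, outcome ~ env)
    m <- residual_moran(f, spatial_weights(w$D))
    c(f$coefficients$p.value[2] < 0.05, m$z > 2)
  }, logical(2))
  expect_gte(mean(hits[2, ]), 0.8)  # residual Moran z > 2 almost always
  expect_gt(mean(hits[1, ]), 0.1)   # naive false positives far above nominal
})
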