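#' Specify a synthetic cross-cultural world
#'
#' A scenario bundles everything needed to generate one synthetic dataset:
#' a point process on the sphere, an environmental covariate composed of a
#' latitudinal gradient plus a spatial Gaussian random field plus white
#' noise (in stated variance shares), and an outcome driven by an optional
#' true effect of the environment plus a spatially (and optionally
#' phylogenetically) autocorrelated latent field. Identical `spec` + `seed`
#' always reproduce the same dataset; the root seed spawns independent
#' streams for points, environment, latent field and outcome so components
#' can be varied independently.
#'
#' @param n Number of sites.
#' @param points List: `process` (`"uniform_box"` or `"clustered"`),
#'   `lon_range`, `lat_range` (decimal degrees), and for `clustered`:
#'   `parents` (number of cluster centres) and `dispersion_km` (Gaussian
#'   offspring jitter scale, km, applied in a local tangent plane).
#' @param env List: `gradient_share`, `spatial_share`, `noise_share`
#'   (non-negative, normalized to sum 1; the gradient component is
#'   `cos(lat)`), and `range_km` for the environmental field.
#' @param outcome List: `family` (`"binomial"` or `"gaussian"`), `beta0`,
#'   `beta_env` (true causal effect), `sigma2_s`, `range_km`, `tau2` for the
#'   latent field, optional `sigma2_p` + `tree` (a `phylo`) for a heritable
#'   component, and `sigma2_e` (Gaussian outcome noise).
#' @param seed Integer root seed.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(n = 200,
                          points = list(),
                          env = list(),
                          outcome = list(),
                          seed = 1L) {
  points <- modifyList(list(process = "clustered", parents = 10,
                            dispersion_km = 400,
                            lon_range = c(-180, 180),
                            lat_range = c(-60, 70)), points)
  env <- modifyList(list(gradient_share = 0.3, spatial_share = 0.5,
                         noise_share = 0.2, range_km = 1500), env)
  outcome <- modifyList(list(family = "binomial", beta0 = -0.4, beta_env = 0,
                             sigma2_s = 2, range_km = 1500, tau2 = 0.25,
                             sigma2_p = 0, tree = NULL, sigma2_e = 1), outcome)
  if (n < 2) abort("Scenario needs n >= 2.")
  if (!points$process %in% c("uniform_box", "clustered")) {
    abort("points$process must be 'uniform_box' or 'clustered'.")
  }
  if (diff(points$lon_range) <= 0 || diff(points$lat_range) <= 0) {
    abort("Empty sampling box.")
  }
  shares <- c(env$gradient_share, env$spatial_share, env$noise_share)
  if (any(shares < 0) || sum(shares) <= 0) {
    abort("Environment variance shares must be non-negative with positive sum.")
  }
  env[c("gradient_share", "spatial_share", "noise_share")] <-
    as.list(shares / sum(shares))
  structure(list(n = as.integer(n), points = points, env = env,
                 outcome = outcome, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> n = %d, %s points, beta_env = %g, sigma2_s = %g (range %g km), seed = %d\n",
              x$n, x$points$process, x$outcome$beta_env, x$outcome$sigma2_s,
              x$outcome$range_km, x$seed))
  invisible(x)
}

#' The tone-humidity mimic scenario
#'
#' A preset emulating the structure of the motivating dataset: 527 clustered
#' sites, a binary outcome with prevalence near 220/527 and a strong
#' exponential latent field, an environmental covariate with a latitudinal
#' gradient plus spatial noise — and *no* true effect (`beta_env = 0`), so
#' any naive significance is a spatial false positive.
#'
#' @param n Number of sites (default 527).
#' @param beta_env True effect (default 0).
#' @param seed Root seed.
#' @return A `scenario_spec`.
#' @export
scenario_tone_humidity <- function(n = 527, beta_env = 0, seed = 1L) {
  scenario_spec(
    n = n,
    points = list(process = "clustered", parents = 8, dispersion_km = 500),
    env = list(gradient_share = 0.25, spatial_share = 0.6, noise_share = 0.15,
               range_km = 2000),
    outcome = list(family = "binomial", beta0 = -0.4, beta_env = beta_env,
                   sigma2_s = 4, range_km = 2000, tau2 = 0.2),
    seed = seed
  )
}

#' A strongly confounded null scenario for false-positive experiments
#'
#' Like [scenario_tone_humidity()] but with the spatial structure
#' concentrated in few clusters and a dominant spatial share in the
#' environment, so that at moderate sample sizes the naive GLM rejects the
#' (truly null) environmental effect in the majority of replicates while a
#' correctly specified spatial model stays calibrated. This is the workhorse
#' scenario for type-I-error experiments with [fpr_experiment()].
#'
#' @param n Number of sites (default 300).
#' @param beta_env True effect (default 0: pure confounding).
#' @param seed Root seed.
#' @return A `scenario_spec`.
#' @export
scenario_confounded <- function(n = 300, beta_env = 0, seed = 1L) {
  scenario_spec(
    n = n,
    points = list(process = "clustered", parents = 15, dispersion_km = 300),
    env = list(gradient_share = 0.05, spatial_share = 0.90,
               noise_share = 0.05, range_km = 3000),
    outcome = list(family = "binomial", beta0 = -0.4, beta_env = beta_env,
                   sigma2_s = 16, range_km = 3000, tau2 = 0.1),
    seed = seed
  )
}

#' Sample site coordinates for a scenario
#'
#' Uniform-box sampling draws lon/lat independently and uniformly in the
#' box; clustered sampling scatters parent points uniformly and displaces
#' offspring with isotropic Gaussian jitter of the stated km scale in the
#' local tangent plane (adequate below ~500 km).
#'
#' @param spec A [scenario_spec()].
#' @return Tibble `id`, `lon`, `lat` (n rows; reproducible from the spec).
#' @export
sample_points <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(derive_seed(spec$seed, "points"))
  pp <- spec$points
  n <- spec$n
  if (pp$process == "uniform_box") {
    lon <- runif(n, pp$lon_range[1], pp$lon_range[2])
    lat <- runif(n, pp$lat_range[1], pp$lat_range[2])
  } else {
    m <- max(1L, as.integer(pp$parents))
    par_lon <- runif(m, pp$lon_range[1], pp$lon_range[2])
    par_lat <- runif(m, pp$lat_range[1], pp$lat_range[2])
    assign_to <- sample.int(m, n, replace = TRUE)
    km_per_deg <- pi * EARTH_RADIUS_KM / 180
    dx <- rnorm(n, 0, pp$dispersion_km)
    dy <- rnorm(n, 0, pp$dispersion_km)
    lat <- pmin(pmax(par_lat[assign_to] + dy / km_per_deg, -89), 89)
    lon <- par_lon[assign_to] +
      dx / (km_per_deg * pmax(cos(lat * pi / 180), 0.05))
    lon <- ((lon + 180) %% 360) - 180
  }
  tibble::tibble(id = sprintf("u%04d", seq_len(n)), lon = lon, lat = lat)
}

#' Simulate a Gaussian random field over given sites
#'
#' Draws `u = L' eps` where `L'` is the (jitter-stabilized) Cholesky factor
#' of the kernel covariance and `eps` is i.i.d. standard normal; mean zero.
#'
#' @param D Distance matrix in km.
#' @param spec A [kernel_spec()].
#' @param seed Integer seed.
#' @return Numeric vector of length `nrow(D)`.
#' @export
simulate_grf <- function(D, spec, seed = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.null(seed)) set.seed(seed)
  S <- spatial_covariance(D, spec)
  if (all(S == 0)) return(rep(0, nrow(D)))
  cs <- chol_safe(S)
  unname(drop(t(cs$R) %*% rnorm(nrow(D))))
}

#' Simulate a Brownian trait on a phylogeny
#'
#' Multivariate-normal draw with covariance `sigma2_p` times the shared
#' root-to-tip path-length matrix.
#'
#' @param tree A `phylo` with branch lengths.
#' @param sigma2_p Trait variance scale (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector in `tree$tip.label` order.
#' @export
simulate_phylo_trait <- function(tree, sigma2_p = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  V <- phylo_covariance(tree, tree$tip.label)
  if (max(diag(V)) <= 0) abort("Zero-depth tree: no variance to simulate.")
  if (!is.null(seed)) set.seed(seed)
  cs <- chol_safe(sigma2_p * V)
  setNames(drop(t(cs$R) %*% rnorm(nrow(V))), tree$tip.label)
}

#' Build a synthetic world
#'
#' Generates coordinates, environment and outcome per the scenario:
#' `env_i = sqrt(g_share) grad_i + sqrt(s_share) grf_i + sqrt(n_share) eps_i`
#' (each component standardized, so `env` has roughly unit variance), then
#' `eta_i = beta0 + beta_env * env_i + u_i (+ phylo_i)` with `u` a GRF from
#' the outcome kernel, and a Bernoulli (logit) or Gaussian outcome. All
#' latent truths are kept in dot-prefixed columns (`.u`, `.eta`,
#' `.env_gradient`, `.env_spatial`, `.env_noise`) which are never picked up
#' by a model formula unless explicitly named.
#'
#' @param spec A [scenario_spec()].
#' @return A `galton_world`: `$data` (geo table tibble with `env`,
#'   `outcome`, truth columns), `$spec`, `$D` (distance matrix), `$tree`.
#' @export
build_world <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  pts <- sample_points(spec)
  D <- distance_matrix(pts)
  ev <- spec$env

  set.seed(derive_seed(spec$seed, "env"))
  grad <- cos(pts$lat * pi / 180)
  grf_env <- simulate_grf(D, kernel_spec("exponential", sigma2 = 1,
                                         range = ev$range_km),
                          seed = derive_seed(spec$seed, "env"))
  noise <- rnorm(spec$n)
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  env <- sqrt(ev$gradient_share) * std(grad) +
    sqrt(ev$spatial_share) * std(grf_env) +
    sqrt(ev$noise_share) * std(noise)

  oc <- spec$outcome
  u <- simulate_grf(D, kernel_spec("exponential", sigma2 = oc$sigma2_s,
                                   range = oc$range_km, nugget = oc$tau2),
                    seed = derive_seed(spec$seed, "field"))
  phylo_part <- rep(0, spec$n)
  tree <- oc$tree
  if ((oc$sigma2_p %||% 0) > 0) {
    if (is.null(tree)) {
      set.seed(derive_seed(spec$seed, "tree"))
      tree <- ape::rcoal(spec$n)
      tree$tip.label <- pts$id
    }
    tr <- simulate_phylo_trait(tree, oc$sigma2_p,
                               seed = derive_seed(spec$seed, "tree"))
    phylo_part <- unname(tr[pts$id])
  }
  eta <- oc$beta0 + oc$beta_env * env + u + phylo_part

  set.seed(derive_seed(spec$seed, "outcome"))
  draw_outcome <- function(eta) {
    if (oc$family == "binomial") rbinom(spec$n, 1, plogis(eta))
    else eta + rnorm(spec$n, 0, sqrt(oc$sigma2_e))
  }
  y <- draw_outcome(eta)
  if (oc$family == "binomial" && length(unique(y)) < 2) {
    # one rescue draw with the linear predictor recentred (prevalence ~ 1/2)
    eta <- eta - mean(eta)
    y <- draw_outcome(eta)
    if (length(unique(y)) < 2) {
      abort("Degenerate binary outcome (single class) even after shifting beta0.")
    }
  }
  data <- dplyr::mutate(pts, env = env, outcome = y,
                        .u = u, .eta = eta,
                        .env_gradient = std(grad),
                        .env_spatial = std(grf_env),
                        .env_noise = std(noise),
                        .phylo = phylo_part)
  structure(list(data = data, spec = spec, D = D, tree = tree),
            class = "galton_world")
}

#' @export
print.galton_world <- function(x, ...) {
  prev <- if (x$spec$outcome$family == "binomial")
    sprintf(", prevalence = %.2f", mean(x$data$outcome)) else ""
  cat(sprintf("<galton_world> n = %d, %s outcome%s, beta_env = %g, seed = %d\n",
              x$spec$n, x$spec$outcome$family, prev, x$spec$outcome$beta_env,
              x$spec$seed))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' The observable table goes to `<path>.csv` in the same schema
#' [read_geo_table()] expects; the generating spec and latent truths go to a
#' sibling `<path>_truth.json`; a simulated tree (if any) to `<path>.nwk`.
#'
#' @param world A `galton_world`.
#' @param path Output path prefix (no extension).
#' @return Invisibly, the paths written.
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "galton_world"))
  obs <- dplyr::select(world$data, !dplyr::starts_with("."))
  csv <- paste0(path, ".csv")
  readr::write_csv(obs, csv)
  truth <- list(spec = unclass(world$spec),
                truth = as.list(dplyr::select(world$data, "id",
                                              dplyr::starts_with("."))))
  js <- paste0(path, "_truth.json")
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  if (!is.null(world$tree)) {
    nwk <- paste0(path, ".nwk")
    ape::write.tree(world$tree, nwk)
    paths <- c(paths, nwk)
  }
  invisible(paths)
}
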