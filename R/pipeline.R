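#' Run the full reanalysis workflow on a trait table
#'
#' The canonical sequence for deciding whether a cross-cultural
#' trait-environment correlation survives spatial control:
#' \enumerate{
#'   \item naive GLM ([fit_glm()]);
#'   \item Moran's I on its Pearson residuals ([residual_moran()]);
#'   \item spatial GLMM with the same formula ([fit_spatial_glmm()]);
#'   \item model comparison and verdict ([compare_models()]).
#' }
#'
#' @param data A data frame or a CSV/TSV path (read via [read_geo_table()]).
#' @param formula Model formula, e.g. `outcome ~ env`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param kernel [kernel_spec()] for the spatial GLMM (initial values).
#' @param phylo Optional phylogenetic source (see [fit_spatial_glmm()]).
#' @param weights_scheme,d_floor Weights for the residual Moran diagnostic
#'   (see [spatial_weights()]).
#' @param moran_method Moran's I method (default `"randomization"`).
#' @param alpha Significance threshold for the verdict.
#' @param seed Integer seed recorded in the report and used for any
#'   permutation step.
#' @param standardize Standardize covariates in both models?
#' @return A `galton_report` with elements `naive`, `moran`, `spatial`,
#'   `comparison`, and `meta` (n, prevalence, config hash, seed).
#' @export
reanalyze <- function(data, formula, family = c("binomial", "gaussian"),
                      kernel = kernel_spec("exponential", sigma2 = 1,
                                           range = 1000, nugget = 0.1),
                      phylo = NULL,
                      weights_scheme = "inverse_distance", d_floor = 1,
                      moran_method = "randomization",
                      alpha = 0.05, seed = 1L, standardize = FALSE) {
  family <- match.arg(family)
  vars <- all.vars(formula)
  if (is.character(data) && length(data) == 1) {
    data <- read_geo_table(data, required = vars)
  } else {
    data <- as_geo_table(data, required = vars)
  }
  config <- list(formula = deparse(formula), family = family,
                 kernel = unclass(kernel), weights_scheme = weights_scheme,
                 d_floor = d_floor, moran_method = moran_method,
                 alpha = alpha, seed = as.integer(seed),
                 standardize = standardize)
  naive <- fit_glm(data, formula, family = family, standardize = standardize)
  D <- distance_matrix(data)
  W <- spatial_weights(D, scheme = weights_scheme, d_floor = d_floor)
  moran <- residual_moran(naive, W, method = moran_method, seed = seed)
  spatial <- fit_spatial_glmm(data, formula, family = family, kernel = kernel,
                              phylo = phylo, standardize = standardize)
  comparison <- compare_models(naive, spatial, alpha = alpha)
  outcome_var <- vars[1]
  meta <- list(n = naive$n,
               prevalence = if (family == "binomial")
                 mean(data[[outcome_var]]) else NA_real_,
               covariates = setdiff(vars, outcome_var),
               alpha = alpha, seed = as.integer(seed),
               config_hash = rlang::hash(config),
               version = as.character(utils::packageVersion("galton")))
  structure(list(naive = naive, moran = moran, spatial = spatial,
                 comparison = comparison, meta = meta, config = config),
            class = "galton_report")
}

#' @export
print.galton_report <- function(x, ...) {
  cat(sprintf("Reanalysis report (n = %d%s)\n", x$meta$n,
              if (!is.na(x$meta$prevalence))
                sprintf(", outcome prevalence = %.3f", x$meta$prevalence)
              else ""))
  cat("\nNaive model:\n  ", summarize_fit_line_safe(x$naive), "\n", sep = "")
  cat("\nResidual autocorrelation:\n  ")
  print(x$moran)
  cat("\nSpatial model (focal covariate):\n")
  co <- x$spatial$coefficients
  focal <- x$comparison$focal
  row <- co[co$term == focal, ]
  cat(sprintf("  beta = %.3f (SE %.3f), z = %.2f, p = %.4g; AIC = %.2f\n",
              row$estimate, row$std.error, row$statistic, row$p.value,
              x$spatial$aic))
  vc <- x$spatial$varcomp
  cat(sprintf("  variance components: sigma2_s = %.3f, range = %.0f km, tau2 = %.3f\n",
              vc$estimate[vc$component == "sigma2_s"],
              vc$estimate[vc$component == "range"],
              vc$estimate[vc$component == "tau2"]))
  cat("\n")
  print(x$comparison)
  invisible(x)
}

summarize_fit_line_safe <- function(fit) {
  if (fit$family == "binomial") summarize_fit_line(fit)
  else sprintf("N = %d, gaussian fit, AIC = %.2f", fit$n, fit$aic)
}

#' Serialize a reanalysis report to JSON
#'
#' @param report A `galton_report`.
#' @param path Optional output path; if `NULL`, returns the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "galton_report"))
  obj <- list(
    schema = "galton_report/1",
    meta = report$meta,
    config = report$config,
    naive = list(coefficients = report$naive$coefficients,
                 logLik = report$naive$logLik, aic = report$naive$aic,
                 caption = summarize_fit_line_safe(report$naive)),
    residual_moran = jsonlite::fromJSON(moran_json(report$moran)),
    spatial = list(coefficients = report$spatial$coefficients,
                   varcomp = report$spatial$varcomp,
                   logLik = report$spatial$logLik, aic = report$spatial$aic),
    comparison = tidy(report$comparison)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' False-positive-rate experiment over replicated synthetic worlds
#'
#' Repeatedly generates worlds from `spec` (each replicate gets a derived
#' seed), fits the naive GLM and the spatial GLMM, and records whether each
#' rejects the focal covariate at `alpha`, plus the comparison verdict.
#' With `beta_env = 0` in the spec the rejection rates are type-I error
#' estimates: the naive rate shows the spatial false-positive inflation,
#' the spatial rate shows the correction.
#'
#' @param spec A [scenario_spec()]; its seed is the experiment root seed.
#' @param replicates Number of replicate worlds (>= 1).
#' @param alpha Significance threshold.
#' @param fit_spatial Fit the spatial model too? (`FALSE` gives a cheap
#'   naive-only calibration run.)
#' @param kernel Kernel passed to [fit_spatial_glmm()].
#' @return A `galton_experiment`: `$replicates` tibble (per-replicate p
#'   values, rejections, verdicts, seeds) and `$summary` tibble with
#'   rejection rates and exact (Clopper-Pearson) 95% binomial CIs.
#' @export
fpr_experiment <- function(spec, replicates = 100, alpha = 0.05,
                           fit_spatial = TRUE,
                           kernel = kernel_spec("exponential", sigma2 = 1,
                                                range = 1000,
                                                nugget = 0.1)) {
  stopifnot(inherits(spec, "scenario_spec"))
  replicates <- as.integer(replicates)
  if (replicates < 1) abort("Need at least one replicate.")
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rspec <- spec
    rspec$seed <- derive_seed(spec$seed + r, "replicate")
    world <- build_world(rspec)
    naive <- fit_glm(world$data, outcome ~ env,
                     family = spec$outcome$family)
    p_n <- naive$coefficients$p.value[naive$coefficients$term == "env"]
    if (fit_spatial) {
      sp <- fit_spatial_glmm(world$data, outcome ~ env,
                             family = spec$outcome$family, kernel = kernel)
      p_s <- sp$coefficients$p.value[sp$coefficients$term == "env"]
      verdict <- compare_models(naive, sp, alpha = alpha)$verdict
    } else {
      p_s <- NA_real_
      verdict <- NA_character_
    }
    rows[[r]] <- tibble::tibble(replicate = r, seed = rspec$seed,
                                p_naive = p_n, p_spatial = p_s,
                                reject_naive = p_n < alpha,
                                reject_spatial = p_s < alpha,
                                verdict = verdict)
  }
  reps <- dplyr::bind_rows(rows)
  rate_row <- function(method, rejections) {
    k <- sum(rejections); ci <- binom.test(k, replicates)$conf.int
    tibble::tibble(method = method, rejections = k, replicates = replicates,
                   rate = k / replicates, conf.low = ci[1], conf.high = ci[2])
  }
  summary <- rate_row("naive_glm", reps$reject_naive)
  if (fit_spatial) {
    summary <- dplyr::bind_rows(summary,
                                rate_row("spatial_glmm", reps$reject_spatial))
  }
  structure(list(replicates = reps, summary = summary, spec = spec,
                 alpha = alpha),
            class = "galton_experiment")
}

#' @export
print.galton_experiment <- function(x, ...) {
  cat(sprintf("False-positive-rate experiment: %d replicates, alpha = %g, beta_env = %g\n",
              nrow(x$replicates), x$alpha, x$spec$outcome$beta_env))
  print(x$summary)
  if (!all(is.na(x$replicates$verdict))) {
    cat("Verdicts:\n")
    print(table(x$replicates$verdict))
  }
  invisible(x)
}

#' @export
tidy.galton_experiment <- function(x, ...) x$replicates

#' @export
glance.galton_experiment <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "method",
                             values_from = c("rate", "conf.low", "conf.high",
                                             "rejections"))
  dplyr::mutate(wide, alpha = x$alpha,
                modal_verdict = if (all(is.na(x$replicates$verdict)))
                  NA_character_
                else names(which.max(table(x$replicates$verdict))))
}
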