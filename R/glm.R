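#' Fit a naive generalized linear model (from-scratch IRLS)
#'
#' Maximum-likelihood logistic (binomial-logit) or Gaussian-identity
#' regression by iteratively reweighted least squares, with Wald standard
#' errors from the inverse observed information, two-sided p values, 95%
#' confidence intervals, odds ratios (logistic), log-likelihood and AIC.
#' This is the "naive" model of the workflow: it assumes independent
#' observations and is therefore the model whose residuals get diagnosed
#' with [residual_moran()].
#'
#' @param data A data frame (typically a geo table) containing the model
#'   variables; rows with missing values in them are dropped listwise.
#' @param formula Model formula, e.g. `outcome ~ humidity`.
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity).
#' @param standardize Center/scale the non-intercept columns of the design
#'   matrix to mean 0, SD 1 before fitting?
#' @param max_iter,tol_score,tol_dev IRLS controls: iteration cap,
#'   convergence thresholds on `max |score|` and relative deviance change.
#' @return A `galton_glm` object; see [tidy()], [glance()],
#'   [summarize_fit_line()].
#' @examples
#' d <- tibble::tibble(y = c(0, 1, 0, 1), x = c(0, 0, 1, 1))
#' fit_glm(d, y ~ x)
#' @export
fit_glm <- function(data, formula, family = c("binomial", "gaussian"),
                    standardize = FALSE, max_iter = 100,
                    tol_score = 1e-8, tol_dev = 1e-10) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Model variable(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[, vars, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped (missing model variables).")
    data <- data[keep, , drop = FALSE]
  }
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (standardize) {
    for (j in seq_len(p)) {
      if (colnames(X)[j] == "(Intercept)") next
      s <- sd(X[, j])
      if (s > 0) X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  if (qr(X)$rank < p) abort("Design matrix is rank deficient.")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) abort("Binomial family requires a 0/1 outcome.")
    if (length(unique(y)) < 2) {
      abort("Binary outcome contains a single class; logistic model unfittable.")
    }
    fit <- irls_logit(X, y, max_iter, tol_score, tol_dev)
    mu <- fit$mu
    pearson <- (y - mu) / sqrt(mu * (1 - mu))
    devres <- sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu)))
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    k <- p
  } else {
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    mu <- drop(X %*% beta)
    rss <- sum((y - mu)^2)
    s2_ml <- rss / n
    cov_beta <- chol2inv(qr.R(qrX)) * (rss / (n - p))
    ll <- -n / 2 * (log(2 * pi * s2_ml) + 1)
    fit <- list(beta = beta, cov = cov_beta, iter = 1L, grad_norm = 0,
                deviance = rss, mu = mu)
    pearson <- (y - mu) / sqrt(rss / (n - p))
    devres <- y - mu
    k <- p + 1  # residual variance counts as an estimated parameter
  }
  se <- sqrt(diag(fit$cov))
  zval <- fit$beta / se
  pval <- 2 * pnorm(-abs(zval))
  crit <- qnorm(0.975)
  lo <- fit$beta - crit * se
  hi <- fit$beta + crit * se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(fit$beta), std.error = unname(se),
    statistic = unname(zval), p.value = unname(pval),
    conf.low = unname(lo), conf.high = unname(hi)
  )
  if (family == "binomial") {
    coefs$odds.ratio <- exp(coefs$estimate)
    coefs$or.low <- exp(coefs$conf.low)
    coefs$or.high <- exp(coefs$conf.high)
  }
  structure(list(
    coefficients = coefs, family = family, formula = formula,
    logLik = ll, aic = 2 * k - 2 * ll, k = k, n = n,
    df.residual = n - p, deviance = fit$deviance,
    fitted = fit$mu, y = y, X = X,
    ids = if ("id" %in% names(data)) as.character(data$id) else NULL,
    residuals = list(pearson = pearson, deviance = devres,
                     response = y - fit$mu),
    converged = TRUE, iter = fit$iter, grad_norm = fit$grad_norm,
    standardized = standardize
  ), class = "galton_glm")
}

irls_logit <- function(X, y, max_iter, tol_score, tol_dev) {
  p <- ncol(X)
  beta <- rep(0, p)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(X, y - mu))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300)))
    dev_drop <- dev_old - dev
    if (max(abs(beta)) > 15 && dev_drop > 0) {
      worst <- colnames(X)[which.max(abs(beta))]
      abort(paste0("Perfect (or quasi-perfect) separation detected; ",
                   "runaway coefficient for '", worst, "'."))
    }
    if (max(abs(score)) < tol_score ||
        (is.finite(dev_old) && abs(dev_drop) < tol_dev * (abs(dev) + 0.1))) {
      if (dev < 1e-6 && nrow(X) > ncol(X)) {
        cand <- setdiff(colnames(X), "(Intercept)")
        worst <- if (length(cand) > 0) {
          cand[which.max(abs(beta[match(cand, colnames(X))]))]
        } else colnames(X)[1]
        abort(paste0("Perfect separation: deviance collapsed to zero; ",
                     "covariate '", worst, "' classifies the outcome exactly."))
      }
      info <- crossprod(X * w, X)
      return(list(beta = beta, cov = chol2inv(chol(info)), iter = it,
                  grad_norm = max(abs(score)), deviance = dev, mu = mu))
    }
    dev_old <- dev
    zvec <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(X * w, X), crossprod(X * w, zvec)))
  }
  abort(paste0("IRLS failed to converge in ", max_iter,
               " iterations (last max |score| = ",
               signif(max(abs(score)), 3), ")."))
}

#' @export
print.galton_glm <- function(x, ...) {
  cat(sprintf("<galton_glm> %s, N = %d, logLik = %.3f, AIC = %.2f\n",
              x$family, x$n, x$logLik, x$aic))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.galton_glm <- function(x, ...) x$coefficients

#' @export
glance.galton_glm <- function(x, ...) {
  tibble::tibble(nobs = x$n, logLik = x$logLik, AIC = x$aic,
                 deviance = x$deviance, df.residual = x$df.residual,
                 family = x$family, iter = x$iter)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced Two `galton_glm` fits on the same rows, the reduced
#'   model's terms a subset of the full model's.
#' @return A tibble with `statistic` (`2 * (ll_full - ll_reduced)`), `df`,
#'   and the chi-squared upper-tail `p.value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "galton_glm"), inherits(reduced, "galton_glm"))
  if (full$n != reduced$n) abort("Models fitted to different numbers of rows.")
  if (!all(reduced$coefficients$term %in% full$coefficients$term)) {
    abort("Models are not nested: reduced terms not a subset of full terms.")
  }
  df <- full$k - reduced$k
  if (df < 0) abort("Models are not nested: reduced model has more parameters.")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  tibble::tibble(statistic = stat, df = df,
                 p.value = if (df == 0) 1 else pchisq(stat, df,
                                                      lower.tail = FALSE))
}

#' One-line model summary in the conventional caption format
#'
#' Formats a logistic fit as
#' `"N = ..., beta = ..., 95%CI [...-...], OR = ..., 95%CI [...-...],
#' z = ..., p = ..., d.f. = ..., AIC = ..."` with the focal coefficient's
#' beta, OR and CIs to 3 significant figures, z to 2 decimals, and AIC to 2
#' decimals.
#'
#' @param fit A `galton_glm` logistic fit.
#' @param focal Name of the focal covariate; default: first non-intercept
#'   term.
#' @return A single string.
#' @export
summarize_fit_line <- function(fit, focal = NULL) {
  stopifnot(inherits(fit, "galton_glm"))
  if (fit$family != "binomial") abort("Caption line is defined for logistic fits.")
  co <- fit$coefficients
  terms <- setdiff(co$term, "(Intercept)")
  focal <- focal %||% terms[1]
  row <- co[co$term == focal, ]
  if (nrow(row) != 1) abort(paste0("Focal term '", focal, "' not in fit."))
  s3 <- function(v) {
    if (abs(v) < 5e-13) return("0.000")
    formatC(signif(v, 3), format = "fg", flag = "#", digits = 3)
  }
  sprintf(paste0("N = %d, β = %s, 95%%CI [%s–%s], OR = %s, ",
                 "95%%CI [%s–%s], z = %.2f, p = %s, d.f. = %d, AIC = %.2f"),
          fit$n, s3(row$estimate), s3(row$conf.low), s3(row$conf.high),
          s3(row$odds.ratio), s3(row$or.low), s3(row$or.high),
          row$statistic, format.pval(row$p.value, digits = 2, eps = 1e-3),
          fit$df.residual, fit$aic)
}
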