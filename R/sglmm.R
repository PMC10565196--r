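#' Fit a latent-Gaussian spatial (phylospatial) GLMM by Laplace approximation
#'
#' The corrective model of the workflow. Each observation carries a latent
#' random effect `u` with a structured covariance built from great-circle
#' distance (exponential/Matern kernel) and, optionally, relatedness:
#'
#' `y_i ~ family(g^-1(x_i' beta + u_i))`,
#' `u ~ MVN(0, Sigma)`, `Sigma = sigma2_s K_s(range) + sigma2_p K_p + tau2 I`
#'
#' with `K_s`, `K_p` correlation-scaled so `sigma2_s`/`sigma2_p` are
#' comparable marginal variance components. Variance parameters are
#' maximized on the log scale over the Laplace-approximate marginal
#' likelihood (Nelder-Mead outer search); at each candidate, the fixed
#' effects and the conditional mode of `u` are found jointly by penalized
#' Newton (penalized IRLS). If the data carry no autocorrelation the
#' variance components shrink toward zero and the fit collapses to the
#' naive GLM. For the Gaussian family the "Laplace" likelihood is exact and
#' equals generalized least squares.
#'
#' @param data Data frame with `lon`/`lat` columns (and `id` if a phylo
#'   source is used) plus the model variables.
#' @param formula Model formula, e.g. `outcome ~ humidity`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param kernel A [kernel_spec()] giving the spatial kernel family/smoothness
#'   and the *initial* values of `sigma2`, `range`, `nugget` for the search.
#' @param phylo Optional phylogenetic source (`phylo` tree, Newick path, or
#'   classification data frame; see [phylo_covariance()]). Adds a `sigma2_p`
#'   component.
#' @param fix Named list fixing variance parameters instead of estimating
#'   them, e.g. `list(sigma2_s = 0, tau2 = 0)`. Names: `sigma2_s`, `range`,
#'   `tau2`, `sigma2_p`, `sigma2_e` (Gaussian residual variance).
#' @param standardize Standardize non-intercept design columns?
#' @param control List: `maxit` (outer, default 500), `reltol` (outer,
#'   1e-8), `inner_maxit` (60), `inner_tol` (1e-8), `tau2_floor` (1e-6).
#' @return A `galton_sglmm` object: coefficient table with Wald inference,
#'   `varcomp` tibble (with `range` in km), Laplace `logLik`, `AIC` counting
#'   fixed effects plus free variance parameters, conditional modes `u`,
#'   convergence diagnostics.
#' @seealso [compare_models()], [spatial_lrt()]
#' @export
fit_spatial_glmm <- function(data, formula, family = c("binomial", "gaussian"),
                             kernel = kernel_spec("exponential", sigma2 = 1,
                                                  range = 1000, nugget = 0.1),
                             phylo = NULL, fix = list(),
                             standardize = FALSE, control = list()) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), inherits(kernel, "kernel_spec"))
  vars <- all.vars(formula)
  need <- unique(c(vars, "lon", "lat"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[, need, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped (missing model variables or coordinates).")
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 10) abort("Spatial GLMM requires at least 10 observations.")
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  if (standardize) {
    for (j in seq_len(ncol(X))) {
      if (colnames(X)[j] == "(Intercept)") next
      s <- sd(X[, j]); if (s > 0) X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  if (qr(X)$rank < ncol(X)) abort("Design matrix is rank deficient.")
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    abort("Binomial family requires a 0/1 outcome.")
  }
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  geo <- tibble::tibble(id = ids, lon = data$lon, lat = data$lat)
  D <- distance_matrix(geo)
  K_p <- if (!is.null(phylo)) to_correlation(phylo_covariance(phylo, ids)) else NULL

  fit <- sglmm_fit(X = X, y = y, D = D, K_p = K_p, family = family,
                   kernel = kernel, fix = fix, control = control)
  fit$formula <- formula
  fit$ids <- ids
  fit$refit <- list(X = X, y = y, D = D, K_p = K_p, family = family,
                    kernel = kernel, fix = fix, control = control)
  fit
}

# Core fitting routine on prepared matrices. Returns a galton_sglmm.
sglmm_fit <- function(X, y, D, K_p, family, kernel, fix, control) {
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-8, inner_maxit = 60,
                          inner_tol = 1e-8, tau2_floor = 1e-6), control)
  n <- nrow(X); p <- ncol(X)
  has_phylo <- !is.null(K_p)

  par_names <- c("sigma2_s", "range", "tau2",
                 if (has_phylo) "sigma2_p",
                 if (family == "gaussian") "sigma2_e")
  start <- c(sigma2_s = kernel$sigma2,
             range = kernel$range,
             tau2 = max(kernel$nugget, 0.05),
             sigma2_p = if (has_phylo) 0.5 else NULL,
             sigma2_e = if (family == "gaussian") max(var(y) / 2, 1e-4) else NULL)
  bad_fix <- setdiff(names(fix), par_names)
  if (length(bad_fix) > 0) {
    abort(paste0("Unknown variance parameter(s) in 'fix': ",
                 paste(bad_fix, collapse = ", ")))
  }
  fixed <- unlist(fix)
  free <- setdiff(par_names, names(fixed))

  theta_assemble <- function(log_free) {
    th <- as.list(fixed)
    th[free] <- as.list(exp(log_free))
    th$tau2 <- max(th$tau2 %||% 0, if (identical(th$sigma2_s, 0) &&
                                       identical(th$sigma2_p %||% 0, 0) &&
                                       family == "binomial") 0 else 0)
    th
  }

  build_sigma <- function(th) {
    S <- matrix(0, n, n)
    if ((th$sigma2_s %||% 0) > 0) {
      S <- S + th$sigma2_s *
        kernel_correlation(D, kernel$family, kernel$nu, max(th$range, 1e-6))
    }
    if (has_phylo && (th$sigma2_p %||% 0) > 0) S <- S + th$sigma2_p * K_p
    S + diag(th$tau2 %||% 0, n)
  }

  # Warm starts carried across objective evaluations.
  state <- new.env(parent = emptyenv())
  state$beta <- rep(0, p)
  state$u <- rep(0, n)

  eval_at <- function(th, want_fit = FALSE) {
    latent_var <- (th$sigma2_s %||% 0) + (th$sigma2_p %||% 0) + (th$tau2 %||% 0)
    if (family == "gaussian") {
      V <- build_sigma(th) + diag(th$sigma2_e, n)
      cv <- chol_safe(V)
      Vi_X <- backsolve(cv$R, forwardsolve(t(cv$R), X))
      Vi_y <- backsolve(cv$R, forwardsolve(t(cv$R), y))
      XtViX <- crossprod(X, Vi_X)
      beta <- drop(solve(XtViX, crossprod(X, Vi_y)))
      res <- y - drop(X %*% beta)
      Vi_r <- backsolve(cv$R, forwardsolve(t(cv$R), res))
      ll <- -0.5 * (cv$logdet + sum(res * Vi_r) + n * log(2 * pi))
      if (!want_fit) return(ll)
      u_hat <- if (latent_var > 0) drop(build_sigma(th) %*% Vi_r) else rep(0, n)
      mu <- drop(X %*% beta) + u_hat
      return(list(ll = ll, beta = beta, u = u_hat,
                  cov_beta = solve(XtViX), fitted = mu,
                  pearson = res / sqrt(th$sigma2_e),
                  inner_iter = 1L, inner_grad = 0))
    }
    # binomial with no latent variance: plain GLM
    if (latent_var <= 0) {
      g <- irls_logit(X, y, 100, 1e-8, 1e-10)
      ll <- sum(y * log(g$mu) + (1 - y) * log1p(-g$mu))
      if (!want_fit) return(ll)
      return(list(ll = ll, beta = g$beta, u = rep(0, n),
                  cov_beta = g$cov, fitted = g$mu,
                  pearson = (y - g$mu) / sqrt(g$mu * (1 - g$mu)),
                  inner_iter = g$iter, inner_grad = g$grad_norm))
    }
    S <- build_sigma(th)
    cs <- chol_safe(S)
    Q <- chol2inv(cs$R)
    beta <- state$beta; u <- state$u
    pen_ll <- function(beta, u) {
      eta <- drop(X %*% beta) + u
      sum(y * eta - log1p(exp(eta))) - 0.5 * sum(u * (Q %*% u))
    }
    lp <- pen_ll(beta, u)
    ok <- FALSE
    for (it in seq_len(ctrl$inner_maxit)) {
      eta <- drop(X %*% beta) + u
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      r <- y - mu
      g_vec <- c(drop(crossprod(X, r)), r - drop(Q %*% u))
      if (max(abs(g_vec)) < ctrl$inner_tol) { ok <- TRUE; break }
      Xw <- X * w
      H <- matrix(0, p + n, p + n)
      H[seq_len(p), seq_len(p)] <- crossprod(Xw, X)
      H[seq_len(p), p + seq_len(n)] <- t(Xw)
      H[p + seq_len(n), seq_len(p)] <- Xw
      H[p + seq_len(n), p + seq_len(n)] <- Q + diag(w, n)
      Rh <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(Rh)) {
        H <- H + diag(1e-8, p + n)
        Rh <- chol(H)
      }
      step <- backsolve(Rh, forwardsolve(t(Rh), g_vec))
      alpha_step <- 1
      repeat {
        beta_new <- beta + alpha_step * step[seq_len(p)]
        u_new <- u + alpha_step * step[p + seq_len(n)]
        lp_new <- pen_ll(beta_new, u_new)
        if (is.finite(lp_new) && lp_new >= lp - 1e-10) break
        alpha_step <- alpha_step / 2
        if (alpha_step < 1e-8) break
      }
      beta <- beta_new; u <- u_new; lp <- lp_new
      ok <- TRUE
    }
    state$beta <- beta; state$u <- u
    eta <- drop(X %*% beta) + u
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    QW <- Q + diag(w, n)
    cqw <- chol_safe(QW)
    ll <- pen_ll(beta, u) - 0.5 * (cs$logdet + cqw$logdet)
    if (!want_fit) return(ll)
    # Wald information for beta: X' W X - X' W (W + Q)^-1 W X  (Woodbury form
    # of X' (W^-1 + Sigma)^-1 X)
    Xw <- X * w
    M <- backsolve(cqw$R, forwardsolve(t(cqw$R), Xw))
    info <- crossprod(Xw, X) - crossprod(Xw, M)
    list(ll = ll, beta = beta, u = u,
         cov_beta = solve(info), fitted = mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         inner_iter = ctrl$inner_maxit, inner_grad = max(abs(
           c(drop(crossprod(X, y - mu)), (y - mu) - drop(Q %*% u)))))
  }

  objective <- function(log_free) {
    th <- theta_assemble(log_free)
    if ((th$tau2 %||% 0) < ctrl$tau2_floor &&
        (!"tau2" %in% names(fixed))) th$tau2 <- ctrl$tau2_floor
    ll <- tryCatch(eval_at(th), error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)  # barrier: reject pathological theta
    -ll
  }

  outer <- NULL
  if (length(free) > 0) {
    par0 <- log(pmax(start[free], 1e-8))
    if (length(free) == 1) {
      outer <- optim(par0, objective, method = "Brent",
                     lower = log(1e-10), upper = log(1e8))
    } else {
      outer <- optim(par0, objective, method = "Nelder-Mead",
                     control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
      if (outer$convergence != 0) {
        # one restart from the incumbent
        outer <- optim(outer$par, objective, method = "Nelder-Mead",
                       control = list(maxit = ctrl$maxit,
                                      reltol = ctrl$reltol))
      }
    }
    if (!is.null(outer$convergence) && outer$convergence != 0) {
      warn("Outer variance-parameter search hit its iteration cap; results may be at a flat likelihood.")
    }
    log_free_hat <- outer$par
  } else {
    log_free_hat <- numeric(0)
  }
  th_hat <- theta_assemble(log_free_hat)
  if ((th_hat$tau2 %||% 0) < ctrl$tau2_floor && !"tau2" %in% names(fixed) &&
      length(free) > 0) th_hat$tau2 <- ctrl$tau2_floor
  final <- eval_at(th_hat, want_fit = TRUE)

  # Refinement: the joint (beta, u) mode slightly shrinks beta relative to
  # the Laplace objective proper (the log-determinant depends on beta through
  # the weights). Re-optimize beta against the true Laplace marginal at the
  # estimated theta, with u re-solved at every candidate beta.
  latent_var_hat <- (th_hat$sigma2_s %||% 0) + (th_hat$sigma2_p %||% 0) +
    (th_hat$tau2 %||% 0)
  if (family == "binomial" && latent_var_hat > 0) {
    S <- build_sigma(th_hat)
    cs <- chol_safe(S)
    Q <- chol2inv(cs$R)
    u_cur <- final$u
    laplace_beta <- function(beta) {
      u <- u_cur
      for (it in seq_len(ctrl$inner_maxit)) {
        eta <- drop(X %*% beta) + u
        mu <- plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-10)
        g <- (y - mu) - drop(Q %*% u)
        if (max(abs(g)) < ctrl$inner_tol) break
        u <- u + drop(solve(Q + diag(w, n), g))
      }
      u_cur <<- u
      eta <- drop(X %*% beta) + u
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      lp <- sum(y * eta - log1p(exp(eta))) - 0.5 * sum(u * (Q %*% u))
      cqw <- chol_safe(Q + diag(w, n))
      list(ll = lp - 0.5 * (cs$logdet + cqw$logdet), u = u, mu = mu, w = w,
           cqwR = cqw$R)
    }
    ref <- if (p == 1) {
      optim(final$beta, function(b) -laplace_beta(b)$ll, method = "Brent",
            lower = final$beta - 10, upper = final$beta + 10)
    } else {
      optim(final$beta, function(b) -laplace_beta(b)$ll,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-9))
    }
    if (ref$value <= -final$ll + 1e-8) {
      at <- laplace_beta(ref$par)
      Xw <- X * at$w
      M <- backsolve(at$cqwR, forwardsolve(t(at$cqwR), Xw))
      info <- crossprod(Xw, X) - crossprod(Xw, M)
      final <- list(ll = at$ll, beta = ref$par, u = at$u,
                    cov_beta = solve(info), fitted = at$mu,
                    pearson = (y - at$mu) / sqrt(at$mu * (1 - at$mu)),
                    inner_iter = final$inner_iter,
                    inner_grad = final$inner_grad)
    }

    # Wald covariance for beta from the observed information of the Laplace
    # marginal in (beta, log theta) jointly: conditioning on theta-hat alone
    # understates the uncertainty of beta when the variance parameters are
    # themselves estimated. Free parameters sitting at their boundary (e.g.
    # the nugget at its floor) carry no curvature and are held fixed here.
    active <- free[vapply(free, function(nm) {
      nm == "range" || (th_hat[[nm]] %||% 0) > 1e-5
    }, logical(1))]
    if (length(active) > 0) {
      u_fd <- final$u
      lap_full <- function(phi) {
        beta <- phi[seq_len(p)]
        lth <- log_free_hat
        lth[match(active, free)] <- phi[p + seq_along(active)]
        th <- theta_assemble(lth)
        if ((th$tau2 %||% 0) < ctrl$tau2_floor && !"tau2" %in% names(fixed)) {
          th$tau2 <- ctrl$tau2_floor
        }
        S <- build_sigma(th)
        cs2 <- chol_safe(S)
        Q2 <- chol2inv(cs2$R)
        u <- u_fd
        for (it in seq_len(ctrl$inner_maxit)) {
          eta <- drop(X %*% beta) + u
          mu <- plogis(eta)
          w2 <- pmax(mu * (1 - mu), 1e-10)
          g <- (y - mu) - drop(Q2 %*% u)
          if (max(abs(g)) < ctrl$inner_tol) break
          u <- u + drop(solve(Q2 + diag(w2, n), g))
        }
        u_fd <<- u
        eta <- drop(X %*% beta) + u
        mu <- plogis(eta)
        w2 <- pmax(mu * (1 - mu), 1e-10)
        lp <- sum(y * eta - log1p(exp(eta))) - 0.5 * sum(u * (Q2 %*% u))
        cqw2 <- chol_safe(Q2 + diag(w2, n))
        -(lp - 0.5 * (cs2$logdet + cqw2$logdet))
      }
      phi_hat <- c(final$beta, log_free_hat[match(active, free)])
      H <- fd_hessian(lap_full, phi_hat, h = 1e-3)
      cov_full <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(cov_full)) {
        cb <- cov_full[seq_len(p), seq_len(p), drop = FALSE]
        if (all(is.finite(diag(cb))) && all(diag(cb) > 0)) {
          final$cov_beta <- cb
        }
      }
    }
  }

  # forward-difference outer gradient at the optimum (diagnostic only)
  outer_grad <- if (length(free) > 0) {
    f0 <- -final$ll
    vapply(seq_along(log_free_hat), function(j) {
      lp <- log_free_hat; lp[j] <- lp[j] + 1e-4
      (objective(lp) - f0) / 1e-4
    }, numeric(1))
  } else numeric(0)

  se <- sqrt(pmax(diag(final$cov_beta), 0))
  zval <- final$beta / se
  crit <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(final$beta),
    std.error = unname(se), statistic = unname(zval),
    p.value = unname(2 * pnorm(-abs(zval))),
    conf.low = unname(final$beta - crit * se),
    conf.high = unname(final$beta + crit * se)
  )
  if (family == "binomial") {
    coefs$odds.ratio <- exp(coefs$estimate)
    coefs$or.low <- exp(coefs$conf.low)
    coefs$or.high <- exp(coefs$conf.high)
  }
  varcomp <- tibble::tibble(
    component = par_names,
    estimate = vapply(par_names, function(nm) th_hat[[nm]] %||% 0, numeric(1)),
    fixed = par_names %in% names(fixed),
    unit = ifelse(par_names == "range", "km", "variance")
  )
  k <- p + length(free)
  structure(list(
    coefficients = coefs, varcomp = varcomp, family = family,
    kernel_family = kernel$family, nu = kernel$nu,
    logLik = final$ll, aic = 2 * k - 2 * final$ll, k = k,
    n = n, df.residual = n - p,
    u = final$u, fitted = final$fitted, y = y, X = X,
    residuals = list(pearson = final$pearson),
    convergence = list(
      outer_convergence = if (is.null(outer)) 0L else outer$convergence,
      outer_evals = if (is.null(outer)) 1L else unname(outer$counts[1]),
      outer_grad = outer_grad, free = free)
  ), class = "galton_sglmm")
}

#' @export
print.galton_sglmm <- function(x, ...) {
  cat(sprintf("<galton_sglmm> %s + %s spatial field, N = %d, logLik = %.3f, AIC = %.2f\n",
              x$family, x$kernel_family, x$n, x$logLik, x$aic))
  print(x$coefficients)
  cat("Variance components:\n")
  print(x$varcomp)
  invisible(x)
}

#' @export
tidy.galton_sglmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") return(x$coefficients)
  dplyr::mutate(x$varcomp, term = .data$component)
}

#' @export
glance.galton_sglmm <- function(x, ...) {
  vc <- setNames(as.list(x$varcomp$estimate), x$varcomp$component)
  tibble::tibble(nobs = x$n, logLik = x$logLik, AIC = x$aic,
                 sigma2_s = vc$sigma2_s %||% 0, range = vc$range %||% NA_real_,
                 tau2 = vc$tau2 %||% 0, sigma2_p = vc$sigma2_p %||% 0,
                 family = x$family)
}

#' Likelihood-ratio test for a term in the spatial model
#'
#' Refits the spatial GLMM without `term` (variance structure re-estimated)
#' and compares Laplace log-likelihoods; the secondary significance
#' assessment alongside the Wald z.
#'
#' @param fit A `galton_sglmm` from [fit_spatial_glmm()].
#' @param term Coefficient to drop; default: first non-intercept term.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
spatial_lrt <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "galton_sglmm"))
  rf <- fit$refit
  if (is.null(rf)) abort("Fit does not carry refit information.")
  terms <- setdiff(colnames(rf$X), "(Intercept)")
  term <- term %||% terms[1]
  if (!term %in% colnames(rf$X)) abort(paste0("Term '", term, "' not in model."))
  X0 <- rf$X[, setdiff(colnames(rf$X), term), drop = FALSE]
  fit0 <- sglmm_fit(X = X0, y = rf$y, D = rf$D, K_p = rf$K_p,
                    family = rf$family, kernel = rf$kernel, fix = rf$fix,
                    control = rf$control)
  stat <- max(0, 2 * (fit$logLik - fit0$logLik))
  tibble::tibble(statistic = stat, df = 1,
                 p.value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Compare a naive and a spatial fit of the same association
#'
#' Emits the AIC difference, both focal p values, and a categorical verdict:
#' \describe{
#'   \item{spatially_robust}{significant in both models;}
#'   \item{explained_by_space}{naive-significant only — the association is
#'     accounted for by proximity;}
#'   \item{space_revealed}{spatial-significant only;}
#'   \item{no_association}{significant in neither.}
#' }
#'
#' @param naive A `galton_glm`.
#' @param spatial A `galton_sglmm` fitted to the same rows and formula.
#' @param focal Focal covariate; default first non-intercept term.
#' @param alpha Significance threshold (default 0.05).
#' @return A `galton_comparison` list; `tidy()` gives a one-row tibble.
#' @export
compare_models <- function(naive, spatial, focal = NULL, alpha = 0.05) {
  stopifnot(inherits(naive, "galton_glm"), inherits(spatial, "galton_sglmm"))
  if (naive$n != spatial$n) abort("Models fitted to different numbers of rows.")
  if (!identical(sort(naive$coefficients$term),
                 sort(spatial$coefficients$term))) {
    abort("Models have different fixed-effect terms.")
  }
  terms <- setdiff(naive$coefficients$term, "(Intercept)")
  focal <- focal %||% terms[1]
  p_n <- naive$coefficients$p.value[naive$coefficients$term == focal]
  p_s <- spatial$coefficients$p.value[spatial$coefficients$term == focal]
  if (length(p_n) != 1 || length(p_s) != 1) {
    abort(paste0("Focal term '", focal, "' missing from a model."))
  }
  verdict <- if (p_n < alpha && p_s < alpha) "spatially_robust"
  else if (p_n < alpha && p_s >= alpha) "explained_by_space"
  else if (p_n >= alpha && p_s < alpha) "space_revealed"
  else "no_association"
  structure(list(focal = focal, alpha = alpha,
                 p_naive = p_n, p_spatial = p_s,
                 aic_naive = naive$aic, aic_spatial = spatial$aic,
                 delta_aic = naive$aic - spatial$aic,
                 delta_beta = spatial$coefficients$estimate[
                   spatial$coefficients$term == focal] -
                   naive$coefficients$estimate[
                     naive$coefficients$term == focal],
                 verdict = verdict),
            class = "galton_comparison")
}

#' @export
print.galton_comparison <- function(x, ...) {
  cat(sprintf("Model comparison for '%s' (alpha = %g):\n", x$focal, x$alpha))
  cat(sprintf("  naive p = %.4g, spatial p = %.4g, dAIC (naive - spatial) = %.2f\n",
              x$p_naive, x$p_spatial, x$delta_aic))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' @export
tidy.galton_comparison <- function(x, ...) {
  tibble::tibble(focal = x$focal, p.naive = x$p_naive, p.spatial = x$p_spatial,
                 aic.naive = x$aic_naive, aic.spatial = x$aic_spatial,
                 delta.aic = x$delta_aic, delta.beta = x$delta_beta,
                 alpha = x$alpha, verdict = x$verdict)
}
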