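#' Build a spatial weights matrix from distances
#'
#' Weights quantify how strongly each pair of observations should count in
#' the autocorrelation cross-product. Schemes:
#' \itemize{
#'   \item `inverse_distance` (default): `w_ij = 1 / max(d_ij, d_floor)`,
#'     the common residual-diagnostic choice; `d_floor` (km) guards
#'     coincident points;
#'   \item `k_nearest`: binary indicator of j being among i's `k` nearest;
#'   \item `kernel`: `w_ij = exp(-d_ij / range_w)`.
#' }
#'
#' @param D Distance matrix in km.
#' @param scheme Weighting scheme.
#' @param k Number of neighbours (`k_nearest`).
#' @param range_w Kernel decay range in km (`kernel`).
#' @param d_floor Minimum distance in km for `inverse_distance`.
#' @param row_standardize Divide each row by its sum?
#' @return An object of class `spatial_weights`: the matrix `W`, its ids, the
#'   scheme, and the Moran sums `S0`, `S1`, `S2`.
#' @export
spatial_weights <- function(D, scheme = c("inverse_distance", "k_nearest",
                                          "kernel"),
                            k = 5, range_w = 1000, d_floor = 1,
                            row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  check_distance_matrix(D)
  n <- nrow(D)
  W <- switch(scheme,
    inverse_distance = 1 / pmax(D, d_floor),
    k_nearest = {
      B <- matrix(0, n, n)
      for (i in seq_len(n)) {
        ord <- order(D[i, -i])
        nb <- seq_len(n)[-i][ord][seq_len(min(k, n - 1))]
        B[i, nb] <- 1
      }
      B
    },
    kernel = exp(-D / range_w)
  )
  diag(W) <- 0
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  if (sum(W) <= 0) abort("All spatial weights are zero.")
  new_spatial_weights(W, ids = rownames(D), scheme = scheme,
                      row_standardized = row_standardize)
}

new_spatial_weights <- function(W, ids = NULL, scheme = "custom",
                                row_standardized = FALSE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) abort("Weights must be square.")
  if (any(W < 0)) abort("Weights must be non-negative.")
  if (any(diag(W) != 0)) abort("Weights diagonal must be zero.")
  if (sum(W) <= 0) abort("All spatial weights are zero.")
  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  structure(list(W = W, ids = ids %||% rownames(W), scheme = scheme,
                 row_standardized = row_standardized,
                 S0 = S0, S1 = S1, S2 = S2),
            class = "spatial_weights")
}

as_spatial_weights <- function(W) {
  if (inherits(W, "spatial_weights")) W else new_spatial_weights(W)
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, scheme = %s%s, S0 = %.4g\n",
              nrow(x$W), x$scheme,
              if (x$row_standardized) " (row-standardized)" else ""), sep = "")
  invisible(x)
}

#' Moran's I autocorrelation test
#'
#' Global Moran's I for a numeric vector under a spatial weights matrix:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`.
#' Null expectation is `-1/(n-1)`. The null variance uses the Cliff-Ord
#' randomization formula (kurtosis-corrected; default), the normality
#' formula, or a Monte-Carlo permutation null. A significant positive z
#' means values cluster in space; a significant negative z means they are
#' over-dispersed.
#'
#' @param x Numeric vector, not constant, length >= 4.
#' @param W A [spatial_weights()] object or a bare weights matrix.
#' @param method `"randomization"`, `"normality"`, or `"permutation"`.
#' @param permutations Number of permutations `B` for
#'   `method = "permutation"`, or `"all"` to enumerate every one of the `n!`
#'   relabelings (n <= 8) and return the exact permutation p value.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (analytic methods; permutation p is two-sided on `|I - E[I]|`).
#' @param seed Optional integer seed for the permutation null.
#' @return A `moran_result`: statistic, expected, sd, z, p, n, method.
#' @examples
#' pts <- tibble::tibble(id = letters[1:6], lon = c(0, 1, 2, 30, 31, 32),
#'                       lat = c(0, 1, 0, 30, 31, 30))
#' W <- spatial_weights(distance_matrix(pts))
#' morans_i(c(1, 1.2, 0.9, 5, 5.3, 4.8), W)
#' @export
morans_i <- function(x, W, method = c("randomization", "normality",
                                      "permutation"),
                     permutations = 999,
                     alternative = c("two.sided", "greater", "less"),
                     seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  W <- as_spatial_weights(W)
  n <- length(x)
  if (n != nrow(W$W)) abort("Length of x does not match weights dimension.")
  if (n < 4) abort("Moran's I requires n >= 4 (randomization variance undefined below).")
  if (!all(is.finite(x))) abort("x contains non-finite values.")
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 <= .Machine$double.eps * n) abort("Moran's I undefined: zero variance in x.")

  I_of <- function(z) (n / W$S0) * drop(crossprod(z, W$W %*% z)) / sum(z^2)
  I_obs <- I_of(z)
  E_I <- -1 / (n - 1)

  if (method == "permutation") {
    if (identical(permutations, "all")) {
      P <- all_permutations(n)
      I_all <- apply(P, 1, function(idx) I_of(z[idx]))
      p <- mean(abs(I_all - E_I) >= abs(I_obs - E_I) - 1e-12)
      permutations <- nrow(P)
    } else {
      if (!is.null(seed)) set.seed(seed)
      B <- as.integer(permutations)
      exceed <- 0L
      for (b in seq_len(B)) {
        if (abs(I_of(z[sample.int(n)]) - E_I) >= abs(I_obs - E_I) - 1e-12) {
          exceed <- exceed + 1L
        }
      }
      p <- (1 + exceed) / (B + 1)
    }
    var_I <- NA_real_
    zscore <- NA_real_
  } else {
    S0 <- W$S0; S1 <- W$S1; S2 <- W$S2
    if (method == "randomization") {
      b2 <- n * sum(z^4) / m2^2
      num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
        b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
      var_I <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - E_I^2
    } else {
      var_I <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E_I^2
    }
    if (var_I <= 0) abort("Non-positive null variance for Moran's I.")
    zscore <- (I_obs - E_I) / sqrt(var_I)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(zscore)),
                greater = pnorm(zscore, lower.tail = FALSE),
                less = pnorm(zscore))
  }
  structure(list(statistic = I_obs, expected = E_I,
                 sd = if (is.na(var_I)) NA_real_ else sqrt(var_I),
                 z = zscore, p = p, n = n, method = method,
                 scheme = W$scheme, permutations = if (method == "permutation")
                   as.integer(permutations) else NA_integer_,
                 alternative = alternative, seed = seed),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I (%s): I = %.4f, E[I] = %.4f, sd = %s, z = %s, p = %.4g, n = %d\n",
              x$method, x$statistic, x$expected,
              if (is.na(x$sd)) "NA" else sprintf("%.4f", x$sd),
              if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
              x$p, x$n))
  invisible(x)
}

#' @export
tidy.moran_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, expected = x$expected, sd = x$sd,
                 z = x$z, p.value = x$p, n = x$n, method = x$method,
                 scheme = x$scheme)
}

#' Serialize an autocorrelation result to JSON
#'
#' Fields: `statistic, expected, sd, z, p, n, method, scheme, seed`.
#'
#' @param x A `moran_result`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @export
moran_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "moran_result"))
  obj <- list(statistic = x$statistic, expected = x$expected, sd = x$sd,
              z = x$z, p = x$p, n = x$n, method = x$method,
              scheme = x$scheme, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Moran's I on the residuals of a fitted model
#'
#' Applies [morans_i()] to a fit's Pearson residuals — the standard
#' diagnostic for spatial autocorrelation left unexplained by the
#' covariates. Residuals must align with the weights' id order.
#'
#' @param fit A model from [fit_glm()] (or [fit_spatial_glmm()]).
#' @param W A [spatial_weights()] object.
#' @inheritParams morans_i
#' @return A `moran_result`.
#' @export
residual_moran <- function(fit, W, method = "randomization", ...) {
  W <- as_spatial_weights(W)
  r <- fit$residuals$pearson
  if (!is.null(fit$ids) && !is.null(W$ids) &&
      !identical(as.character(fit$ids), as.character(W$ids))) {
    abort("Id order mismatch between model residuals and spatial weights.")
  }
  if (length(r) != nrow(W$W)) {
    abort("Residual length does not match weights dimension.")
  }
  if (sd(r) < 1e-10) {
    abort("Residuals are (numerically) constant: Moran's I degenerate for a saturated/perfect fit.")
  }
  morans_i(r, W, method = method, ...)
}

#' Mantel test between two distance/dissimilarity matrices
#'
#' Pearson correlation `r` between the strictly-lower-triangle entries of
#' `A` and `B`, with a permutation null built by jointly permuting the rows
#' and columns of `A`. One-sided (`greater`) by default: the usual question
#' is whether similar values co-occur with spatial proximity.
#'
#' @param A,B Symmetric matrices of identical dimension (and id order).
#' @param permutations Number of matrix permutations, or `"all"` to
#'   enumerate every relabeling (n <= 8; exact p).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @param seed Optional integer seed.
#' @return A `mantel_result` with `r`, `p`, `permutations`, `n`.
#' @export
mantel_test <- function(A, B, permutations = 999,
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.matrix(A) || !is.matrix(B) || !all(dim(A) == dim(B))) {
    abort("A and B must be matrices of identical dimension.")
  }
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8) {
    abort("Mantel inputs must be symmetric.")
  }
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    abort("Id order mismatch between A and B.")
  }
  n <- nrow(A)
  low <- lower.tri(A)
  r_obs <- cor(A[low], B[low])
  hit_fun <- function(r_b) switch(alternative,
                                  greater = r_b >= r_obs - 1e-12,
                                  less = r_b <= r_obs + 1e-12,
                                  two.sided = abs(r_b) >= abs(r_obs) - 1e-12)
  if (identical(permutations, "all")) {
    P <- all_permutations(n)
    r_all <- apply(P, 1, function(idx) cor(A[idx, idx][low], B[low]))
    p <- mean(vapply(r_all, hit_fun, logical(1)))
    B_n <- nrow(P)
  } else {
    if (!is.null(seed)) set.seed(seed)
    B_n <- as.integer(permutations)
    exceed <- 0L
    for (b in seq_len(B_n)) {
      idx <- sample.int(n)
      if (hit_fun(cor(A[idx, idx][low], B[low]))) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (B_n + 1)
  }
  structure(list(r = r_obs, p = p,
                 permutations = B_n, n = n, alternative = alternative,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
              x$r, x$p, x$alternative, x$permutations, x$n))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$r, p.value = x$p,
                 permutations = x$permutations, n = x$n,
                 alternative = x$alternative)
}
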