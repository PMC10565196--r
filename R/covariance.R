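#' Specify a spatial covariance kernel
#'
#' Covariance between two sites a distance `d` km apart is
#' `sigma2 * k(d / range) + nugget * (d == 0 on the diagonal)`, where `k` is
#' the exponential kernel `exp(-d/range)` or a half-integer Matern:
#' \itemize{
#'   \item `nu = 0.5`: identical to the exponential kernel;
#'   \item `nu = 1.5`: `(1 + sqrt(3) d/r) exp(-sqrt(3) d/r)`;
#'   \item `nu = 2.5`: `(1 + sqrt(5) d/r + 5 d^2/(3 r^2)) exp(-sqrt(5) d/r)`.
#' }
#'
#' @param family `"exponential"` or `"matern"`.
#' @param nu Matern smoothness, one of 0.5, 1.5, 2.5.
#' @param sigma2 Marginal (partial-sill) variance, >= 0.
#' @param range Decay range `rho` in km, > 0.
#' @param nugget Variance at zero distance not carried by the field, >= 0.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("exponential", sigma2 = 1, range = 1000)
#' @export
kernel_spec <- function(family = c("exponential", "matern"), nu = 0.5,
                        sigma2 = 1, range = 1000, nugget = 0) {
  family <- match.arg(family)
  if (!nu %in% c(0.5, 1.5, 2.5)) {
    abort("Matern smoothness 'nu' must be one of 0.5, 1.5, 2.5.")
  }
  if (!is.finite(range) || range <= 0) abort("Kernel 'range' must be > 0.")
  if (sigma2 < 0) abort("Kernel 'sigma2' must be >= 0.")
  if (nugget < 0) abort("Kernel 'nugget' must be >= 0.")
  structure(list(family = family, nu = if (family == "exponential") 0.5 else nu,
                 sigma2 = sigma2, range = range, nugget = nugget),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s (nu = %g): sigma2 = %g, range = %g km, nugget = %g\n",
              x$family, x$nu, x$sigma2, x$range, x$nugget))
  invisible(x)
}

# Unit-variance correlation kernel evaluated at distances d (km).
kernel_correlation <- function(d, family, nu, range) {
  s <- d / range
  if (family == "exponential" || nu == 0.5) {
    exp(-s)
  } else if (nu == 1.5) {
    (1 + sqrt(3) * s) * exp(-sqrt(3) * s)
  } else if (nu == 2.5) {
    (1 + sqrt(5) * s + 5 * s^2 / 3) * exp(-sqrt(5) * s)
  } else {
    abort("Unsupported Matern smoothness.")
  }
}

#' Spatial covariance matrix from a distance matrix
#'
#' `Sigma[i, j] = sigma2 * k(d_ij / range) + nugget * I[i == j]`.
#'
#' @param D Distance matrix in km (see [distance_matrix()]).
#' @param spec A [kernel_spec()].
#' @return Covariance matrix with attribute `provenance = "spatial"`.
#' @export
spatial_covariance <- function(D, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  check_distance_matrix(D)
  S <- spec$sigma2 * kernel_correlation(D, spec$family, spec$nu, spec$range)
  S <- S + diag(spec$nugget, nrow(D))
  dimnames(S) <- dimnames(D)
  attr(S, "provenance") <- "spatial"
  S
}

#' Phylogenetic covariance from a tree or hierarchical classification
#'
#' Two sources of relatedness are supported:
#' \itemize{
#'   \item a rooted `phylo` tree with branch lengths (or a Newick file path):
#'     Brownian-motion covariance, `Sigma[i, j]` = shared root-to-tip path
#'     length (via [ape::vcv()]);
#'   \item a hierarchical classification data frame with columns
#'     `taxon, level1, level2, ...` (coarsest group first): `Sigma[i, j]` =
#'     (number of shared nested levels) / (total levels), so the diagonal is 1
#'     and taxa sharing no group have covariance 0. Sharing at level k counts
#'     only if all coarser levels also match.
#' }
#'
#' @param src A `phylo` object, a path to a Newick file, or a classification
#'   data frame.
#' @param ids Character vector giving the required row/column order; every id
#'   must resolve to a tip or classification row.
#' @return Covariance matrix in `ids` order, `provenance = "phylogenetic"`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_covariance(tr, c("A", "B", "C"))
#' @export
phylo_covariance <- function(src, ids) {
  ids <- as.character(ids)
  if (is.character(src) && length(src) == 1 && file.exists(src)) {
    src <- ape::read.tree(src)
  }
  if (inherits(src, "phylo")) {
    if (is.null(src$edge.length)) abort("Tree has no branch lengths.")
    if (any(src$edge.length < 0)) abort("Tree has negative branch lengths.")
    missing <- setdiff(ids, src$tip.label)
    if (length(missing) > 0) {
      abort(paste0("Ids not found in tree: ", paste(missing, collapse = ", ")))
    }
    V <- ape::vcv(src)
    S <- V[ids, ids, drop = FALSE]
  } else if (is.data.frame(src)) {
    S <- classification_covariance(src, ids)
  } else {
    abort("'src' must be a phylo tree, a Newick path, or a classification data frame.")
  }
  dimnames(S) <- list(ids, ids)
  attr(S, "provenance") <- "phylogenetic"
  S
}

classification_covariance <- function(cls, ids) {
  if (ncol(cls) < 2) abort("Classification needs a taxon column plus >= 1 level.")
  taxa <- as.character(cls[[1]])
  missing <- setdiff(ids, taxa)
  if (length(missing) > 0) {
    abort(paste0("Ids not found in classification: ",
                 paste(missing, collapse = ", ")))
  }
  lv <- as.matrix(cls[match(ids, taxa), -1, drop = FALSE])
  L <- ncol(lv)
  n <- length(ids)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- 0L
      for (k in seq_len(L)) {
        if (!is.na(lv[i, k]) && !is.na(lv[j, k]) && lv[i, k] == lv[j, k]) {
          shared <- shared + 1L
        } else {
          break
        }
      }
      S[i, j] <- shared / L
    }
  }
  diag(S) <- 1
  S
}

#' Combine spatial and phylogenetic covariances into a phylospatial matrix
#'
#' Both inputs are rescaled to unit diagonal (correlation scale) so the
#' weights are comparable variance components:
#' `Sigma = sigma2_s * K_s + sigma2_p * K_p + tau2 * I`. With both weights
#' zero the result is independent noise, `tau2 * I`.
#'
#' @param spatial,phylo Covariance matrices with identical id order (row
#'   names); `phylo` may be `NULL` when `sigma2_p = 0`.
#' @param sigma2_s,sigma2_p,tau2 Non-negative variance components.
#' @return Combined covariance matrix, `provenance = "combined"`.
#' @export
combine_covariances <- function(spatial, phylo = NULL, sigma2_s = 1,
                                sigma2_p = 0, tau2 = 0) {
  if (any(c(sigma2_s, sigma2_p, tau2) < 0)) {
    abort("Variance components must be non-negative.")
  }
  n <- nrow(spatial)
  if (!is.null(phylo)) {
    if (!identical(rownames(spatial), rownames(phylo))) {
      abort("Id order mismatch between spatial and phylogenetic matrices.")
    }
  } else if (sigma2_p > 0) {
    abort("sigma2_p > 0 but no phylogenetic matrix supplied.")
  }
  S <- sigma2_s * to_correlation(spatial)
  if (!is.null(phylo) && sigma2_p > 0) S <- S + sigma2_p * to_correlation(phylo)
  S <- S + diag(tau2, n)
  dimnames(S) <- dimnames(spatial)
  attr(S, "provenance") <- "combined"
  S
}

# Rescale a PSD matrix to unit diagonal; a zero-variance row stays zero.
to_correlation <- function(S) {
  d <- sqrt(pmax(diag(S), 0))
  d[d == 0] <- 1
  S / tcrossprod(d)
}
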