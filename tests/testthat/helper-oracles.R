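# Independent oracles used across tests. These are deliberately naive
# implementations (loops, enumeration, generic optimizers) kept separate
# from the package's own code paths.

# Spherical law of cosines distance, km.
slc_distance <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  cosang <- sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(dl)
  R * acos(pmin(pmax(cosang, -1), 1))
}

# Moran's I by explicit double sum.
brute_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Exact permutation p for Moran's I over all n! relabelings.
brute_moran_perm_p <- function(x, W) {
  n <- length(x)
  E <- -1 / (n - 1)
  obs <- brute_moran(x, W)
  perms <- all_perms(n)
  stat <- apply(perms, 1, function(idx) brute_moran(x[idx], W))
  mean(abs(stat - E) >= abs(obs - E) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Exact Mantel permutation p (one-sided greater) by enumeration.
brute_mantel_perm_p <- function(A, B) {
  low <- lower.tri(A)
  obs <- cor(A[low], B[low])
  perms <- all_perms(nrow(A))
  stat <- apply(perms, 1, function(idx) cor(A[idx, idx][low], B[low]))
  mean(stat >= obs - 1e-12)
}

# Generic numerical maximizer of the Bernoulli log-likelihood.
optim_logit <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- drop(X %*% b)
    -drop(crossprod(X, y - plogis(eta)))
  }
  optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-15))$par
}

# A small deterministic geo table spread over two clusters.
toy_geo <- function(n = 8, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("t%02d", 1:n),
    lon = c(runif(ceiling(n / 2), 0, 5), runif(floor(n / 2), 100, 105)),
    lat = c(runif(ceiling(n / 2), 0, 5), runif(floor(n / 2), 40, 45))
  )
}
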