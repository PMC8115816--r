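# Independent oracles used across tests. These re-derive expected results by
# direct, unoptimised computation and never share code with the implementation.

# Weighted least-squares S-Map oracle: explicit design matrix, SVD
# pseudo-inverse with relative cutoff, exponential distance weights.
oracle_smap_one <- function(lib_pts, lib_tgts, q, theta, rcond = 1e-8) {
  d <- sqrt(rowSums(sweep(lib_pts, 2, q)^2))
  dbar <- mean(d)
  w <- if (theta == 0 || dbar == 0) rep(1, length(d)) else exp(-theta * d / dbar)
  sw <- sqrt(w)
  A <- cbind(1, lib_pts) * sw
  B <- as.matrix(lib_tgts) * sw
  sv <- svd(A)
  dinv <- ifelse(sv$d > rcond * max(sv$d), 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% B))
  drop(c(1, q) %*% coef)
}

oracle_smap <- function(lib_pts, lib_tgts, q_pts, theta, rcond = 1e-8) {
  out <- matrix(NA_real_, nrow(q_pts), ncol(as.matrix(lib_tgts)))
  for (i in seq_len(nrow(q_pts)))
    out[i, ] <- oracle_smap_one(lib_pts, lib_tgts, q_pts[i, ], theta, rcond)
  out
}

# Equal-weight ordinary least squares by normal equations (theta = 0 oracle).
oracle_ols <- function(lib_pts, lib_tgts, q_pts) {
  X <- cbind(1, lib_pts)
  coef <- solve(crossprod(X), crossprod(X, as.matrix(lib_tgts)))
  cbind(1, q_pts) %*% coef
}

# Brute-force acceptance oracle for the discontinuous embedding: test every
# candidate lag-0 sample independently.
oracle_accepted_samples <- function(defined, E, tau, Tp, start) {
  n <- length(defined)
  ok <- logical(n)
  for (t in seq_len(n)) {
    if (t < start) next
    lags <- t - (0:(E - 1)) * tau
    tgt <- t + Tp
    if (min(lags) < 1 || tgt > n) next
    ok[t] <- all(defined[lags]) && defined[tgt]
  }
  which(ok)
}

# random embedding instance for oracle-equivalence checks
random_instance <- function(n_lib, n_q, E, K, seed) {
  set.seed(seed)
  D <- E * K
  lib <- delay_embedding(matrix(rnorm(n_lib * D), n_lib, D),
                         matrix(rnorm(n_lib * K), n_lib, K),
                         seq_len(n_lib), E = E, source = "lib")
  qry <- delay_embedding(matrix(rnorm(n_q * D), n_q, D),
                         matrix(rnorm(n_q * K), n_q, K),
                         seq_len(n_q), E = E, source = "qry")
  list(lib = lib, qry = qry)
}

# noise-free limit-cycle series used by several tests
cycle_series <- function(duration_s = 100, dt = 1 / 16, omega = pi,
                         amplitude = 5, noise_sd = 0, seed = 1, ...) {
  generate_series(synthetic_config(duration_s = duration_s, dt = dt,
                                   amplitude = amplitude,
                                   omega_schedule = omega,
                                   noise_sd = noise_sd, seed = seed, ...))
}
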