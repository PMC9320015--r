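# Shared fixtures and independent oracles for the numeric tests.

# A small random problem with kernel and weight matrices precomputed.
rand_instance <- function(m = 5, n = 3, s = 0.8, bandwidth = 1) {
  X <- matrix(rnorm(m * n), m, n)
  y <- rnorm(m)
  km <- kernel_matrix(X, kernel_spec(bandwidth = bandwidth))
  W <- suppressWarnings(locality_weights(X, s))
  list(X = X, y = y, K = km$K, W = W, km = km, m = m, n = n)
}

# Brute-force triple-loop residual matrix: A[i,j] = yi - yj +
# sum_p K(xp, xi) (xj - xi)' cp.  Deliberately naive.
residual_oracle <- function(C, K, X, y) {
  m <- nrow(X)
  A <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    acc <- y[i] - y[j]
    for (p in seq_len(m))
      acc <- acc + K[p, i] * sum((X[j, ] - X[i, ]) * C[p, ])
    A[i, j] <- acc
  }
  diag(A) <- 0
  A
}

# Double-loop quadratic form: sum_i sum_j K[i,j] <ci, cj>.
rkhs_oracle <- function(C, K) {
  m <- nrow(C)
  tot <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    tot <- tot + K[i, j] * sum(C[i, ] * C[j, ])
  tot
}

# Central finite differences of the full regularized objective.
fd_gradient <- function(C, K, W, X, y, t, lambda, h = 1e-6) {
  G <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
    Cp <- C; Cp[i, j] <- Cp[i, j] + h
    Cm <- C; Cm[i, j] <- Cm[i, j] - h
    G[i, j] <- (tgl_objective(Cp, K, W, X, y, t, lambda) -
                  tgl_objective(Cm, K, W, X, y, t, lambda)) / (2 * h)
  }
  G
}

# Numeric Hessian of the objective from central differences of the
# analytic gradient, in the stacked (row-major) coefficient layout.
num_hessian <- function(C, K, W, X, y, t, lambda, h = 1e-5) {
  m <- nrow(C); n <- ncol(C); p <- m * n
  gv <- function(v) {
    Cm <- matrix(v, m, n, byrow = TRUE)
    as.vector(t(risk_gradient(Cm, K, W, X, y, t) +
                  lambda * regularizer_gradient(Cm, K)))
  }
  v0 <- as.vector(t(C))
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    H[, j] <- (gv(v0 + e) - gv(v0 - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Frozen settings of the replicated selection study.
study_control <- function() tgl_control()

cauchy_cell <- function(frac, t, correlated = FALSE, reps = 30L, base_seed = 0L) {
  run_cell(list(m = 50, n = 50, nn = 30, noise = "cauchy",
                outlier_fraction = frac, correlated = correlated),
           t = t, reps = reps, base_seed = base_seed,
           control = study_control())
}
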