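#' Sparse sinusoidal weight vector
#'
#' Ground-truth linear coefficients of the synthetic benchmarks:
#' \eqn{w_l = 2 + 0.5 \sin(2\pi l / 10)} for \eqn{l = 1, \ldots, nn}
#' (1-based) and zero beyond, so the true support is exactly the first
#' `nn` coordinates and every supported weight lies in `[1.5, 2.5]`.
#'
#' @param n total number of variables; `nn` size of the support.
#' @return numeric vector of length `n`.
#' @export
sim_weights <- function(n, nn) {
  if (nn > n) stop("'nn' must not exceed 'n'", call. = FALSE)
  l <- seq_len(n)
  ifelse(l <= nn, 2 + 0.5 * sin(2 * pi * l / 10), 0)
}

#' Gaussian design matrix
#'
#' Rows i.i.d. \eqn{N(0, I_n)} or, with `correlated = TRUE`,
#' \eqn{N(0, \Sigma)} with AR(1)-type covariance
#' \eqn{\Sigma_{lp} = 0.5^{|l - p|}} (sampled through the Cholesky
#' factor).  Draws from the current RNG state.
#'
#' @param m,n dimensions.
#' @param correlated logical.
#' @return m x n matrix.
#' @export
sim_design <- function(m, n, correlated = FALSE) {
  Z <- matrix(rnorm(m * n), m, n)
  if (!correlated) return(Z)
  Sigma <- 0.5^abs(outer(seq_len(n), seq_len(n), "-"))
  Z %*% chol(Sigma)
}

#' Noise draws for the synthetic benchmarks
#'
#' Three families: `"cauchy"` with location 2 and scale 4 (heavy tails,
#' no moments), `"chisq"` as \eqn{0.01 \chi^2_5} (skewed, positive, mean
#' 0.05, not centered), and `"gaussian"` as \eqn{N(0, 0.3)} with 0.3
#' read as the variance.  Draws from the current RNG state.
#'
#' @param kind `"cauchy"`, `"chisq"` or `"gaussian"`.
#' @param m number of draws.
#' @return numeric vector of length `m`.
#' @export
sim_noise <- function(kind = c("cauchy", "chisq", "gaussian"), m) {
  kind <- match.arg(kind)
  switch(kind,
    cauchy = rcauchy(m, location = 2, scale = 4),
    chisq = 0.01 * rchisq(m, df = 5),
    gaussian = rnorm(m, 0, sqrt(0.3)))
}

#' Outlier contamination
#'
#' Replaces a uniformly chosen subset of `floor(fraction * m)` noise
#' entries by independent \eqn{N(0, 100)} draws (variance 100, i.e.
#' standard deviation 10) — the classical replacement contamination
#' model.  Draws from the current RNG state.
#'
#' @param eps numeric noise vector.
#' @param fraction contamination fraction in `[0, 1)`.
#' @return list with `eps` (contaminated vector) and `which` (replaced
#'   positions, possibly empty).
#' @export
contaminate <- function(eps, fraction) {
  if (fraction < 0 || fraction >= 1)
    stop("'fraction' must be in [0, 1)", call. = FALSE)
  m <- length(eps)
  k <- floor(fraction * m)
  if (k == 0L) return(list(eps = eps, which = integer(0)))
  idx <- sample.int(m, k)
  eps[idx] <- rnorm(k, 0, 10)
  list(eps = eps, which = sort(idx))
}

#' Generate a synthetic variable-selection benchmark
#'
#' Draws one dataset from the linear model \eqn{y_i = x_i \cdot w +
#' \epsilon_i} with the sparse sinusoidal weights of [sim_weights()],
#' a Gaussian design ([sim_design()]), one of three noise families
#' ([sim_noise()]), and optional replacement contamination by
#' \eqn{N(0, 100)} outliers ([contaminate()]).  Fully deterministic
#' given `seed`.
#'
#' @param m samples; `n` variables; `nn` support size.
#' @param noise `"cauchy"`, `"chisq"`, `"gaussian"`, or `"none"` (a
#'   noise-free variant for testing: `y = X w` exactly).
#' @param outlier_fraction fraction of noise entries replaced by
#'   high-variance Gaussian outliers.
#' @param correlated use the AR(1)-correlated design.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `"tgl_sim"`: list with `X`, `y`, `w`,
#'   `support` (`1:nn`), `outliers` (replaced positions) and `spec`.
#' @examples
#' sim <- tgl_sim(m = 50, n = 50, nn = 30, noise = "cauchy",
#'                outlier_fraction = 0.2, seed = 7)
#' dim(sim$X)
#' @export
tgl_sim <- function(m = 50, n = 50, nn = 30,
                    noise = c("cauchy", "chisq", "gaussian", "none"),
                    outlier_fraction = 0, correlated = FALSE, seed = NULL) {
  noise <- match.arg(noise)
  if (m < 2) stop("'m' must be at least 2", call. = FALSE)
  if (nn > n) stop("'nn' must not exceed 'n'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- sim_weights(n, nn)
  X <- sim_design(m, n, correlated)
  eps <- if (noise == "none") numeric(m) else sim_noise(noise, m)
  cont <- contaminate(eps, outlier_fraction)
  y <- as.numeric(X %*% w) + cont$eps
  structure(list(X = X, y = y, w = w, support = seq_len(nn),
                 outliers = cont$which,
                 spec = list(m = m, n = n, nn = nn, noise = noise,
                             outlier_fraction = outlier_fraction,
                             correlated = correlated, seed = seed)),
            class = "tgl_sim")
}

#' @export
print.tgl_sim <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Synthetic benchmark: m = %d, n = %d, support 1:%d\n", s$m, s$n, s$nn))
  cat(sprintf("  noise: %s, outliers: %g%% (%d replaced), design: %s\n",
              s$noise, 100 * s$outlier_fraction, length(x$outliers),
              if (s$correlated) "AR(1)-correlated" else "independent"))
  if (!is.null(s$seed)) cat(sprintf("  seed: %d\n", s$seed))
  invisible(x)
}
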