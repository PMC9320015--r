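#' Pairwise Taylor residual matrix
#'
#' For a coefficient matrix `C` (row i is the expansion coefficient
#' \eqn{c_i \in R^n} of the gradient field \eqn{\vec f = \sum_i c_i
#' K(x_i, \cdot)}), the (i, j) residual is the first-order expansion
#' error \deqn{A_{ij} = y_i - y_j + \vec f(x_i)^\top (x_j - x_i),}
#' where \eqn{\vec f(x_i) = \sum_p K(x_p, x_i) c_p}.  The diagonal is
#' identically zero.
#'
#' @param C m x n coefficient matrix.
#' @param K m x m kernel Gram matrix.
#' @param X m x n design matrix.
#' @param y response vector of length m.
#' @return m x m residual matrix.
#' @export
residual_matrix <- function(C, K, X, y) {
  m <- nrow(X)
  stopifnot(is.matrix(C), nrow(C) == m, ncol(C) == ncol(X),
            is.matrix(K), nrow(K) == m, ncol(K) == m, length(y) == m)
  F <- K %*% C                       # row i = field at x_i
  A <- outer(y, y, "-") + tcrossprod(F, X) - rowSums(F * X)
  diag(A) <- 0
  A
}

#' Weighted pairwise squared losses
#'
#' Entrywise \eqn{V_{ij} = \omega_{ij} A_{ij}^2}: the locality-weighted
#' squared Taylor residual of each sample pair.
#'
#' @param A residual matrix from [residual_matrix()].
#' @param W locality weight matrix from [locality_weights()].
#' @return m x m nonnegative loss matrix with zero diagonal.
#' @export
pair_loss_matrix <- function(A, W) {
  stopifnot(is.matrix(A), is.matrix(W), all(dim(A) == dim(W)))
  if (any(W < 0)) stop("locality weights must be nonnegative", call. = FALSE)
  W * A * A
}

# Below this threshold on |t| the tilted aggregate switches to its
# zero-tilt (plain mean) limit to avoid cancellation in log(1 + t*mean)/t.
T_SWITCH <- 1e-8

#' Tilted empirical risk
#'
#' The exponentially tilted aggregate of the pair losses,
#' \deqn{E(t) = \frac1t \log \frac{1}{m^2} \sum_{i,j} e^{t V_{ij}},}
#' computed through a max-shifted log-sum-exp so it never overflows.  For
#' \eqn{|t|} below `1e-8` the plain mean \eqn{\frac{1}{m^2}\sum V_{ij}}
#' (the untilted limit) is returned.  Negative `t` damps large losses
#' (robustness); positive `t` amplifies them.
#'
#' @param V nonnegative loss matrix (or any numeric array of losses).
#' @param t tilt parameter; `0` gives the plain mean.
#' @return scalar risk.
#' @examples
#' V <- matrix(c(0, 2, 2, 0), 2)
#' tilted_risk(V, 1)  # log((1 + exp(2))/2)
#' @export
tilted_risk <- function(V, t) {
  if (any(!is.finite(V))) stop("'V' contains non-finite entries", call. = FALSE)
  if (abs(t) < T_SWITCH) return(mean(V))
  tv <- t * V
  mx <- max(tv)
  (mx + log(mean(exp(tv - mx)))) / t
}

#' Tilt weights
#'
#' The effective per-pair influence under the tilted risk,
#' \deqn{\Phi_{ij} = \exp\{t (V_{ij} - E(t))\} =
#'   \frac{e^{t V_{ij}}}{\frac{1}{m^2}\sum_{k,l} e^{t V_{kl}}},}
#' a positive matrix whose mean over all \eqn{m^2} pairs is exactly one.
#' At `t = 0` every weight is one (ordinary empirical risk).
#'
#' @inheritParams tilted_risk
#' @return matrix of the same shape as `V`, entrywise positive, mean 1.
#' @export
tilt_weights <- function(V, t) {
  if (any(!is.finite(V))) stop("'V' contains non-finite entries", call. = FALSE)
  if (abs(t) < T_SWITCH) return(array(1, dim = dim(V)))
  tv <- t * V
  mx <- max(tv)
  e <- exp(tv - mx)
  e / mean(e)
}

#' Gradient of the tilted risk in the expansion coefficients
#'
#' Analytic gradient of [tilted_risk()] composed with the pair-loss
#' construction, as an m x n matrix whose row p is
#' \deqn{\frac{1}{m^2} \sum_{i,j} \Phi_{ij} \, 2\, \omega_{ij} A_{ij}
#'   \, K(x_p, x_i) (x_j - x_i).}
#' Row-major flattening (rows of the output stacked in order) gives the
#' gradient with respect to the stacked coefficient vector
#' \eqn{(c_1^\top, \ldots, c_m^\top)^\top}.
#'
#' @inheritParams residual_matrix
#' @param W locality weight matrix.
#' @param t tilt parameter.
#' @return m x n gradient matrix.
#' @export
risk_gradient <- function(C, K, W, X, y, t) {
  m <- nrow(X)
  A <- residual_matrix(C, K, X, y)
  V <- pair_loss_matrix(A, W)
  Phi <- tilt_weights(V, t)
  S <- 2 * Phi * W * A
  B <- S %*% X - rowSums(S) * X
  (K %*% B) / m^2
}

#' Squared RKHS norm of the fitted gradient field
#'
#' Total \eqn{\|\vec f\|_K^2 = \mathrm{tr}(C^\top K C)} together with the
#' per-coordinate norms \eqn{\|f^l\|_K^2 = c^{l\top} K c^l} (column l of
#' `C`), whose shares define the relevance ranking.
#'
#' @param C m x n coefficient matrix.
#' @param K m x m kernel Gram matrix (positive semidefinite).
#' @param tol tolerance for declaring `K` numerically indefinite.
#' @return list with `total` (scalar) and `by_coordinate` (length-n
#'   vector summing to `total`).
#' @export
rkhs_norm_sq <- function(C, K, tol = 1e-8) {
  stopifnot(is.matrix(C), is.matrix(K), nrow(C) == nrow(K))
  v <- colSums(C * (K %*% C))
  scale <- max(1, abs(v))
  if (min(v) < -tol * scale)
    stop(sprintf("negative squared norm (%.3e): kernel matrix is indefinite",
                 min(v)), call. = FALSE)
  v <- pmax(v, 0)
  list(total = sum(v), by_coordinate = v)
}

#' Gradient of the squared RKHS norm
#'
#' \eqn{\nabla_C \|\vec f\|_K^2 = 2 K C} (row p equals
#' \eqn{2 \sum_i K(x_i, x_p) c_i^\top}).
#'
#' @inheritParams rkhs_norm_sq
#' @return m x n matrix.
#' @export
regularizer_gradient <- function(C, K) {
  stopifnot(is.matrix(C), is.matrix(K), nrow(C) == nrow(K))
  2 * (K %*% C)
}

#' Regularized tilted objective
#'
#' \eqn{L(C, t) = E(t) + \lambda \|\vec f\|_K^2}: the quantity the
#' solver minimizes.
#'
#' @inheritParams risk_gradient
#' @param lambda positive regularization parameter.
#' @return scalar objective value.
#' @export
tgl_objective <- function(C, K, W, X, y, t, lambda) {
  if (lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  A <- residual_matrix(C, K, X, y)
  V <- pair_loss_matrix(A, W)
  tilted_risk(V, t) + lambda * rkhs_norm_sq(C, K)$total
}
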