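#' Plug-in bound constants for the convergence theory
#'
#' Empirical stand-ins for the boundedness constants the step-size theory
#' assumes: `M` bounds the responses, `MX` the design row norms, `CK` the
#' squared norm of the fitted field on the sample, `kappa` the kernel
#' diagonal, and `beta_min`/`beta_max` the extreme Gram eigenvalues.
#'
#' @param X design matrix; `y` response vector.
#' @param km a `"tgl_kernel"` object from [kernel_matrix()].
#' @param C optional current coefficient matrix used to evaluate the
#'   field-norm bound `CK`; if missing, `CK = 1`.
#' @return list of class `"tgl_constants"` with elements `M`, `MX`, `CK`,
#'   `kappa`, `beta_min`, `beta_max`.
#' @export
estimate_constants <- function(X, y, km, C = NULL) {
  CK <- 1
  if (!is.null(C)) {
    F <- km$K %*% C
    CK <- max(rowSums(F * F))
  }
  structure(list(M = max(abs(y)), MX = max(sqrt(rowSums(X * X))),
                 CK = CK, kappa = km$kappa,
                 beta_min = km$beta_min, beta_max = km$beta_max),
            class = "tgl_constants")
}

#' Strong-convexity and smoothness constants of the tilted objective
#'
#' Evaluates the two-sided Hessian eigenvalue bounds
#' \deqn{\mu = \min\{2 n \lambda \beta_{\min} + 128\, t\, (M^2 + C_K M_X)
#'   M_X^2\, m\, \kappa^4,\; 2 n \lambda \beta_{\min}\}}
#' \deqn{\gamma = \max\{128\, t\, (M^2 + C_K M_X) M_X^2\, m\, \kappa^4 +
#'   2 n \lambda \beta_{\max},\; 2 \kappa^4 M_X^2 + 2 n \lambda
#'   \beta_{\max}\}}
#' which give the fixed step size \eqn{1/\gamma} and the linear rate
#' \eqn{(1 - \mu/\gamma)^k}.  `mu` may be nonpositive when the tilt is
#' too negative; see [convexity_threshold()].
#'
#' @param t tilt parameter; `lambda` regularization; `n` number of
#'   variables; `m` number of samples.
#' @param consts a `"tgl_constants"` object from [estimate_constants()].
#' @return list with `mu` and `gamma`.
#' @export
convexity_constants <- function(t, lambda, n, m, consts) {
  if (lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  tilt_term <- 128 * t * (consts$M^2 + consts$CK * consts$MX) *
    consts$MX^2 * m * consts$kappa^4
  mu <- min(2 * n * lambda * consts$beta_min + tilt_term,
            2 * n * lambda * consts$beta_min)
  gamma <- max(tilt_term + 2 * n * lambda * consts$beta_max,
               2 * consts$kappa^4 * consts$MX^2 +
                 2 * n * lambda * consts$beta_max)
  list(mu = mu, gamma = gamma)
}

#' Most negative tilt preserving strong convexity
#'
#' The threshold \eqn{t_{\min} = -n \lambda \beta_{\min} / (64 (M^2 + C_K
#' M_X) M_X^2 m \kappa^4)}; the objective is provably strongly convex
#' (\eqn{\mu > 0}) for every tilt above it.  Always negative.
#'
#' @inheritParams convexity_constants
#' @return scalar threshold (negative).
#' @export
convexity_threshold <- function(lambda, n, m, consts) {
  den <- 64 * (consts$M^2 + consts$CK * consts$MX) * consts$MX^2 * m *
    consts$kappa^4
  if (den <= 0)
    stop("degenerate bounds: threshold denominator is not positive",
         call. = FALSE)
  -n * lambda * consts$beta_min / den
}
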