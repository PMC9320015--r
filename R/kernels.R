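#' Kernel specification
#'
#' Describes the Mercer kernel used for the RKHS expansion of the gradient
#' field.  The Gaussian radial basis kernel is the default throughout the
#' package; its bandwidth, when not given, is set by the median heuristic
#' (median pairwise Euclidean distance of the design).
#'
#' @param family one of `"gaussian_rbf"`, `"linear"`, `"polynomial"`.
#' @param bandwidth positive bandwidth of the Gaussian kernel
#'   \eqn{K(x, x') = \exp(-\|x - x'\|^2 / (2 h^2))}; `NULL` requests the
#'   median heuristic at fit time.
#' @param degree,offset polynomial kernel parameters,
#'   \eqn{K(x, x') = (x^\top x' + \mathrm{offset})^{\mathrm{degree}}}.
#' @return an object of class `"kernel_spec"`.
#' @examples
#' kernel_spec("gaussian_rbf", bandwidth = 1)
#' @export
kernel_spec <- function(family = c("gaussian_rbf", "linear", "polynomial"),
                        bandwidth = NULL, degree = 2L, offset = 1) {
  family <- match.arg(family)
  if (!is.null(bandwidth)) {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1L || !is.finite(bandwidth) ||
        bandwidth <= 0)
      stop("'bandwidth' must be a single positive number", call. = FALSE)
  }
  if (family == "polynomial") {
    if (degree < 1) stop("'degree' must be >= 1", call. = FALSE)
  }
  structure(list(family = family, bandwidth = bandwidth,
                 degree = as.integer(degree), offset = offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
    gaussian_rbf = paste0("bandwidth = ",
                          if (is.null(x$bandwidth)) "median heuristic"
                          else format(x$bandwidth)),
    linear = "",
    polynomial = paste0("degree = ", x$degree, ", offset = ", format(x$offset)))
  cat("Kernel: ", x$family, if (nzchar(extra)) paste0(" (", extra, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Median-heuristic bandwidth
#'
#' Median of the pairwise Euclidean distances between the rows of `X`
#' (zero distances excluded so duplicated rows cannot collapse the
#' bandwidth to zero).
#'
#' @param X numeric design matrix, samples in rows.
#' @return a positive scalar.
#' @export
median_bandwidth <- function(X) {
  d <- as.vector(dist(X))
  d <- d[d > 0]
  if (length(d) == 0L) return(1)
  stats::median(d)
}

check_design <- function(X, what = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop("'", what, "' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(X)))
    stop("'", what, "' contains non-finite entries", call. = FALSE)
  invisible(X)
}

sq_dist <- function(X, X2 = NULL) {
  # pairwise squared Euclidean distances, clamped at zero
  if (is.null(X2)) X2 <- X
  n1 <- rowSums(X * X)
  n2 <- rowSums(X2 * X2)
  d2 <- outer(n1, n2, "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  d2
}

#' Kernel Gram matrix with spectral summaries
#'
#' Evaluates the kernel on all sample pairs and reports the quantities the
#' convergence theory needs: \eqn{\kappa = \max_i K(x_i, x_i)} and the
#' extreme eigenvalues of the Gram matrix.
#'
#' @param X numeric matrix (m samples by n variables).
#' @param spec a [kernel_spec()]; a `NULL` bandwidth is resolved by the
#'   median heuristic on `X`.
#' @param tol tolerance on negative eigenvalues before a positive
#'   semidefinite family is declared numerically indefinite.
#' @return a list of class `"tgl_kernel"` with elements `K` (m x m Gram
#'   matrix), `kappa`, `beta_min`, `beta_max`, and the resolved `spec`.
#' @examples
#' X <- matrix(c(0, 1, 2), ncol = 1)
#' km <- kernel_matrix(X, kernel_spec(bandwidth = 1))
#' km$K[1, 2]  # exp(-1/2)
#' @export
kernel_matrix <- function(X, spec = kernel_spec(), tol = 1e-8) {
  check_design(X)
  if (!inherits(spec, "kernel_spec")) stop("'spec' must be a kernel_spec")
  if (spec$family == "gaussian_rbf" && is.null(spec$bandwidth))
    spec$bandwidth <- median_bandwidth(X)
  K <- switch(spec$family,
    gaussian_rbf = exp(-sq_dist(X) / (2 * spec$bandwidth^2)),
    linear = tcrossprod(X),
    polynomial = (tcrossprod(X) + spec$offset)^spec$degree)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tol * scale)
    stop(sprintf("kernel matrix is numerically indefinite (eigenvalue %.3e)",
                 min(ev)), call. = FALSE)
  structure(list(K = K, kappa = max(diag(K)),
                 beta_min = max(min(ev), 0), beta_max = max(ev),
                 spec = spec),
            class = "tgl_kernel")
}

#' Cross-kernel between new points and the sample
#'
#' @param X training design (m x n); `Xnew` query points (m' x n).
#' @param spec a fully resolved [kernel_spec()] (bandwidth set).
#' @return m' x m matrix with entries \eqn{K(x'_a, x_i)}.
#' @keywords internal
cross_kernel <- function(Xnew, X, spec) {
  switch(spec$family,
    gaussian_rbf = exp(-sq_dist(Xnew, X) / (2 * spec$bandwidth^2)),
    linear = tcrossprod(Xnew, X),
    polynomial = (tcrossprod(Xnew, X) + spec$offset)^spec$degree)
}

#' Gaussian locality weights
#'
#' Pairwise weights \eqn{\omega(x_i, x_j) = s^{-(n+2)}
#' \exp(-\|x_i-x_j\|^2 / (2 s^2))} that localize the first-order Taylor
#' expansion of the pair loss.  By default the raw matrix is rescaled so
#' the mean over all \eqn{m^2} entries is one: the raw prefactor
#' \eqn{s^{-(n+2)}} overflows for moderate dimension and would make the
#' scale of the tilt parameter dataset-dependent, whereas mean-one
#' weights give losses (and hence the tilt) a stable, dimension-free
#' scale.  Only the relative weighting of pairs affects the minimizer of
#' the untilted objective; under tilting a global rescale is equivalent
#' to rescaling the tilt.
#'
#' @param X numeric matrix (m x n).
#' @param s positive locality bandwidth.  Values above 1 fall outside the
#'   range the locality analysis assumes and trigger a warning (the
#'   weights remain well defined).
#' @param normalize logical; rescale so the mean entry is 1 (default).
#' @return m x m symmetric, strictly positive weight matrix.
#' @examples
#' W <- locality_weights(matrix(c(0, 1), ncol = 1), s = 0.5,
#'                       normalize = FALSE)
#' W[1, 1]  # 0.5^-3 = 8
#' @export
locality_weights <- function(X, s, normalize = TRUE) {
  check_design(X)
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("'s' must be a single positive number", call. = FALSE)
  if (s > 1)
    warning("locality bandwidth s > 1 lies outside the assumed range (0, 1]",
            call. = FALSE)
  n <- ncol(X)
  E <- exp(-sq_dist(X) / (2 * s^2))
  if (normalize) {
    W <- E / mean(E)
  } else {
    W <- s^(-(n + 2)) * E
  }
  (W + t(W)) / 2
}
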