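#' Fit a tilted gradient learning model
#'
#' Estimates the gradient field \eqn{\vec f(x) = \sum_i c_i K(x_i, x)} of
#' an unknown regression function by minimizing the tilted pairwise
#' objective \deqn{L(C, t) = \frac1t \log \frac{1}{m^2} \sum_{i,j}
#' e^{t\, \omega_{ij} (y_i - y_j + \vec f(x_i)^\top (x_j - x_i))^2}
#' + \lambda \|\vec f\|_K^2} by gradient descent from \eqn{C = 0}.  A
#' negative tilt `t` downweights high-loss pairs, which protects the
#' coordinate relevance ranking against heavy-tailed noise and outliers;
#' `t = 0` is ordinary (untilted) gradient learning.
#'
#' With `step_rule = "backtracking"` (default) the step size is chosen by
#' Armijo line search.  With `step_rule = "theorem"` the fixed step
#' \eqn{1/\gamma} from [convexity_constants()] is used, provided the
#' strong-convexity condition `t > convexity_threshold(...)` holds;
#' otherwise the fit falls back to backtracking with a warning.  Either
#' way the objective trace is monitored and any increasing step is
#' rejected and retried at half the size.
#'
#' @param x numeric design matrix (m samples by n variables), or a data
#'   frame of numeric columns.
#' @param y numeric response vector of length m.
#' @param t tilt parameter (0 = untilted empirical risk).
#' @param lambda positive RKHS regularization parameter.
#' @param s locality bandwidth of the pair weights; `NULL` uses the
#'   median pairwise distance of `x`.
#' @param kernel a [kernel_spec()]; default Gaussian RBF with
#'   median-heuristic bandwidth.
#' @param normalize_weights rescale locality weights to mean one
#'   (default; see [locality_weights()]).
#' @param step_rule `"backtracking"` or `"theorem"`.
#' @param max_iter maximum number of gradient iterations.
#' @param tol relative objective-change stopping threshold.
#' @param verbose print progress every 100 iterations.
#' @return an object of class `"tgl"`: a list with components
#'   `coefficients` (m x n matrix `C`), `objective_trace`, `step_size`,
#'   `mu`, `gamma`, `constants`, `converged`, `n_iter`, `kernel`
#'   (resolved spec), plus the training data and settings.
#' @seealso [relevance()] for ranking variables from a fit, [tgl_exact()]
#'   for the closed-form untilted solution, [tgl_sim()] for synthetic
#'   benchmarks.
#' @examples
#' sim <- tgl_sim(m = 20, n = 5, nn = 3, noise = "gaussian", seed = 1)
#' fit <- tgl(sim$X, sim$y, t = 0, max_iter = 200)
#' fit
#' relevance(fit)
#' @export
tgl <- function(x, y, t = 0, lambda = 1e-3, s = NULL,
                kernel = kernel_spec(), normalize_weights = TRUE,
                step_rule = c("backtracking", "theorem"),
                max_iter = 5000L, tol = 1e-8, verbose = FALSE) {
  cl <- match.call()
  step_rule <- match.arg(step_rule)
  if (is.data.frame(x)) x <- as.matrix(x)
  check_design(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (any(!is.finite(y))) stop("'y' contains non-finite entries", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least two samples", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  if (max_iter < 1L) stop("'max_iter' must be >= 1", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)

  m <- nrow(x); n <- ncol(x)
  km <- kernel_matrix(x, kernel)
  if (is.null(s)) s <- median_bandwidth(x)
  W <- suppressWarnings(locality_weights(x, s, normalize = normalize_weights))

  consts <- estimate_constants(x, y, km)
  cc <- convexity_constants(t, lambda, n, m, consts)
  t_min <- convexity_threshold(lambda, n, m, consts)

  used_rule <- step_rule
  if (step_rule == "theorem" && t <= t_min) {
    warning(sprintf(
      "tilt t = %g is below the strong-convexity threshold %.3g; %s",
      t, t_min, "falling back to backtracking line search"), call. = FALSE)
    used_rule <- "backtracking"
  }

  res <- tgl_descent(km$K, W, x, y, t, lambda,
                     rule = used_rule, gamma = cc$gamma,
                     max_iter = as.integer(max_iter), tol = tol,
                     verbose = verbose)

  structure(list(coefficients = res$C,
                 objective_trace = res$trace,
                 step_size = res$step_size,
                 mu = cc$mu, gamma = cc$gamma, t_min = t_min,
                 constants = consts,
                 converged = res$converged, n_iter = res$n_iter,
                 safeguard_halvings = res$halvings,
                 t = t, lambda = lambda, s = s,
                 normalize_weights = normalize_weights,
                 step_rule = used_rule, tol = tol, max_iter = max_iter,
                 kernel = km$spec, K = km$K, W = W, X = x, y = y,
                 call = cl),
            class = "tgl")
}

# Gradient descent engine on the tilted objective.  Shared by both step
# rules; every accepted step must not increase the objective (theorem
# mode halves the step on an increase, backtracking enforces Armijo).
tgl_descent <- function(K, W, X, y, t, lambda, rule, gamma,
                        max_iter, tol, verbose = FALSE) {
  m <- nrow(X); n <- ncol(X)
  C <- matrix(0, m, n)
  obj <- function(C) {
    A <- residual_matrix(C, K, X, y)
    tilted_risk(pair_loss_matrix(A, W), t) +
      lambda * sum(colSums(C * (K %*% C)))
  }
  grad <- function(C) {
    risk_gradient(C, K, W, X, y, t) + lambda * regularizer_gradient(C, K)
  }
  L <- obj(C)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- L
  converged <- FALSE
  halvings <- 0L
  alpha <- if (rule == "theorem") 1 / gamma else 1
  for (k in seq_len(max_iter)) {
    G <- grad(C)
    gnorm2 <- sum(G * G)
    if (!is.finite(L) || any(!is.finite(G)))
      stop(sprintf("non-finite objective or gradient at iteration %d", k),
           call. = FALSE)
    if (rule == "theorem") {
      repeat {
        C_new <- C - alpha * G
        L_new <- obj(C_new)
        if (L_new <= L || alpha < .Machine$double.eps) break
        alpha <- alpha / 2           # safeguard: plug-in gamma too small
        halvings <- halvings + 1L
      }
    } else {
      alpha <- min(alpha * 2, 1e6)   # warm-started Armijo search
      repeat {
        C_new <- C - alpha * G
        L_new <- obj(C_new)
        if (L_new <= L - 1e-4 * alpha * gnorm2 || alpha < .Machine$double.eps)
          break
        alpha <- alpha / 2
      }
    }
    rel <- abs(L - L_new) / max(1, abs(L))
    C <- C_new
    L <- L_new
    trace[k + 1L] <- L
    if (verbose && k %% 100L == 0L)
      message(sprintf("iter %5d  objective %.8g  step %.3g", k, L, alpha))
    if (rel < tol) { converged <- TRUE; break }
  }
  n_iter <- if (converged) k else max_iter
  list(C = C, trace = trace[seq_len(n_iter + 1L)], converged = converged,
       n_iter = n_iter, step_size = alpha, halvings = halvings)
}

#' Closed-form untilted solution
#'
#' At `t = 0` the objective is an explicit positive-definite quadratic in
#' the stacked coefficients, so the minimizer solves a single
#' \eqn{mn \times mn} linear system.  The system matrix is assembled by
#' probing the (affine) analytic gradient on coordinate directions; the
#' result serves as an exact oracle for the iterative solver.
#'
#' @inheritParams tgl
#' @param max_size guard on the dense system dimension `m * n`.
#' @return an object of class `"tgl"` (with `n_iter = 0` and a length-1
#'   objective trace at the solution).
#' @export
tgl_exact <- function(x, y, lambda = 1e-3, s = NULL,
                      kernel = kernel_spec(), normalize_weights = TRUE,
                      max_size = 5000L) {
  cl <- match.call()
  if (is.data.frame(x)) x <- as.matrix(x)
  check_design(x)
  y <- as.numeric(y)
  m <- nrow(x); n <- ncol(x)
  if (m * n > max_size)
    stop(sprintf("dense solve of size %d exceeds guard %d", m * n, max_size),
         call. = FALSE)
  km <- kernel_matrix(x, kernel)
  if (is.null(s)) s <- median_bandwidth(x)
  W <- suppressWarnings(locality_weights(x, s, normalize = normalize_weights))

  grad_vec <- function(v) {
    C <- matrix(v, m, n, byrow = TRUE)
    G <- risk_gradient(C, km$K, W, x, y, t = 0) +
      lambda * regularizer_gradient(C, km$K)
    as.vector(t(G))
  }
  p <- m * n
  g0 <- grad_vec(numeric(p))
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- 1
    H[, j] <- grad_vec(e) - g0
  }
  H <- (H + t(H)) / 2
  v <- -solve(H, g0)
  C <- matrix(v, m, n, byrow = TRUE)
  L <- tgl_objective(C, km$K, W, x, y, t = 0, lambda = lambda)
  consts <- estimate_constants(x, y, km, C)
  cc <- convexity_constants(0, lambda, n, m, consts)

  structure(list(coefficients = C, objective_trace = L,
                 step_size = NA_real_, mu = cc$mu, gamma = cc$gamma,
                 t_min = convexity_threshold(lambda, n, m, consts),
                 constants = consts, converged = TRUE, n_iter = 0L,
                 safeguard_halvings = 0L,
                 t = 0, lambda = lambda, s = s,
                 normalize_weights = normalize_weights,
                 step_rule = "exact", tol = NA_real_, max_iter = 0L,
                 kernel = km$spec, K = km$K, W = W, X = x, y = y,
                 call = cl),
            class = "tgl")
}
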