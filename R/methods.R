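#' @export
print.tgl <- function(x, ...) {
  cat("Tilted gradient learning fit\n")
  cat(sprintf("  samples: %d, variables: %d\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  tilt t = %g, lambda = %g, s = %.4g\n", x$t, x$lambda, x$s))
  cat(sprintf("  solver: %s, %d iterations, %s\n", x$step_rule, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat(sprintf("  final objective: %.6g\n", utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' @export
coef.tgl <- function(object, ...) object$coefficients

#' Evaluate the fitted gradient field
#'
#' Returns \eqn{\vec f(x') = \sum_i c_i K(x_i, x')} at each query point:
#' the model's estimate of the regression function's gradient there.
#'
#' @param object a fitted `"tgl"` model.
#' @param newdata matrix of query points (rows), or `NULL` for the
#'   training points.
#' @param ... unused.
#' @return matrix with one row per query point and one column per
#'   variable.
#' @export
predict.tgl <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$K %*% object$coefficients)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object$X))
    stop("'newdata' must have ", ncol(object$X), " columns", call. = FALSE)
  cross_kernel(newdata, object$X, object$kernel) %*% object$coefficients
}

#' @export
fitted.tgl <- function(object, ...) predict.tgl(object)

#' Pairwise Taylor residuals of a fit
#'
#' @param object a fitted `"tgl"` model.
#' @param ... unused.
#' @return the m x m matrix of first-order expansion residuals
#'   \eqn{y_i - y_j + \vec f(x_i)^\top (x_j - x_i)}.
#' @export
residuals.tgl <- function(object, ...) {
  residual_matrix(object$coefficients, object$K, object$X, object$y)
}

#' @export
summary.tgl <- function(object, nn = NULL, ...) {
  rel <- relevance(object)
  structure(list(fit = object, relevance = rel, nn = nn), class = "summary.tgl")
}

#' @export
print.summary.tgl <- function(x, ...) {
  print(x$fit)
  cat("\nCoordinate relevance (top 10):\n")
  ord <- x$relevance$order
  k <- min(10L, length(ord))
  df <- data.frame(coordinate = ord[seq_len(k)],
                   score = x$relevance$scores[ord[seq_len(k)]])
  print(df, row.names = FALSE, digits = 4)
  if (!is.null(x$nn)) {
    sel <- head(ord, x$nn)
    cat(sprintf("\nTop-%d selected: %s\n", x$nn,
                paste(sort(sel), collapse = ", ")))
  }
  invisible(x)
}

#' Plot a tilted gradient learning fit
#'
#' Left panel: objective trace over gradient iterations.  Right panel:
#' coordinate relevance scores (RKHS norm shares).
#'
#' @param x a fitted `"tgl"` model.
#' @param which `"trace"`, `"relevance"`, or `"both"`.
#' @param ... passed to the base plotting functions.
#' @export
plot.tgl <- function(x, which = c("both", "trace", "relevance"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- par(mfrow = c(1, 2)); on.exit(par(old))
  }
  if (which %in% c("both", "trace")) {
    tr <- x$objective_trace
    plot(seq_along(tr) - 1L, tr, type = "l", xlab = "iteration",
         ylab = "objective", main = "Descent trace", ...)
  }
  if (which %in% c("both", "relevance")) {
    r <- relevance(x)$scores
    barplot(r, names.arg = seq_along(r), xlab = "coordinate",
            ylab = "relevance share", main = "Coordinate relevance", ...)
  }
  invisible(x)
}
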