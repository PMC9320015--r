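#' Coordinate relevance ranking
#'
#' Ranks variables by their share of the fitted gradient field's energy.
#' The default `"norm"` method uses per-coordinate RKHS norms,
#' \deqn{r_l = \frac{\|f^l\|_K^2}{\sum_{p=1}^n \|f^p\|_K^2},}
#' the ranking used by gradient learning (tilted or not).  The `"coef"`
#' method ranks by raw coefficient energy,
#' \eqn{r_l = \sum_i (c_{il})^2 / \sum_{q}\sum_i (c_{iq})^2}, the
#' ranking used by robust gradient learning variants; the two coincide
#' for an identity Gram matrix.  Scores are nonnegative and sum to one.
#' Ties in the ordering are broken by ascending coordinate index.
#'
#' @param object a fitted `"tgl"` model, or a coefficient matrix.
#' @param method `"norm"` (RKHS norm shares) or `"coef"` (coefficient
#'   energy shares).
#' @param K Gram matrix; only needed when `object` is a bare matrix and
#'   `method = "norm"`.
#' @return an object of class `"tgl_relevance"`: list with `scores`
#'   (length-n, sums to 1), `order` (coordinates by decreasing score) and
#'   `method`.
#' @examples
#' C <- cbind(c(1, 0), c(1, 1))
#' relevance(C, method = "coef")$scores  # (1/3, 2/3)
#' @export
relevance <- function(object, method = c("norm", "coef"), K = NULL) {
  method <- match.arg(method)
  if (inherits(object, "tgl")) {
    C <- object$coefficients
    if (is.null(K)) K <- object$K
  } else {
    C <- as.matrix(object)
  }
  e <- switch(method,
    norm = {
      if (is.null(K)) stop("'K' is required for method = \"norm\"", call. = FALSE)
      rkhs_norm_sq(C, K)$by_coordinate
    },
    coef = colSums(C * C))
  tot <- sum(e)
  if (tot <= 0)
    stop("all-zero coefficient field: no ranking possible", call. = FALSE)
  scores <- e / tot
  structure(list(scores = as.numeric(scores),
                 order = order(scores, seq_along(scores),
                               decreasing = c(TRUE, FALSE), method = "radix"),
                 method = method),
            class = "tgl_relevance")
}

#' @export
print.tgl_relevance <- function(x, ...) {
  cat("Coordinate relevance (", x$method, " shares)\n", sep = "")
  df <- data.frame(coordinate = x$order, score = x$scores[x$order])
  print(head(df, 10L), row.names = FALSE, digits = 4)
  if (length(x$order) > 10L) cat("... (", length(x$order), " coordinates)\n")
  invisible(x)
}

#' Select the top-ranked variables
#'
#' @param object a fit, relevance object, or coefficient matrix.
#' @param k number of variables to select.
#' @param ... passed to [relevance()] when `object` is not already a
#'   ranking.
#' @return integer vector of `k` selected coordinate indices (in rank
#'   order).
#' @export
select_variables <- function(object, k, ...) {
  rel <- if (inherits(object, "tgl_relevance")) object else relevance(object, ...)
  n <- length(rel$scores)
  if (k < 0 || k > n) stop("'k' must be between 0 and ", n, call. = FALSE)
  head(rel$order, k)
}

#' Count correctly selected variables
#'
#' Size of the intersection between the selected index set and the true
#' support — the per-replicate statistic of the selection benchmarks,
#' where the generator places the true support on the first `nn`
#' coordinates.
#'
#' @param selected integer vector of selected indices.
#' @param support integer vector of true-support indices (or a single
#'   integer `nn`, shorthand for `1:nn`).
#' @return integer count in `[0, length(support)]`.
#' @export
count_effective <- function(selected, support) {
  if (length(support) == 1L && support >= 1) support <- seq_len(support)
  length(intersect(as.integer(selected), as.integer(support)))
}
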