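#' Read a design matrix and response from delimited text
#'
#' Expects a table with samples in rows whose last column is the
#' response `y` (column name `y` if a header is present), all remaining
#' columns forming the design matrix.
#'
#' @param path file path (CSV or TSV; delimiter inferred from the
#'   extension, or given explicitly).
#' @param sep field delimiter; default inferred (`","` for `.csv`,
#'   otherwise tab).
#' @param header does the file carry a header row?
#' @return list with `X` (matrix) and `y` (vector).
#' @export
read_dataset <- function(path, sep = NULL, header = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, sep = sep, header = header)
  if (ncol(df) < 2L) stop("dataset needs at least one predictor and y",
                          call. = FALSE)
  ycol <- if (header && "y" %in% names(df)) match("y", names(df)) else ncol(df)
  y <- as.numeric(df[[ycol]])
  X <- as.matrix(df[, -ycol, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("dataset contains non-finite values", call. = FALSE)
  list(X = X, y = y)
}

#' Write a dataset (or synthetic benchmark) to delimited text
#'
#' Writes `X` with the response appended as a final `y` column.  For a
#' `"tgl_sim"` object a JSON sidecar `<path>.meta.json` records the
#' generating specification so the draw is reproducible.
#'
#' @param data a `"tgl_sim"` object, or a list with `X` and `y`.
#' @param path output file path.
#' @param sep field delimiter; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  X <- data$X; y <- data$y
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$y <- y
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (inherits(data, "tgl_sim")) {
    meta <- data$spec
    meta$support <- data$support
    meta$outliers <- data$outliers
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a structured fit report
#'
#' Serializes a fitted model's coefficients, objective trace, step-size
#' constants and settings as JSON.
#'
#' @param fit a `"tgl"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tgl"))
  rep <- list(
    coefficients = unname(fit$coefficients),
    objective_trace = fit$objective_trace,
    step_size = fit$step_size,
    mu = fit$mu, gamma = fit$gamma, t_min = fit$t_min,
    constants = unclass(fit$constants),
    converged = fit$converged, n_iter = fit$n_iter,
    settings = list(t = fit$t, lambda = fit$lambda, s = fit$s,
                    normalize_weights = fit$normalize_weights,
                    step_rule = fit$step_rule, tol = fit$tol,
                    max_iter = fit$max_iter,
                    kernel = unclass(fit$kernel)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
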