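#' Frozen solver settings for the selection experiments
#'
#' One set of hyperparameters used for every cell of the replicated
#' selection study, chosen once on the clean uncorrelated Gaussian-noise
#' scenario and then held fixed across all noise families, contamination
#' levels and designs (a single-choice protocol; see the package
#' vignette for the calibration).
#'
#' @param lambda RKHS regularization.
#' @param s locality bandwidth (`NULL` = median pairwise distance).
#' @param kernel a [kernel_spec()].
#' @param step_rule,max_iter,tol solver settings passed to [tgl()].
#' @return list of class `"tgl_control"`.
#' @export
tgl_control <- function(lambda = 1e-3, s = NULL, kernel = kernel_spec(),
                        step_rule = "backtracking", max_iter = 500L,
                        tol = 1e-7) {
  structure(list(lambda = lambda, s = s, kernel = kernel,
                 step_rule = step_rule, max_iter = max_iter, tol = tol),
            class = "tgl_control")
}

#' Run one replicated cell of the selection study
#'
#' For each replicate: draw a dataset from the scenario, fit the model at
#' the given tilt, rank coordinates by RKHS norm share, select the top
#' `nn`, and count how many fall in the true support.  Replicate `r`
#' uses seed `base_seed + r`, so a cell is a pure function of its
#' arguments.
#'
#' @param scenario named list of [tgl_sim()] arguments (e.g. `list(m =
#'   50, n = 50, nn = 30, noise = "cauchy", outlier_fraction = 0.4)`).
#' @param t tilt parameter of the fitted model (0 = untilted baseline).
#' @param reps number of replicates.
#' @param base_seed integer seed offset.
#' @param control a [tgl_control()].
#' @param ranking `"norm"` (RKHS shares) or `"coef"` (coefficient
#'   energy).
#' @return list of class `"tgl_cell"` with `counts` (per-replicate
#'   effective-variable counts), `mean`, `sd`, `failed` (replicates
#'   dropped for non-convergence), and the settings.
#' @export
run_cell <- function(scenario, t, reps = 30L, base_seed = 1L,
                     control = tgl_control(), ranking = "norm") {
  stopifnot(reps >= 1L)
  nn <- scenario$nn %||% 30L
  counts <- rep(NA_real_, reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    sim <- do.call(tgl_sim, c(scenario, list(seed = base_seed + r)))
    fit <- tryCatch(
      tgl(sim$X, sim$y, t = t, lambda = control$lambda, s = control$s,
          kernel = control$kernel, step_rule = control$step_rule,
          max_iter = control$max_iter, tol = control$tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(fit)),
              call. = FALSE)
      failed <- failed + 1L
      next
    }
    sel <- select_variables(relevance(fit, method = ranking), nn)
    counts[r] <- count_effective(sel, sim$support)
  }
  if (failed > 0.2 * reps)
    stop(sprintf("%d of %d replicates failed", failed, reps), call. = FALSE)
  ok <- counts[!is.na(counts)]
  structure(list(counts = counts, mean = mean(ok), sd = sd(ok),
                 failed = failed, scenario = scenario, t = t,
                 reps = reps, base_seed = base_seed, ranking = ranking),
            class = "tgl_cell")
}

#' @export
print.tgl_cell <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "Selection cell: %s noise, %g%% outliers, %s design, t = %g\n",
    s$noise %||% "cauchy", 100 * (s$outlier_fraction %||% 0),
    if (isTRUE(s$correlated)) "correlated" else "independent", x$t))
  cat(sprintf("  effective variables: mean %.2f (sd %.2f) over %d reps%s\n",
              x$mean, x$sd, x$reps,
              if (x$failed > 0) sprintf(", %d failed", x$failed) else ""))
  invisible(x)
}

#' Replicated selection study over a grid of scenarios and tilts
#'
#' Reproduces the layout of the benchmark table: one row per (noise,
#' size, tilt) and one column per (design correlation, outlier
#' fraction), each cell the mean effective-variable count over
#' replicates.  Scenario `c` (in grid order) uses seeds `base_seed +
#' 10000 * c + r` so no two cells share a seed.
#'
#' @param noises,sizes,fractions,correlated,t_values grid axes; `sizes`
#'   is a list of `c(m, n)` pairs.
#' @param nn support size (number of effective variables).
#' @param reps replicates per cell.
#' @param base_seed integer.
#' @param control a [tgl_control()].
#' @param verbose log per-cell timing to stderr.
#' @return data frame of class `"tgl_table"` with columns `noise`, `m`,
#'   `n`, `t`, `correlated`, `outlier_fraction`, `mean`, `sd`.
#' @export
tgl_table <- function(noises = c("cauchy", "chisq", "gaussian"),
                      sizes = list(c(50, 50), c(30, 80)),
                      fractions = c(0, 0.2, 0.4),
                      correlated = c(FALSE, TRUE),
                      t_values = c(0, 6e-6, -1, -10),
                      nn = 30L, reps = 30L, base_seed = 1L,
                      control = tgl_control(), verbose = FALSE) {
  rows <- list()
  cell_id <- 0L
  for (noise in noises) for (size in sizes) for (t in t_values)
    for (corr in correlated) for (frac in fractions) {
      cell_id <- cell_id + 1L
      scenario <- list(m = size[1], n = size[2], nn = nn, noise = noise,
                       outlier_fraction = frac, correlated = corr)
      t0 <- proc.time()[["elapsed"]]
      cell <- run_cell(scenario, t = t, reps = reps,
                       base_seed = base_seed + 10000L * cell_id,
                       control = control)
      if (verbose)
        message(sprintf(
          "cell %d (%s m=%d n=%d t=%g corr=%s frac=%g): mean %.2f [%.1fs]",
          cell_id, noise, size[1], size[2], t, corr, frac, cell$mean,
          proc.time()[["elapsed"]] - t0))
      rows[[cell_id]] <- data.frame(
        noise = noise, m = size[1], n = size[2], t = t,
        correlated = corr, outlier_fraction = frac,
        mean = cell$mean, sd = cell$sd)
    }
  out <- do.call(rbind, rows)
  class(out) <- c("tgl_table", class(out))
  out
}

#' Tilt sweep on one scenario
#'
#' Mean effective-variable count as a function of the tilt parameter —
#' the diagnostic for locating the robustness sweet spot (typically near
#' `t = -1`; very large `|t|` over-concentrates the tilt weights and
#' degrades selection).
#'
#' @param scenario as in [run_cell()].
#' @param t_values numeric vector of tilts to profile.
#' @inheritParams run_cell
#' @return data frame with columns `t`, `mean`, `sd`.
#' @export
t_sweep <- function(scenario, t_values, reps = 10L, base_seed = 1L,
                    control = tgl_control()) {
  rows <- lapply(seq_along(t_values), function(i) {
    cell <- run_cell(scenario, t = t_values[i], reps = reps,
                     base_seed = base_seed, control = control)
    data.frame(t = t_values[i], mean = cell$mean, sd = cell$sd)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
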