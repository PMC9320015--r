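# tgl — tilted gradient learning for robust variable selection

`tgl` estimates the **gradient field** of an unknown regression function
from data and ranks input variables by how strongly the response reacts to
them — a model-free alternative to sparse linear selection that assumes
nothing about the functional form.  Its target audience is statisticians
and quantitative biologists screening moderate-to-high-dimensional
tabular data (biomarker panels, exposure matrices) where the noise may be
heavy-tailed or contaminated.

## The model

For samples $(x_i, y_i)$, $x_i \in \mathbb R^n$, the field $\vec f(x) =
\sum_{i=1}^m c_i K(x_i, x)$ (a Mercer kernel expansion with coefficients
$C \in \mathbb R^{m\times n}$) is fitted by minimizing the **tilted**
pairwise Taylor objective

$$
L(C, t) = \frac 1t \log \frac 1{m^2} \sum_{i,j=1}^m
\exp\!\Bigl\{ t\, \omega_{ij} \bigl(y_i - y_j + \vec f(x_i)^\top (x_j -
x_i)\bigr)^2 \Bigr\} \;+\; \lambda\, \mathrm{tr}(C^\top K C),
$$

where $\omega_{ij}$ are Gaussian locality weights.  The tilt $t$ replaces
the empirical mean of pair losses by a log-mean-exp: $t < 0$ downweights
high-loss pairs (robustness to outliers and heavy tails), $t > 0$
amplifies them, and $t \to 0$ recovers ordinary empirical-risk gradient
learning.  Fitting is by gradient descent with either an Armijo line
search or a provable fixed step $1/\gamma$ derived from plug-in
strong-convexity/smoothness constants.  Variables are ranked by their
share of the field's RKHS energy, $r_l = \|f^l\|_K^2 / \sum_p
\|f^p\|_K^2$.

See the vignette (`vignettes/tilted-gradient-learning.Rmd`) for the full
account of the model, solver, defaults and study design.

## Worked example

```r
library(tgl)

# benchmark draw: m = 50 samples, n = 50 variables, true support 1:30,
# Gaussian noise
sim <- tgl_sim(m = 50, n = 50, nn = 30, noise = "gaussian", seed = 1)

fit <- tgl(sim$X, sim$y, t = 0, lambda = 1e-3, max_iter = 500, tol = 1e-7)
fit
#> Tilted gradient learning fit
#>   samples: 50, variables: 50
#>   tilt t = 0, lambda = 0.001, s = 10.31
#>   solver: backtracking, 500 iterations, NOT converged
#>   final objective: 0.518914

rel <- relevance(fit)          # RKHS-norm shares, sum to 1
sel <- select_variables(rel, 30)
sort(sel)
#>  [1]  1  2  3  4  5  6  7  8  9 10 11 12 13 14 15 16 17 18 19 20 21 22
#> [23] 23 24 25 26 27 28 29 30
count_effective(sel, sim$support)
#> [1] 30
```

All 30 selected coordinates fall in the true support.  ("NOT converged"
reports that the 500-iteration budget of the frozen study settings ended
before the relative-change tolerance; rankings are stable at this
budget.)  Robustness studies run through `run_cell()` / `tgl_table()` /
`t_sweep()`, e.g. mean effective-variable counts under 40% outlier
contamination for the untilted baseline versus a negative tilt:

```r
scen <- list(m = 50, n = 50, nn = 30, noise = "cauchy", outlier_fraction = 0.4)
run_cell(scen, t = 0,  reps = 30, base_seed = 1, control = tgl_control())
run_cell(scen, t = -1, reps = 30, base_seed = 1, control = tgl_control())
```

A thin command-line front end is installed at `exec/tgl.R`
(subcommands `simulate`, `fit`, `select`, `table`, `sweep`).

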