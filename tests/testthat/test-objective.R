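test_that("residual matrix agrees with the brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(3:6, 1); n <- sample(1:4, 1)
    inst <- rand_instance(m, n)
    C <- matrix(rnorm(m * n), m, n)
    A <- residual_matrix(C, inst$K, inst$X, inst$y)
    expect_equal(A, residual_oracle(C, inst$K, inst$X, inst$y),
                 tolerance = 1e-12)
    expect_equal(diag(A), rep(0, m))
  }
})

test_that("residual matrix reduces to response differences at C = 0", {
  inst <- rand_instance(4, 2)
  A <- residual_matrix(matrix(0, 4, 2), inst$K, inst$X, inst$y)
  expect_equal(A, outer(inst$y, inst$y, "-"), tolerance = 1e-14)
  expect_equal(A[1, 2], inst$y[1] - inst$y[2])
})

test_that("hand-computed two-point residual is reproduced", {
  # K = I, x = (0, 1), y = (0, 1), c = (1, 0): A[1,2] = -1 + 1*1*1 = 0
  K <- diag(2)
  X <- matrix(c(0, 1), ncol = 1)
  y <- c(0, 1)
  C <- matrix(c(1, 0), ncol = 1)
  A <- residual_matrix(C, K, X, y)
  expect_equal(A[1, 2], 0)
  expect_equal(A[2, 1], (1 - 0) + 0)  # c2 = 0 leaves the raw difference
})

test_that("pair losses are weighted squared residuals with zero diagonal", {
  A <- matrix(c(0, 3, -3, 0), 2, 2)
  W <- matrix(c(1, 2, 2, 1), 2, 2)
  V <- pair_loss_matrix(A, W)
  expect_equal(V[1, 2], 18)
  expect_equal(diag(V), c(0, 0))
  expect_true(all(V >= 0))
  expect_error(pair_loss_matrix(A, -W), "nonnegative")
})

test_that("tilted risk interpolates mean and max and is continuous at zero", {
  V <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(tilted_risk(V, 1), log((1 + exp(2)) / 2), tolerance = 1e-12)
  # constant losses are a fixed point for every tilt
  Vc <- matrix(3, 4, 4)
  for (t in c(-10, -1, 0, 1, 10)) expect_equal(tilted_risk(Vc, t), 3)
  # continuity across the zero-tilt switch
  set.seed(3)
  Vr <- matrix(abs(rnorm(25)), 5, 5); diag(Vr) <- 0
  expect_equal(tilted_risk(Vr, 1e-10), tilted_risk(Vr, 0), tolerance = 1e-6)
  # monotone in t; extreme-tilt limits
  ts <- c(-10, -1, 0, 1, 10)
  risks <- vapply(ts, function(t) tilted_risk(Vr, t), numeric(1))
  expect_true(all(diff(risks) >= -1e-12))
  expect_equal(tilted_risk(Vr, 500), max(Vr), tolerance = 0.05)
  expect_equal(tilted_risk(Vr, -5000), 0, tolerance = 0.01)  # zero diagonal
})

test_that("tilted risk is overflow-safe for extreme tilts", {
  V <- matrix(c(0, 1e4, 1e4, 0), 2, 2)
  expect_true(is.finite(tilted_risk(V, 1)))
  expect_true(is.finite(tilted_risk(V, -1)))
  expect_true(all(is.finite(tilt_weights(V, 1))))
})

test_that("tilt weights are a mean-one exponential reweighting", {
  V <- matrix(c(0, 2, 2, 0), 2, 2)
  Phi <- tilt_weights(V, -1)
  expect_equal(Phi[1, 1], 4 / (2 + 2 * exp(-2)), tolerance = 1e-6)
  expect_equal(Phi[1, 2], exp(-2) * 4 / (2 + 2 * exp(-2)), tolerance = 1e-6)
  expect_equal(mean(Phi), 1, tolerance = 1e-12)
  expect_equal(tilt_weights(V, 0), matrix(1, 2, 2))
  expect_equal(tilt_weights(matrix(5, 3, 3), -7), matrix(1, 3, 3))
  set.seed(9)
  for (t in c(-3, -0.2, 0.4, 2)) {
    Vr <- matrix(abs(rnorm(36)), 6, 6); diag(Vr) <- 0
    expect_equal(mean(tilt_weights(Vr, t)), 1, tolerance = 1e-12)
  }
})

test_that("risk gradient matches finite differences and its zero-tilt form", {
  set.seed(31)
  inst <- rand_instance(4, 2)
  C <- matrix(rnorm(8) * 0.4, 4, 2)
  lam <- 0.05
  for (t in c(-1.5, 0, 0.7)) {
    G <- risk_gradient(C, inst$K, inst$W, inst$X, inst$y, t) +
      lam * regularizer_gradient(C, inst$K)
    expect_lt(max(abs(G - fd_gradient(C, inst$K, inst$W, inst$X, inst$y,
                                      t, lam))), 1e-5)
  }
  # t = 0 equals the uniform-weight (Phi = 1) gradient computed directly
  A <- residual_matrix(C, inst$K, inst$X, inst$y)
  S <- 2 * inst$W * A
  G0 <- (inst$K %*% (S %*% inst$X - rowSums(S) * inst$X)) / 16
  expect_equal(risk_gradient(C, inst$K, inst$W, inst$X, inst$y, 0), G0,
               tolerance = 1e-12)
})

test_that("risk is stationary at zero residuals and translation invariant", {
  inst <- rand_instance(5, 2)
  y_const <- rep(2.5, 5)
  C0 <- matrix(0, 5, 2)
  expect_equal(risk_gradient(C0, inst$K, inst$W, inst$X, y_const, -1),
               matrix(0, 5, 2))
  # shifting all responses leaves residuals, losses and gradients unchanged
  C <- matrix(rnorm(10), 5, 2)
  shift <- 17
  expect_equal(residual_matrix(C, inst$K, inst$X, inst$y),
               residual_matrix(C, inst$K, inst$X, inst$y + shift),
               tolerance = 1e-10)
  expect_equal(risk_gradient(C, inst$K, inst$W, inst$X, inst$y, -1),
               risk_gradient(C, inst$K, inst$W, inst$X, inst$y + shift, -1),
               tolerance = 1e-10)
})

test_that("RKHS norms match the double-loop oracle and identity-kernel case", {
  set.seed(41)
  inst <- rand_instance(5, 3)
  C <- matrix(rnorm(15), 5, 3)
  ns <- rkhs_norm_sq(C, inst$K)
  expect_equal(ns$total, rkhs_oracle(C, inst$K), tolerance = 1e-10)
  expect_equal(sum(ns$by_coordinate), ns$total)
  expect_equal(rkhs_norm_sq(C, diag(5))$total, sum(C^2))
  z <- rkhs_norm_sq(matrix(0, 5, 3), inst$K)
  expect_equal(z$total, 0)
  expect_equal(z$by_coordinate, rep(0, 3))
})

test_that("regularizer gradient is 2KC and matches finite differences", {
  set.seed(43)
  inst <- rand_instance(4, 2)
  C <- matrix(rnorm(8), 4, 2)
  expect_equal(regularizer_gradient(C, diag(4)), 2 * C)
  expect_equal(regularizer_gradient(C, inst$K), 2 * inst$K %*% C)
  h <- 1e-6
  fd <- matrix(0, 4, 2)
  for (i in 1:4) for (j in 1:2) {
    Cp <- C; Cp[i, j] <- Cp[i, j] + h
    Cm <- C; Cm[i, j] <- Cm[i, j] - h
    fd[i, j] <- (rkhs_norm_sq(Cp, inst$K)$total -
                   rkhs_norm_sq(Cm, inst$K)$total) / (2 * h)
  }
  expect_lt(max(abs(regularizer_gradient(C, inst$K) - fd)), 1e-5)
})

test_that("objective is monotone in the regularizer weight and in the tilt", {
  set.seed(47)
  inst <- rand_instance(5, 2)
  C <- matrix(rnorm(10), 5, 2)
  L1 <- tgl_objective(C, inst$K, inst$W, inst$X, inst$y, 0, 0.1)
  L2 <- tgl_objective(C, inst$K, inst$W, inst$X, inst$y, 0, 0.5)
  expect_gt(L2, L1)
  Ls <- vapply(c(-10, -1, 0, 1, 10), function(t)
    tgl_objective(C, inst$K, inst$W, inst$X, inst$y, t, 0.1), numeric(1))
  expect_true(all(diff(Ls) >= -1e-10))
})

test_that("joint row permutation leaves pairwise structures consistent", {
  set.seed(53)
  inst <- rand_instance(5, 3)
  C <- matrix(rnorm(15), 5, 3)
  p <- sample(5)
  Kp <- inst$K[p, p]; Wp <- inst$W[p, p]
  A <- residual_matrix(C, inst$K, inst$X, inst$y)
  Ap <- residual_matrix(C[p, ], Kp, inst$X[p, ], inst$y[p])
  expect_equal(Ap, A[p, p], tolerance = 1e-12)
  V <- pair_loss_matrix(A, inst$W)
  expect_equal(tilted_risk(pair_loss_matrix(Ap, Wp), -0.5),
               tilted_risk(V, -0.5), tolerance = 1e-12)
})
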