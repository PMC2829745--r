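test_that("linear step does plain first-order arithmetic", {
  F0 <- matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2)
  expect_identical(step_linear(F0, matrix(0, 2, 2), 0.1), F0)
  expect_equal(step_linear(diag(2), matrix(c(0, 0, 0.5, 0), 2, 2), 1),
               matrix(c(1, 0, 0.5, 1), 2, 2))
  # det(I + L dt) = 1 + dt tr L + dt^2 det L
  set.seed(1)
  for (i in 1:20) {
    L <- matrix(rnorm(4), 2, 2); dt <- runif(1, 0.01, 0.5)
    expect_equal(det(step_linear(diag(2), L, dt)),
                 1 + dt * sum(diag(L)) + dt^2 * det(L), tolerance = 1e-12)
  }
})

test_that("exponential step matches closed forms of the 2x2 exponential", {
  # nilpotent: exp truncates exactly
  Ln <- matrix(c(0, 0, 0.5, 0), 2, 2)
  expect_equal(step_exponential(diag(2), Ln, 1),
               matrix(c(1, 0, 0.5, 1), 2, 2), tolerance = 1e-15)
  # antisymmetric: rotation by omega dt, orthogonal to 1e-12
  w <- 0.8; dt <- 0.7
  R <- step_exponential(diag(2), matrix(c(0, w, -w, 0), 2, 2), dt)
  expect_equal(R, matrix(c(cos(w * dt), sin(w * dt),
                           -sin(w * dt), cos(w * dt)), 2, 2),
               tolerance = 1e-14)
  expect_lt(max(abs(t(R) %*% R - diag(2))), 1e-12)
  # trace-free L preserves det exactly: det exp A = exp tr A
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(3)
    L <- matrix(c(a[1], a[3], a[2], -a[1]), 2, 2)
    F0 <- random_invertible()
    expect_lt(abs(det(step_exponential(F0, L, 0.3)) - det(F0)), 1e-12)
  }
  # general matrices agree with an independent scaling-and-squaring oracle
  for (i in 1:10) {
    A <- matrix(rnorm(4), 2, 2)
    expect_equal(expm2(A), as.matrix(Matrix::expm(A)), tolerance = 1e-10)
  }
  # near-degenerate discriminant exercises the series branch
  A <- matrix(c(0.3, 1e-6, 1e-6, 0.3), 2, 2)
  expect_equal(expm2(A), as.matrix(Matrix::expm(A)), tolerance = 1e-12)
})

test_that("composition is the ordered matrix product", {
  F1 <- random_invertible()
  expect_identical(compose(F1, diag(2)), F1 %*% diag(2))
  a <- 0.4; b <- 0.9
  R <- function(x) matrix(c(cos(x), sin(x), -sin(x), cos(x)), 2, 2)
  expect_equal(compose(R(a), R(b)), R(a + b), tolerance = 1e-14)
})

test_that("tracking reproduces closed-form trajectories", {
  # zero velocity: points do not move
  vg0 <- constant_vg_fields(rep(list(matrix(0, 2, 2)), 4), nx = 12, ny = 12)
  grid <- time_grid(0, 0.25, 4)
  seeds <- rbind(c(2, 5, 8), c(3, 6, 9))
  tr <- track_material_points(vg0, seeds, grid)
  for (k in 1:5) expect_equal(tr$positions[, , k], seeds)
  expect_true(all(tr$in_domain))
  # constant translation: exact (interpolation of a constant field)
  vgt <- constant_vg_fields(rep(list(matrix(0, 2, 2)), 4), nx = 12, ny = 12,
                            v = c(1.2, -0.8))
  tr <- track_material_points(vgt, seeds, grid)
  expect_equal(tr$positions[, , 5], seeds + c(1.2, -0.8) * 1,
               tolerance = 1e-12)
  # exits are frozen and flagged, not extrapolated
  trx <- track_material_points(vgt, rbind(10.5, 10.5), grid)
  expect_false(all(trx$in_domain))
  frozen <- trx$positions[, 1, max(which(trx$in_domain[1, ]))]
  expect_equal(trx$positions[, 1, 5], frozen)
})

test_that("Euler tracking of a rotation keeps the radius to 0.5%", {
  m <- phantom_model("rigid_rotation", omega = 0.6, center = c(20, 20),
                     time_span = c(0, 0.5))
  grid <- time_grid(0, 0.025, 20)
  vg <- analytic_vg_fields(m, 41, 41, 1, grid)
  X <- c(30, 20)
  tr <- track_material_points(vg, matrix(X, 2, 1), grid)
  rend <- sqrt(sum((tr$positions[, 1, 21] - c(20, 20))^2))
  expect_lt(abs(rend - 10), 0.005 * 10)
})

test_that("zero velocity gradient integrates to the identity", {
  vg0 <- constant_vg_fields(rep(list(matrix(0, 2, 2)), 5), nx = 10, ny = 10)
  grid <- time_grid(0, 0.1, 5)
  seeds <- rbind(c(2, 4), c(3, 5))
  tr <- track_material_points(vg0, seeds, grid)
  for (method in c("linear_product", "exp_product")) {
    def <- integrate_deformation(vg0, tr, grid, method)
    for (k in 1:6) for (i in 1:2)
      expect_equal(def$F[, , i, k], diag(2))
  }
})

test_that("stationary flow recovers the closed-form exponential solution", {
  L0 <- matrix(c(0.3, 0.4, -0.2, -0.1), 2, 2)
  n <- 16; dt <- 0.05
  vg <- constant_vg_fields(rep(list(L0), n), nx = 10, ny = 10)
  grid <- time_grid(0, dt, n)
  tr <- track_material_points(vg, rbind(4.5, 4.5), grid)
  def <- integrate_deformation(vg, tr, grid, "exp_product")
  for (k in 0:n) {
    expect_equal(def$F[, , 1, k + 1],
                 as.matrix(Matrix::expm(k * dt * L0)), tolerance = 1e-10)
  }
})

test_that("interval splitting composes bit-for-bit for the linear product", {
  set.seed(9)
  Ls <- lapply(1:8, function(i) matrix(rnorm(4, sd = 0.4), 2, 2))
  vg <- constant_vg_fields(Ls, nx = 10, ny = 10)
  grid <- time_grid(0, 0.05, 8)
  tr <- track_material_points(vg, rbind(4.5, 4.5), grid)
  def <- integrate_deformation(vg, tr, grid, "linear_product")
  Ffull <- def$F[, , 1, 9]
  # split adjacent to the newest factor: exactly the same operation order,
  # hence bitwise identical
  Fa7 <- def$F[, , 1, 8]
  expect_identical(compose(step_linear(diag(2), Ls[[8]], 0.05), Fa7), Ffull)
  for (split in c(2, 4, 6)) {
    # F(t, t0) = F(t, ts) F(ts, t0): rebuild both halves from the steps;
    # regrouping the rounded products can move the last bits, nothing more
    Fa <- diag(2); Fb <- diag(2)
    for (k in 1:split) Fa <- step_linear(Fa, Ls[[k]], 0.05)
    for (k in (split + 1):8) Fb <- step_linear(Fb, Ls[[k]], 0.05)
    expect_lt(max(abs(compose(Fb, Fa) - Ffull)), 1e-14)
  }
})

test_that("trace-free flows preserve area: exactly (exp) or at first order (linear)", {
  set.seed(4)
  tf <- function(a, b, c) matrix(c(a, c, b, -a), 2, 2)
  Ls <- lapply(1:20, function(i) tf(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                                    runif(1, -0.5, 0.5)))
  grid <- time_grid(0, 0.05, 20)
  vg <- constant_vg_fields(Ls, nx = 10, ny = 10)
  tr <- track_material_points(vg, rbind(4.5, 4.5), grid)
  dexp <- integrate_deformation(vg, tr, grid, "exp_product")
  dets <- apply(dexp$F[, , 1, ], 3, det)
  expect_lt(max(abs(dets - 1)), 1e-10)
  # linear product: det error shrinks linearly in dt (smooth L(t))
  Lt <- function(t) tf(0.4 * sin(2 * pi * t), 0.3 * cos(2 * pi * t),
                       -0.35 * sin(4 * pi * t + 1))
  err_at <- function(n) {
    dt <- 1 / n
    Fm <- diag(2)
    for (k in 1:n) Fm <- step_linear(Fm, Lt(k * dt), dt)
    abs(det(Fm) - 1)
  }
  errs <- vapply(c(20, 40, 80), err_at, numeric(1))
  expect_gt(errs[1] / errs[2], 1.5)
  expect_gt(errs[2] / errs[3], 1.5)
})

test_that("determinant of the product factorizes over the steps", {
  set.seed(12)
  Ls <- lapply(1:6, function(i) matrix(rnorm(4, sd = 0.5), 2, 2))
  Fm <- diag(2); dprod <- 1
  for (L in Ls) {
    step <- diag(2) + L * 0.1
    Fm <- step %*% Fm
    dprod <- dprod * det(step)
  }
  expect_equal(det(Fm), dprod, tolerance = 1e-12)
})

test_that("matricant series cross-checks the exponential product", {
  vg0 <- constant_vg_fields(rep(list(matrix(0, 2, 2)), 4), nx = 10, ny = 10)
  grid <- time_grid(0, 0.25, 4)
  tr <- track_material_points(vg0, rbind(4.5, 4.5), grid)
  m1 <- matricant_series(vg0, tr, grid, order = 1)
  for (k in 1:5) expect_equal(m1$F[, , 1, k], diag(2))
  # small stationary L0 with |L| T = 0.1: order 3 within the remainder bound
  L0 <- matrix(c(0.06, 0.05, -0.04, -0.02), 2, 2) # spectral norm ~ 0.1
  n <- 20; dt <- 1 / n
  vg <- constant_vg_fields(rep(list(L0), n), nx = 10, ny = 10)
  grid <- time_grid(0, dt, n)
  tr <- track_material_points(vg, rbind(4.5, 4.5), grid)
  m3 <- matricant_series(vg, tr, grid, order = 3)
  dexp <- integrate_deformation(vg, tr, grid, "exp_product")
  expect_lt(max(abs(m3$F[, , 1, n + 1] - dexp$F[, , 1, n + 1])), 1e-5)
  # orders 2 and 3 differ for non-commuting time-varying L (an A-B-A
  # switching sequence makes the third iterated integral nonzero)
  A <- matrix(c(0, 0, 0.5, 0), 2, 2)
  B <- matrix(c(0, 0.5, 0, 0), 2, 2)
  Ls <- c(rep(list(A), 4), rep(list(B), 4), rep(list(A), 4))
  vg <- constant_vg_fields(Ls, nx = 10, ny = 10)
  grid <- time_grid(0, 0.1, 12)
  tr <- track_material_points(vg, rbind(4.5, 4.5), grid)
  m2 <- matricant_series(vg, tr, grid, order = 2)
  m3 <- matricant_series(vg, tr, grid, order = 3)
  expect_gt(max(abs(m2$F[, , 1, 13] - m3$F[, , 1, 13])), 0)
})

test_that("linear and exponential products converge to each other as dt shrinks", {
  m <- phantom_model("incompressible_annulus", center = c(32, 32),
                     time_span = c(0, 0.5), lambda_end = -60, phi_end = 0.12)
  X <- matrix(c(32 + 20, 32), 2, 1)
  gap <- function(n) {
    grid <- time_grid(0, 0.5 / n, n)
    vg <- analytic_vg_fields(m, 65, 65, 1, grid)
    tr <- track_material_points(vg, X, grid)
    dl <- integrate_deformation(vg, tr, grid, "linear_product")
    de <- integrate_deformation(vg, tr, grid, "exp_product")
    max(abs(dl$F[, , 1, n + 1] - de$F[, , 1, n + 1]))
  }
  gaps <- vapply(c(10, 20, 40), gap, numeric(1))
  expect_gt(gaps[1] / gaps[2], 1.8)
  expect_gt(gaps[2] / gaps[3], 1.8)
})

test_that("ground-truth-driven integration converges to the analytic deformation", {
  m <- phantom_model("incompressible_annulus", center = c(32, 32),
                     time_span = c(0, 0.5), lambda_end = -60, phi_end = 0.12)
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  X <- rbind(32 + 15 * cos(ang), 32 + 15 * sin(ang))
  Ftrue <- analytic_deformation(m, X, 0.5)
  err_at <- function(n) {
    grid <- time_grid(0, 0.5 / n, n)
    vg <- analytic_vg_fields(m, 65, 65, 1, grid)
    tr <- track_material_points(vg, X, grid)
    def <- integrate_deformation(vg, tr, grid, "exp_product")
    median(vapply(seq_len(ncol(X)), function(i)
      norm(def$F[, , i, n + 1] - Ftrue[, , i], "F"), numeric(1)))
  }
  e20 <- err_at(20); e40 <- err_at(40); e80 <- err_at(80)
  expect_lt(e80, 0.02)
  expect_gt(e20 / e40, 1.5) # first-order convergence observed
  expect_gt(e40 / e80, 1.5)
})
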