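#' Uniform time grid for deformation integration
#'
#' Frame times `t_k = t0 + k * dt`, `k = 0..n`, with evaluation points
#' `t_k* = t_k` (the right endpoint of each interval, matching a constant
#' frame interval acquisition).
#'
#' @param t0 reference time (s).
#' @param dt frame interval (s).
#' @param n_steps number of intervals (frames after the reference).
#' @return An object of class `time_grid` with fields `t0`, `dt`, `times`
#'   (length `n_steps + 1`) and `t_star` (length `n_steps`).
#' @export
time_grid <- function(t0, dt, n_steps) {
  stopifnot(dt > 0, n_steps >= 1)
  k <- seq_len(n_steps)
  structure(list(t0 = t0, dt = dt, n_steps = as.integer(n_steps),
                 times = t0 + c(0, k) * dt, t_star = t0 + k * dt),
            class = "time_grid")
}

#' One linear multiplicative-integral step
#'
#' Advances the deformation gradient across one interval with the
#' first-order factor: `F_new = (I + L_star * dt) F_prev`.
#'
#' @param F_prev `2 x 2` deformation gradient at the start of the interval.
#' @param L_star `2 x 2` velocity gradient representative for the interval (1/s).
#' @param dt interval length (s).
#' @return `2 x 2` matrix.
#' @export
step_linear <- function(F_prev, L_star, dt) {
  (diag(2) + L_star * dt) %*% F_prev
}

#' Closed-form 2 x 2 matrix exponential
#'
#' Cayley-Hamilton form: with `mu = tr(A)/2`, `B = A - mu I` and
#' `delta = -det(B)`, `exp(A) = exp(mu) (c(delta) I + s(delta) B)` where
#' `c, s` are the cosh/sinhc-type series in `delta`, evaluated in closed
#' form away from `delta = 0` and by series near it.
#'
#' @param A `2 x 2` matrix.
#' @return `2 x 2` matrix `exp(A)`.
#' @export
expm2 <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == 2), all(is.finite(A)))
  mu <- (A[1, 1] + A[2, 2]) / 2
  B <- A - mu * diag(2)
  delta <- B[1, 2] * B[2, 1] + B[1, 1]^2 # = -det(B), B is trace-free
  if (abs(delta) > 1e-8) {
    s <- sqrt(abs(delta))
    if (delta > 0) {
      cc <- cosh(s); ss <- sinh(s) / s
    } else {
      cc <- cos(s); ss <- sin(s) / s
    }
  } else {
    # series in delta: cosh(sqrt(d)) and sinh(sqrt(d))/sqrt(d)
    cc <- 1 + delta / 2 + delta^2 / 24
    ss <- 1 + delta / 6 + delta^2 / 120
  }
  exp(mu) * (cc * diag(2) + ss * B)
}

#' One exponential multiplicative-integral step
#'
#' `F_new = exp(L_star * dt) F_prev` with the closed 2 x 2 matrix
#' exponential. For trace-free `L_star` the step preserves `det F` exactly
#' (up to roundoff), since `det exp(A) = exp(tr A)`.
#'
#' @inheritParams step_linear
#' @return `2 x 2` matrix.
#' @export
step_exponential <- function(F_prev, L_star, dt) {
  expm2(L_star * dt) %*% F_prev
}

#' Compose deformation gradients across adjoining intervals
#'
#' `F(t, t0) = F(t, t1) F(t1, t0)`: the later factor multiplies from the
#' left.
#'
#' @param F_ab `2 x 2` gradient over the later interval `[t1, t]`.
#' @param F_bc `2 x 2` gradient over the earlier interval `[t0, t1]`.
#' @return `2 x 2` matrix.
#' @export
compose <- function(F_ab, F_bc) F_ab %*% F_bc

## Sample v or one L component of the k-th velocity-gradient field at
## physical positions (2 x m). vg_fields is the list returned by
## estimate_velocity_gradient(); component in c("v1","v2","L11","L12","L21","L22").
sample_field <- function(vg_field, component, pts, spacing) {
  img <- switch(component,
    v1 = vg_field$v[, , 1], v2 = vg_field$v[, , 2],
    L11 = vg_field$L[, , 1, 1], L12 = vg_field$L[, , 1, 2],
    L21 = vg_field$L[, , 2, 1], L22 = vg_field$L[, , 2, 2])
  bilinear(img, pts, spacing, validity = vg_field$validity)
}

#' Track material points through a velocity-field sequence
#'
#' Advances reference positions frame by frame with explicit Euler and
#' bilinear interpolation of the velocity:
#' `x_k = x_{k-1} + v_k(x_{k-1}) * dt`, where `v_k` is the field of the
#' k-th frame pair. Trajectories that leave the valid region are frozen at
#' their last valid position and flagged, never extrapolated.
#'
#' @param vg_fields list of velocity-gradient fields (one per frame pair),
#'   as returned by [estimate_velocity_gradient()].
#' @param seeds `2 x m` matrix of reference positions at `t0` (mm).
#' @param grid a [time_grid()] with `n_steps = length(vg_fields)`.
#' @return An object of class `material_trajectories`: list with
#'   `positions` (`2 x m x (n_steps + 1)`, mm; `[, , 1]` equals `seeds`) and
#'   `in_domain` (`m x (n_steps + 1)` logical).
#' @export
track_material_points <- function(vg_fields, seeds, grid) {
  seeds <- as_points(seeds)
  m <- ncol(seeds)
  if (m == 0) stop("empty seed set")
  n <- length(vg_fields)
  stopifnot(inherits(grid, "time_grid"), grid$n_steps == n)
  spacing <- vg_fields[[1]]$spacing
  pos <- array(NA_real_, c(2, m, n + 1))
  ok <- matrix(FALSE, m, n + 1)
  pos[, , 1] <- seeds
  ok[, 1] <- TRUE
  cur <- seeds
  alive <- rep(TRUE, m)
  for (k in seq_len(n)) {
    v1 <- sample_field(vg_fields[[k]], "v1", cur, spacing)
    v2 <- sample_field(vg_fields[[k]], "v2", cur, spacing)
    bad <- alive & (is.na(v1) | is.na(v2))
    alive[bad] <- FALSE
    step <- rbind(v1, v2) * grid$dt
    cur[, alive] <- cur[, alive, drop = FALSE] + step[, alive, drop = FALSE]
    pos[, , k + 1] <- cur
    ok[, k + 1] <- alive
  }
  structure(list(positions = pos, in_domain = ok, spacing = spacing),
            class = "material_trajectories")
}

#' Integrate the deformation-gradient ODE along material trajectories
#'
#' Solves `dF/dt = L F`, `F(t0, t0) = I`, as an ordered product of
#' per-interval factors (newest factor leftmost). The velocity gradient for
#' interval `k` is sampled by bilinear interpolation at the tracked
#' position at the interval's evaluation point `t_k*`. Where a trajectory
#' has left the valid region, `F` is frozen at its last valid frame and
#' flagged.
#'
#' @param vg_fields list of velocity-gradient fields, one per frame pair.
#' @param traj [track_material_points()] output for the same fields.
#' @param grid the [time_grid()] used for tracking.
#' @param method `"linear_product"` (default; factors `I + L dt`, the
#'   computationally cheap choice) or `"exp_product"` (factors
#'   `exp(L dt)`, exactly volume preserving for trace-free `L`).
#' @return An object of class `deformation_field`: list with `F`
#'   (`2 x 2 x m x (n_steps + 1)`; `[, , , 1]` is the identity), `valid`
#'   (`m x (n_steps + 1)` logical) and `method`.
#' @export
integrate_deformation <- function(vg_fields, traj, grid,
                                  method = c("linear_product", "exp_product")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "material_trajectories"),
            inherits(grid, "time_grid"),
            grid$n_steps == length(vg_fields))
  spacing <- traj$spacing
  m <- dim(traj$positions)[2]
  n <- grid$n_steps
  Fs <- array(NA_real_, c(2, 2, m, n + 1))
  valid <- matrix(FALSE, m, n + 1)
  Fs[, , , 1] <- array(diag(2), c(2, 2, m))
  valid[, 1] <- TRUE
  Fcur <- array(diag(2), c(2, 2, m))
  alive <- rep(TRUE, m)
  step_fun <- if (method == "linear_product") step_linear else step_exponential
  for (k in seq_len(n)) {
    # sample L at the tracked position at t_k* = t_k
    xk <- traj$positions[, , k + 1, drop = FALSE][, , 1]
    if (m == 1) xk <- matrix(xk, 2, 1)
    Lc <- lapply(c("L11", "L12", "L21", "L22"), function(cmp)
      sample_field(vg_fields[[k]], cmp, xk, spacing))
    bad <- alive & (!traj$in_domain[, k + 1] |
                    Reduce(`|`, lapply(Lc, is.na)))
    alive[bad] <- FALSE
    for (i in which(alive)) {
      Lk <- matrix(c(Lc[[1]][i], Lc[[3]][i], Lc[[2]][i], Lc[[4]][i]), 2, 2)
      Fcur[, , i] <- step_fun(Fcur[, , i], Lk, grid$dt)
    }
    Fs[, , alive, k + 1] <- Fcur[, , alive]
    valid[alive, k + 1] <- TRUE
    # frozen trajectories keep their last valid F, flagged invalid
    if (any(!alive)) Fs[, , !alive, k + 1] <- Fcur[, , !alive]
  }
  structure(list(F = Fs, valid = valid, method = method),
            class = "deformation_field")
}

#' Matricant-series solution of the deformation ODE
#'
#' Truncated iterated-integral expansion
#' `F = I + int L + int L int L + ...` (trapezoid rule on the frame grid),
#' provided as an independent cross-check of the multiplicative-integral
#' solvers, not as the default solver.
#'
#' @inheritParams integrate_deformation
#' @param order truncation order, 1 to 3.
#' @return A `deformation_field` (method `"matricant_series"`).
#' @export
matricant_series <- function(vg_fields, traj, grid, order = 3) {
  stopifnot(order %in% 1:3)
  spacing <- traj$spacing
  m <- dim(traj$positions)[2]
  n <- grid$n_steps
  # L evaluated at frame times t_0..t_n along each trajectory; take the
  # field of interval k as the value at its right endpoint t_k, and the
  # first field at t_0.
  Lmats <- vector("list", n + 1)
  valid <- matrix(TRUE, m, n + 1)
  for (j in 0:n) {
    k <- max(j, 1)
    xj <- traj$positions[, , j + 1, drop = FALSE][, , 1]
    if (m == 1) xj <- matrix(xj, 2, 1)
    Lc <- lapply(c("L11", "L12", "L21", "L22"), function(cmp)
      sample_field(vg_fields[[k]], cmp, xj, spacing))
    valid[, j + 1] <- traj$in_domain[, j + 1] &
      !Reduce(`|`, lapply(Lc, is.na))
    Lmat <- array(0, c(2, 2, m))
    Lmat[1, 1, ] <- Lc[[1]]; Lmat[1, 2, ] <- Lc[[2]]
    Lmat[2, 1, ] <- Lc[[3]]; Lmat[2, 2, ] <- Lc[[4]]
    Lmat[is.na(Lmat)] <- 0
    Lmats[[j + 1]] <- Lmat
  }
  valid <- t(apply(valid, 1, cumprod)) > 0
  dt <- grid$dt
  # cumulative iterated integrals per trajectory
  Fs <- array(NA_real_, c(2, 2, m, n + 1))
  for (i in seq_len(m)) {
    Ls <- lapply(Lmats, function(a) a[, , i])
    M1 <- M2 <- M3 <- vector("list", n + 1)
    M1[[1]] <- M2[[1]] <- M3[[1]] <- matrix(0, 2, 2)
    for (j in seq_len(n)) {
      M1[[j + 1]] <- M1[[j]] + dt / 2 * (Ls[[j]] + Ls[[j + 1]])
      M2[[j + 1]] <- M2[[j]] + dt / 2 *
        (Ls[[j]] %*% M1[[j]] + Ls[[j + 1]] %*% M1[[j + 1]])
      M3[[j + 1]] <- M3[[j]] + dt / 2 *
        (Ls[[j]] %*% M2[[j]] + Ls[[j + 1]] %*% M2[[j + 1]])
    }
    for (j in 0:n) {
      Fj <- diag(2) + M1[[j + 1]]
      if (order >= 2) Fj <- Fj + M2[[j + 1]]
      if (order >= 3) Fj <- Fj + M3[[j + 1]]
      Fs[, , i, j + 1] <- Fj
    }
  }
  structure(list(F = Fs, valid = valid, method = "matricant_series"),
            class = "deformation_field")
}

#' Build a velocity-gradient field sequence from analytic ground truth
#'
#' Samples [analytic_velocity_gradient()] of a phantom model on the pixel
#' grid at the evaluation point of every frame interval, producing the same
#' structure as [estimate_velocity_gradient()]. Used to exercise the
#' integration and strain stages in isolation from the optic-flow front end.
#'
#' @param model a [phantom_model()].
#' @param nx,ny,spacing pixel grid.
#' @param grid a [time_grid()].
#' @return List of velocity-gradient fields, one per interval.
#' @export
analytic_vg_fields <- function(model, nx, ny, spacing, grid) {
  spacing <- rep_len(spacing, 2L)
  xc <- pixel_coords(nx, ny, spacing)
  pts <- rbind(as.numeric(xc$x1), as.numeric(xc$x2))
  lapply(seq_len(grid$n_steps), function(k) {
    vg <- analytic_velocity_gradient(model, pts, grid$t_star[k])
    v <- array(0, c(nx, ny, 2))
    v[, , 1] <- vg$v[1, ]; v[, , 2] <- vg$v[2, ]
    L <- array(0, c(nx, ny, 2, 2))
    L[, , 1, 1] <- vg$L[1, 1, ]; L[, , 1, 2] <- vg$L[1, 2, ]
    L[, , 2, 1] <- vg$L[2, 1, ]; L[, , 2, 2] <- vg$L[2, 2, ]
    list(v = v, L = L, validity = matrix(TRUE, nx, ny),
         scale = matrix(0, nx, ny), cond = matrix(1, nx, ny),
         spacing = spacing)
  })
}
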