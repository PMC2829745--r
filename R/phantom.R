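#' Analytic phantom motion models
#'
#' A `phantom_model` describes a time-dependent planar motion map
#' `x = chi(X, t)` with closed-form position, inverse position, deformation
#' gradient `F = dx/dX` and Eulerian velocity gradient `L = dv/dx`. These
#' oracles make every downstream stage of the pipeline testable against
#' ground truth without acquired data.
#'
#' Available kinds:
#' \describe{
#'   \item{`translation`}{`x = X + velocity * (t - t0)`; `velocity` in mm/s.}
#'   \item{`rigid_rotation`}{rotation about `center` at angular rate `omega`
#'     (rad/s).}
#'   \item{`uniform_scaling`}{isotropic scaling about `center`; the scale
#'     ramps linearly from 1 at `t0` to `scale_end` at the end of
#'     `time_span`, so `F = s(t) I`.}
#'   \item{`simple_shear`}{`x1 = X1 + gamma * (t - t0) * (X2 - center2)`;
#'     `gamma` is the shear rate in 1/s.}
#'   \item{`incompressible_annulus`}{area-preserving contraction plus twist
#'     of an annulus: in polar coordinates about `center`,
#'     `r = sqrt(R^2 + lambda(t))`, `theta = Theta + phi(t)`, with
#'     `lambda(t)` (mm^2, non-positive for contraction) and `phi(t)` (rad)
#'     following half-cosine ramps from 0 at `t0` to `lambda_end`,
#'     `phi_end` at the end of `time_span`. `det F = 1` identically, the
#'     velocity field is divergence free, and the map emulates systolic
#'     contraction with torsion of a short-axis left-ventricular slice.}
#' }
#'
#' @param kind model kind (see Details).
#' @param center motion center in mm (length 2).
#' @param time_span `c(t0, t_end)` in seconds.
#' @param ... model parameters: `velocity` (length-2 mm/s), `omega` (rad/s),
#'   `scale_end`, `gamma` (1/s), `lambda_end` (mm^2), `phi_end` (rad).
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(kind = c("translation", "rigid_rotation",
                                   "uniform_scaling", "simple_shear",
                                   "incompressible_annulus"),
                          center = c(0, 0), time_span = c(0, 1), ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  stopifnot(length(center) == 2, length(time_span) == 2,
            time_span[2] > time_span[1])
  defaults <- switch(kind,
    translation = list(velocity = c(1, 0)),
    rigid_rotation = list(omega = 0.1),
    uniform_scaling = list(scale_end = 1.1),
    simple_shear = list(gamma = 0.1),
    incompressible_annulus = list(lambda_end = -150, phi_end = 0.15)
  )
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  pars <- utils::modifyList(defaults, pars)
  structure(list(kind = kind, params = pars, center = as.numeric(center),
                 time_span = as.numeric(time_span)),
            class = "phantom_model")
}

check_time <- function(model, t) {
  if (any(t < model$time_span[1] - 1e-9 | t > model$time_span[2] + 1e-9))
    stop("time outside model time_span")
}

## Half-cosine ramp from 0 to 1 over the model time span, and its rate.
ramp_fun <- function(model, t) {
  tau <- (t - model$time_span[1]) / diff(model$time_span)
  list(f = 0.5 * (1 - cos(pi * tau)),
       df = 0.5 * pi * sin(pi * tau) / diff(model$time_span))
}

annulus_state <- function(model, t) {
  r <- ramp_fun(model, t)
  list(lambda = model$params$lambda_end * r$f,
       dlambda = model$params$lambda_end * r$df,
       phi = model$params$phi_end * r$f,
       dphi = model$params$phi_end * r$df)
}

as_points <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 2)
  stopifnot(nrow(X) == 2)
  X
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Analytic motion map of a phantom model
#'
#' @param model a [phantom_model()].
#' @param X reference positions at `t0`: length-2 vector or `2 x m` matrix (mm).
#' @param t time in seconds (scalar).
#' @return Positions `x(X, t)`, same shape as `X`.
#' @export
analytic_position <- function(model, X, t) {
  check_time(model, t)
  vec <- is.null(dim(X))
  X <- as_points(X)
  dtt <- t - model$time_span[1]
  U <- X - model$center
  x <- switch(model$kind,
    translation = X + model$params$velocity * dtt,
    rigid_rotation = model$center + rot2(model$params$omega * dtt) %*% U,
    uniform_scaling = model$center + scale_at(model, t) * U,
    simple_shear = rbind(X[1, ] + model$params$gamma * dtt * U[2, ], X[2, ]),
    incompressible_annulus = {
      st <- annulus_state(model, t)
      R2 <- colSums(U^2)
      if (any(R2 + st$lambda <= 0))
        stop("invalid model: annulus radius would become imaginary")
      r <- sqrt(R2 + st$lambda)
      th <- atan2(U[2, ], U[1, ]) + st$phi
      model$center + rbind(r * cos(th), r * sin(th))
    })
  if (vec) as.numeric(x) else x
}

scale_at <- function(model, t) {
  tau <- (t - model$time_span[1]) / diff(model$time_span)
  1 + (model$params$scale_end - 1) * tau
}

#' Analytic inverse motion map
#'
#' Maps deformed positions `x` at time `t` back to reference positions `X`.
#' Closed form exists for every model kind.
#'
#' @inheritParams analytic_position
#' @param x deformed positions: length-2 vector or `2 x m` matrix (mm).
#' @return Reference positions `X`, same shape as `x`.
#' @export
analytic_inverse_position <- function(model, x, t) {
  check_time(model, t)
  vec <- is.null(dim(x))
  x <- as_points(x)
  dtt <- t - model$time_span[1]
  U <- x - model$center
  X <- switch(model$kind,
    translation = x - model$params$velocity * dtt,
    rigid_rotation = model$center + rot2(-model$params$omega * dtt) %*% U,
    uniform_scaling = model$center + U / scale_at(model, t),
    simple_shear = rbind(x[1, ] - model$params$gamma * dtt * U[2, ], x[2, ]),
    incompressible_annulus = {
      st <- annulus_state(model, t)
      r2 <- colSums(U^2)
      R2 <- r2 - st$lambda
      if (any(R2 < 0))
        stop("invalid model: inverse annulus radius would become imaginary")
      R <- sqrt(R2)
      Th <- atan2(U[2, ], U[1, ]) - st$phi
      model$center + rbind(R * cos(Th), R * sin(Th))
    })
  if (vec) as.numeric(X) else X
}

#' Ground-truth deformation gradient of a phantom model
#'
#' Returns the Jacobian `F(t, t0) = dx/dX` of the motion map at reference
#' position(s) `X`. For a single point a `2 x 2` matrix; for a `2 x m`
#' matrix of points a `2 x 2 x m` array.
#'
#' @inheritParams analytic_position
#' @return `2 x 2` matrix or `2 x 2 x m` array (dimensionless).
#' @export
analytic_deformation <- function(model, X, t) {
  check_time(model, t)
  vec <- is.null(dim(X))
  X <- as_points(X)
  m <- ncol(X)
  dtt <- t - model$time_span[1]
  Fs <- switch(model$kind,
    translation = array(diag(2), c(2, 2, m)),
    rigid_rotation = array(rot2(model$params$omega * dtt), c(2, 2, m)),
    uniform_scaling = array(diag(2) * scale_at(model, t), c(2, 2, m)),
    simple_shear = array(matrix(c(1, 0, model$params$gamma * dtt, 1), 2, 2),
                         c(2, 2, m)),
    incompressible_annulus = {
      st <- annulus_state(model, t)
      U <- X - model$center
      R <- sqrt(colSums(U^2))
      if (any(R^2 + st$lambda <= 0))
        stop("invalid model: annulus radius would become imaginary")
      r <- sqrt(R^2 + st$lambda)
      Th <- atan2(U[2, ], U[1, ])
      th <- Th + st$phi
      out <- array(0, c(2, 2, m))
      # F = (dr/dR) e_r e_R^T + (r/R) e_th e_Th^T, dr/dR = R/r
      cR <- cos(Th); sR <- sin(Th); ct <- cos(th); s_t <- sin(th)
      a <- R / r; b <- r / R
      out[1, 1, ] <- a * ct * cR + b * s_t * sR
      out[1, 2, ] <- a * ct * sR - b * s_t * cR
      out[2, 1, ] <- a * s_t * cR - b * ct * sR
      out[2, 2, ] <- a * s_t * sR + b * ct * cR
      out
    })
  if (vec) Fs[, , 1] else Fs
}

#' Ground-truth Eulerian velocity and velocity gradient
#'
#' Evaluates the velocity field `v(x, t)` and its spatial gradient
#' `L = dv/dx` at deformed-domain positions `x`. Consistent with
#' `dF/dt = L F` at matching material points.
#'
#' @inheritParams analytic_inverse_position
#' @return For a single point, `list(v = <2-vector mm/s>, L = <2x2 1/s>)`;
#'   for `2 x m` points, `list(v = 2 x m, L = 2 x 2 x m)`.
#' @export
analytic_velocity_gradient <- function(model, x, t) {
  check_time(model, t)
  vec <- is.null(dim(x))
  x <- as_points(x)
  m <- ncol(x)
  U <- x - model$center
  J <- matrix(c(0, 1, -1, 0), 2, 2)
  out <- switch(model$kind,
    translation = list(v = matrix(model$params$velocity, 2, m),
                       L = array(0, c(2, 2, m))),
    rigid_rotation = list(v = model$params$omega * J %*% U,
                          L = array(model$params$omega * J, c(2, 2, m))),
    uniform_scaling = {
      # s(t) linear ramp: ds/dt = (scale_end - 1) / T
      a <- (model$params$scale_end - 1) / diff(model$time_span) / scale_at(model, t)
      list(v = a * U, L = array(a * diag(2), c(2, 2, m)))
    },
    simple_shear = {
      g <- model$params$gamma
      L1 <- matrix(c(0, 0, g, 0), 2, 2)
      list(v = rbind(g * U[2, ], rep(0, m)), L = array(L1, c(2, 2, m)))
    },
    incompressible_annulus = {
      st <- annulus_state(model, t)
      rho2 <- colSums(U^2)
      if (any(rho2 - st$lambda < 0))
        stop("invalid model: position outside deformed domain")
      v <- 0.5 * st$dlambda * U / rep(rho2, each = 2) + st$dphi * (J %*% U)
      L <- array(0, c(2, 2, m))
      n1 <- U[1, ] / sqrt(rho2); n2 <- U[2, ] / sqrt(rho2)
      c0 <- 0.5 * st$dlambda / rho2
      L[1, 1, ] <- c0 * (1 - 2 * n1^2)
      L[2, 2, ] <- c0 * (1 - 2 * n2^2)
      L[1, 2, ] <- -2 * c0 * n1 * n2 - st$dphi
      L[2, 1, ] <- -2 * c0 * n1 * n2 + st$dphi
      list(v = v, L = L)
    })
  if (vec) list(v = as.numeric(out$v), L = out$L[, , 1]) else out
}

#' Ground-truth Lagrangian strain of a phantom model
#'
#' Convenience oracle: `E = (F^T F - I) / 2` with `F` from
#' [analytic_deformation()] (Cartesian frames, identity metrics).
#'
#' @inheritParams analytic_position
#' @return `2 x 2` matrix or `2 x 2 x m` array.
#' @export
analytic_strain <- function(model, X, t) {
  Fs <- analytic_deformation(model, X, t)
  if (length(dim(Fs)) == 2) return(0.5 * (crossprod(Fs) - diag(2)))
  out <- Fs
  for (i in seq_len(dim(Fs)[3]))
    out[, , i] <- 0.5 * (crossprod(Fs[, , i]) - diag(2))
  out
}

#' Tag pattern specification
#'
#' Describes one sinusoidal SPAMM tag pattern painted on the tissue at the
#' reference time and passively advected by the motion.
#'
#' @param wave_vector tag wave vector in rad/mm (length 2, nonzero).
#' @param modulation_depth modulation depth in `[0, 1]`.
#' @param noise_sd standard deviation of additive zero-mean Gaussian pixel
#'   noise (intensity units; the noise-free image lies in `[0, 1]`).
#' @param fading_rate exponential tag-fading rate in 1/s (0 disables fading).
#' @return An object of class `tag_spec`.
#' @export
tag_spec <- function(wave_vector, modulation_depth = 1, noise_sd = 0,
                     fading_rate = 0) {
  stopifnot(length(wave_vector) == 2, any(wave_vector != 0),
            modulation_depth >= 0, modulation_depth <= 1,
            noise_sd >= 0, fading_rate >= 0)
  structure(list(wave_vector = as.numeric(wave_vector),
                 modulation_depth = modulation_depth,
                 noise_sd = noise_sd, fading_rate = fading_rate),
            class = "tag_spec")
}

#' Render a tagged image sequence from a phantom model
#'
#' Frame `k` holds
#' `I(x, t_k) = b(t_k) * (1 + m cos(k_w . X(x, t_k))) / 2 + noise`, where
#' `X(x, t)` is the inverse motion map, `m` the modulation depth and
#' `b(t) = exp(-fading_rate * (t - t0))`: the tag crests are material and
#' move with the tissue.
#'
#' @param model a [phantom_model()].
#' @param tag a [tag_spec()].
#' @param nx,ny grid size in pixels.
#' @param spacing pixel spacing in mm.
#' @param n_frames number of frames (>= 2), spanning `model$time_span`
#'   uniformly.
#' @return A [tag_sequence()].
#' @export
render_tagged_sequence <- function(model, tag, nx = 128, ny = 128,
                                   spacing = 1, n_frames = 21) {
  stopifnot(inherits(model, "phantom_model"), inherits(tag, "tag_spec"),
            n_frames >= 2)
  spacing <- rep_len(spacing, 2L)
  xc <- pixel_coords(nx, ny, spacing)
  pts <- rbind(as.numeric(xc$x1), as.numeric(xc$x2))
  dt <- diff(model$time_span) / (n_frames - 1)
  t0 <- model$time_span[1]
  frames <- array(0, c(nx, ny, n_frames))
  for (k in seq_len(n_frames)) {
    tk <- t0 + (k - 1) * dt
    X <- analytic_inverse_position(model, pts, tk)
    ph <- tag$wave_vector[1] * X[1, ] + tag$wave_vector[2] * X[2, ]
    b <- exp(-tag$fading_rate * (tk - t0))
    img <- b * 0.5 * (1 + tag$modulation_depth * cos(ph))
    if (tag$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, tag$noise_sd)
    frames[, , k] <- img
  }
  tag_sequence(frames, spacing = spacing, dt = dt, t0 = t0)
}

#' Default contracting-and-twisting annulus phantom
#'
#' The standard validation setup: a 128 x 128 grid at 1 mm spacing, a
#' myocardial annulus with inner/outer radii 25/45 mm centered on the grid,
#' and 21 frames over a simulated systole (0.5 s) during which the
#' area-preserving radial shift ramps to -150 mm^2 and the twist to
#' 0.15 rad (half-cosine ramps). Two orthogonal tag patterns with a 7 mm
#' tag period are rendered.
#'
#' @param nx,ny,spacing,n_frames grid and sampling, see
#'   [render_tagged_sequence()].
#' @param lambda_end,phi_end end-systolic radial-shift (mm^2) and twist (rad).
#' @param tag_period tag period in mm.
#' @param noise_sd,fading_rate passed to [tag_spec()].
#' @param t_end simulated systole duration in seconds.
#' @return List with the `model`, the two rendered `sequences` (x- and
#'   y-encoded), the ROI `mask`, the annulus `center` (mm), radii
#'   `r_inner`, `r_outer`, and the two `tags`.
#' @export
annulus_phantom <- function(nx = 128, ny = 128, spacing = 1, n_frames = 21,
                            lambda_end = -150, phi_end = 0.15,
                            tag_period = 7, noise_sd = 0, fading_rate = 0,
                            t_end = 0.5) {
  center <- c((nx - 1) / 2, (ny - 1) / 2) * rep_len(spacing, 2L)
  model <- phantom_model("incompressible_annulus", center = center,
                         time_span = c(0, t_end),
                         lambda_end = lambda_end, phi_end = phi_end)
  kw <- 2 * pi / tag_period
  tags <- list(tag_spec(c(kw, 0), noise_sd = noise_sd, fading_rate = fading_rate),
               tag_spec(c(0, kw), noise_sd = noise_sd, fading_rate = fading_rate))
  seqs <- lapply(tags, function(tg)
    render_tagged_sequence(model, tg, nx, ny, spacing, n_frames))
  mask <- annulus_mask(nx, ny, spacing, center, 25, 45)
  list(model = model, sequences = seqs, mask = mask, center = center,
       r_inner = 25, r_outer = 45, tags = tags)
}
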