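# Shared fixtures, memoised so expensive renders happen once per test run.

.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, force(expr), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

# Small annulus phantom (64 x 64, 5 frames) for motion-stage tests: mask
# radii 14-26 mm about the grid center, modest contraction and twist.
small_annulus <- function(noise_sd = 0, n_frames = 5, seed = 42) {
  set.seed(seed)
  center <- c(31.5, 31.5)
  model <- phantom_model("incompressible_annulus", center = center,
                         time_span = c(0, 0.5),
                         lambda_end = -40, phi_end = 0.1)
  kw <- 2 * pi / 7
  s1 <- render_tagged_sequence(model, tag_spec(c(kw, 0), noise_sd = noise_sd),
                               64, 64, 1, n_frames)
  s2 <- render_tagged_sequence(model, tag_spec(c(0, kw), noise_sd = noise_sd),
                               64, 64, 1, n_frames)
  mask <- annulus_mask(64, 64, 1, center, 14, 26)
  list(model = model, s1 = s1, s2 = s2, mask = mask, center = center)
}

# Phase pair of a noise-free phantom model on a small grid.
phase_pair <- function(model, nx = 64, ny = 64, n_frames = 3,
                       tag_period = 7) {
  kw <- 2 * pi / tag_period
  s1 <- render_tagged_sequence(model, tag_spec(c(kw, 0)), nx, ny, 1, n_frames)
  s2 <- render_tagged_sequence(model, tag_spec(c(0, kw)), nx, ny, 1, n_frames)
  list(p1 = bandpass_harmonic(s1, detect_carrier(s1)),
       p2 = bandpass_harmonic(s2, detect_carrier(s2)),
       s1 = s1, s2 = s2)
}

# Random invertible 2x2 matrix with entries in [-1, 1] and |det| > 0.1.
random_invertible <- function() {
  repeat {
    F <- matrix(stats::runif(4, -1, 1), 2, 2)
    if (abs(det(F)) > 0.1) return(F)
  }
}

# Spatially constant velocity-gradient field sequence (one field per
# interval) on a tiny grid, from a list of 2x2 matrices.
constant_vg_fields <- function(Ls, nx = 8, ny = 8, spacing = 1,
                               v = c(0, 0)) {
  lapply(Ls, function(L) {
    varr <- array(0, c(nx, ny, 2))
    varr[, , 1] <- v[1]; varr[, , 2] <- v[2]
    Larr <- array(0, c(nx, ny, 2, 2))
    for (i in 1:2) for (j in 1:2) Larr[, , i, j] <- L[i, j]
    list(v = varr, L = Larr, validity = matrix(TRUE, nx, ny),
         scale = matrix(0, nx, ny), cond = matrix(1, nx, ny),
         spacing = rep(spacing, 2))
  })
}

# 90-degree counterclockwise rotation of a square image about its center.
rot90_img <- function(m) t(m)[nrow(m):1, , drop = FALSE]
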