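test_that("a stationary pattern yields the zero solution", {
  pp <- fixture("pp_still", {
    m <- phantom_model("translation", velocity = c(0, 0), time_span = c(0, 1))
    phase_pair(m, 64, 64, 3)
  })
  sys <- build_ofce_system(list(pp$p1, pp$p2), c(32, 32), 1, scale = 5)
  expect_true(sys$buildable)
  expect_equal(sys$b, rep(0, 6), tolerance = 1e-10)
  sol <- solve(sys$A, sys$b)
  expect_equal(sol, rep(0, 6), tolerance = 1e-9)
})

test_that("scale selection minimizes the condition number with smaller-scale ties", {
  A_good <- diag(6); A_bad <- diag(c(1, 1, 1, 1, 1, 1e-9))
  sys <- function(A) list(A = A, b = rep(1, 6), buildable = TRUE)
  # only one finite-condition scale survives the ceiling
  out <- select_scale(list(sys(A_bad), sys(A_good), sys(A_bad)),
                      scales = c(1, 2, 3))
  expect_equal(out$scale, 2)
  expect_equal(out$cond, 1)
  expect_equal(out$solution, rep(1, 6))
  # equal condition numbers: the smaller scale wins
  out <- select_scale(list(sys(2 * diag(6)), sys(diag(6))), scales = c(1, 2))
  expect_equal(out$scale, 1)
  # everything unbuildable or singular: NULL
  out <- select_scale(list(list(A = diag(6), b = rep(0, 6), buildable = FALSE),
                           sys(matrix(0, 6, 6))), scales = c(1, 2))
  expect_null(out)
  expect_gte(select_scale(list(sys(A_good)), 1)$cond, 1)
})

test_that("translation is recovered within 5% with negligible gradients", {
  v_true <- c(1.2, -0.8)
  pp <- fixture("pp_trans", {
    m <- phantom_model("translation", velocity = c(1.2, -0.8),
                       time_span = c(0, 1))
    phase_pair(m, 64, 64, 3)
  })
  mask <- matrix(FALSE, 64, 64); mask[23:42, 23:42] <- TRUE
  vg <- fixture("vg_trans", estimate_velocity_gradient(
    pp$p1, pp$p2, default_scale_sweep(7), mask))
  expect_length(vg, 2)
  f <- vg[[1]]
  sel <- f$validity
  expect_gt(mean(sel[mask]), 0.9)
  vmed <- c(median(f$v[, , 1][sel]), median(f$v[, , 2][sel]))
  expect_lt(sqrt(sum((vmed - v_true)^2)) / sqrt(sum(v_true^2)), 0.05)
  Lmax <- max(abs(median(f$L[, , 1, 1][sel])), abs(median(f$L[, , 1, 2][sel])),
              abs(median(f$L[, , 2, 1][sel])), abs(median(f$L[, , 2, 2][sel])))
  expect_lt(Lmax, 0.05)
  expect_true(all(f$cond[sel] >= 1))
  expect_true(all(is.finite(f$L[, , , ][rep(sel, 4)])))
})

test_that("a rigid rotation recovers the spin tensor within 10%", {
  w <- 0.3
  pp <- fixture("pp_rot", {
    m <- phantom_model("rigid_rotation", omega = 0.3, center = c(31.5, 31.5),
                       time_span = c(0, 0.5))
    phase_pair(m, 64, 64, 3)
  })
  mask <- annulus_mask(64, 64, 1, c(31.5, 31.5), 14, 26)
  vg <- estimate_velocity_gradient(pp$p1, pp$p2, default_scale_sweep(7), mask)
  f <- vg[[1]]
  sel <- f$validity
  L_true <- matrix(c(0, w, -w, 0), 2, 2)
  for (i in 1:2) for (j in 1:2) {
    est <- median(f$L[, , i, j][sel])
    expect_lt(abs(est - L_true[i, j]), 0.1 * w)
  }
})

test_that("the annulus velocity gradient comes out nearly trace-free", {
  ann <- fixture("ann_small", small_annulus())
  vg <- fixture("vg_ann", {
    p1 <- bandpass_harmonic(ann$s1, detect_carrier(ann$s1))
    p2 <- bandpass_harmonic(ann$s2, detect_carrier(ann$s2))
    estimate_velocity_gradient(p1, p2, default_scale_sweep(7), ann$mask)
  })
  f <- vg[[2]]
  sel <- f$validity
  trL <- abs(f$L[, , 1, 1][sel] + f$L[, , 2, 2][sel])
  frob <- sqrt(f$L[, , 1, 1][sel]^2 + f$L[, , 1, 2][sel]^2 +
               f$L[, , 2, 1][sel]^2 + f$L[, , 2, 2][sel]^2)
  expect_lt(median(trL), 0.1 * median(frob))
})

test_that("frame-pair count and error handling follow the contracts", {
  pp <- fixture("pp_still", {
    m <- phantom_model("translation", velocity = c(0, 0), time_span = c(0, 1))
    phase_pair(m, 64, 64, 3)
  })
  # T = 2 input gives exactly one field
  p1s <- pp$p1; p2s <- pp$p2
  p1s$complex_frames <- p1s$complex_frames[, , 1:2]
  p1s$validity <- p1s$validity[, , 1:2]
  p2s$complex_frames <- p2s$complex_frames[, , 1:2]
  p2s$validity <- p2s$validity[, , 1:2]
  mask <- matrix(FALSE, 64, 64); mask[28:36, 28:36] <- TRUE
  expect_length(estimate_velocity_gradient(p1s, p2s,
                                           default_scale_sweep(7), mask), 1)
  expect_error(estimate_velocity_gradient(p1s, p2s, default_scale_sweep(7),
                                          matrix(FALSE, 64, 64)), "empty")
  expect_error(estimate_velocity_gradient(p1s, p1s, default_scale_sweep(7),
                                          mask), "independent")
})

test_that("scale sweeps validate their grid", {
  expect_error(scale_sweep(c(2, 1, 3)), "increasing")
  expect_error(scale_sweep(c(1, 2)), "length")
  sw <- default_scale_sweep(7)
  expect_length(sw$scales, 8)
  expect_equal(sw$scales[1], 3.5)
  expect_equal(sw$scales[8], 21)
})

test_that("estimation is equivariant under a quarter-turn of the scene", {
  ann <- fixture("ann_small", small_annulus())
  vg <- fixture("vg_ann", {
    p1 <- bandpass_harmonic(ann$s1, detect_carrier(ann$s1))
    p2 <- bandpass_harmonic(ann$s2, detect_carrier(ann$s2))
    estimate_velocity_gradient(p1, p2, default_scale_sweep(7), ann$mask)
  })
  rot_seq <- function(s) {
    fr <- array(0, dim(s$frames))
    for (k in seq_len(dim(s$frames)[3])) fr[, , k] <- rot90_img(s$frames[, , k])
    tag_sequence(fr, s$spacing, s$dt, s$t0)
  }
  s1r <- rot_seq(ann$s1); s2r <- rot_seq(ann$s2)
  maskr <- rot90_img(ann$mask)
  vgr <- estimate_velocity_gradient(bandpass_harmonic(s1r, detect_carrier(s1r)),
                                    bandpass_harmonic(s2r, detect_carrier(s2r)),
                                    default_scale_sweep(7), maskr)
  R <- matrix(c(0, 1, -1, 0), 2, 2) # +90 degrees
  f <- vg[[1]]; fr <- vgr[[1]]
  n <- 64
  # pixel (i, j) maps to (n + 1 - j, i)
  idx <- which(ann$mask & f$validity, arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), by = 7), , drop = FALSE]
  dv <- dL <- c()
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    ir <- n + 1 - j; jr <- i
    if (!fr$validity[ir, jr]) next
    v0 <- c(f$v[i, j, 1], f$v[i, j, 2])
    v1 <- c(fr$v[ir, jr, 1], fr$v[ir, jr, 2])
    dv <- c(dv, max(abs(v1 - R %*% v0)))
    L0 <- matrix(c(f$L[i, j, 1, 1], f$L[i, j, 2, 1],
                   f$L[i, j, 1, 2], f$L[i, j, 2, 2]), 2, 2)
    L1 <- matrix(c(fr$L[ir, jr, 1, 1], fr$L[ir, jr, 2, 1],
                   fr$L[ir, jr, 1, 2], fr$L[ir, jr, 2, 2]), 2, 2)
    dL <- c(dL, max(abs(L1 - R %*% L0 %*% t(R))))
  }
  expect_gt(length(dv), 50)
  expect_lt(median(dv), 1e-3)
  expect_lt(median(dL), 1e-3)
})

test_that("gradient recovery error decreases with the noise level", {
  w <- 0.4
  err_at <- function(noise_sd) {
    set.seed(123)
    m <- phantom_model("rigid_rotation", omega = w, center = c(31.5, 31.5),
                       time_span = c(0, 0.5))
    kw <- 2 * pi / 7
    s1 <- render_tagged_sequence(m, tag_spec(c(kw, 0), noise_sd = noise_sd),
                                 64, 64, 1, 3)
    s2 <- render_tagged_sequence(m, tag_spec(c(0, kw), noise_sd = noise_sd),
                                 64, 64, 1, 3)
    mask <- annulus_mask(64, 64, 1, c(31.5, 31.5), 16, 24)
    vg <- estimate_velocity_gradient(bandpass_harmonic(s1, c(kw, 0)),
                                     bandpass_harmonic(s2, c(0, kw)),
                                     default_scale_sweep(7), mask)
    f <- vg[[1]]
    sel <- f$validity
    L_true <- matrix(c(0, w, -w, 0), 2, 2)
    e <- 0
    for (i in 1:2) for (j in 1:2)
      e <- max(e, abs(median(f$L[, , i, j][sel]) - L_true[i, j]))
    e
  }
  errs <- vapply(c(0.1, 0.05, 0.01, 0), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("moderate noise still leaves most pixels well conditioned", {
  ann <- fixture("ann_noisy", small_annulus(noise_sd = 0.05))
  p1 <- bandpass_harmonic(ann$s1, detect_carrier(ann$s1))
  p2 <- bandpass_harmonic(ann$s2, detect_carrier(ann$s2))
  vg <- estimate_velocity_gradient(p1, p2, default_scale_sweep(7), ann$mask)
  f <- vg[[1]]
  conds <- f$cond[ann$mask]
  conds <- conds[is.finite(conds)]
  expect_gt(mean(conds < 1e3), 0.95)
})
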