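#' Scale sweep for conditioning-driven scale selection
#'
#' Ordered list of spatial Gaussian-derivative scales tried at every pixel;
#' the scale whose local optic-flow system is best conditioned wins.
#'
#' @param scales strictly increasing vector of at least 3 scales (mm).
#' @param temporal_scale temporal support in frames (currently fixed at 1:
#'   derivatives couple consecutive frame pairs only).
#' @return An object of class `scale_sweep`.
#' @export
scale_sweep <- function(scales, temporal_scale = 1) {
  stopifnot("at least 3 scales required (length)" = length(scales) >= 3,
            "scales must be strictly increasing" = all(diff(scales) > 0),
            "scales must be positive" = all(scales > 0))
  structure(list(scales = as.numeric(scales),
                 temporal_scale = temporal_scale),
            class = "scale_sweep")
}

#' Default scale sweep from the tag spacing
#'
#' Eight log-spaced scales from half to three times the tag spacing.
#'
#' @param tag_spacing tag period in mm (e.g. `2 * pi / |carrier|`).
#' @param n number of scales.
#' @param range multiplicative range relative to `tag_spacing`.
#' @return A [scale_sweep()].
#' @export
default_scale_sweep <- function(tag_spacing, n = 8,
                                range = c(0.5, 3)) {
  scale_sweep(exp(seq(log(range[1] * tag_spacing),
                      log(range[2] * tag_spacing), length.out = n)))
}

## Per-frame phase-derivative stack of one phase sequence at one scale.
phase_stack <- function(pseq, frame, scale) {
  d <- w_derivatives(pseq, frame, scale, second = TRUE)
  pd <- phase_derivs_from_w(d, pseq$carrier, second = TRUE)
  pd$w <- d$w
  pd
}

## Assemble the 6x6 OFCE systems of one frame pair at one scale for a set
## of pixels (linear indices into the image). Unknown order:
## (v1, v2, L11, L12, L21, L22), with L[a, j] = d v_a / d x_j.
## Equations per phase p: the optic-flow constraint phi_t + v . grad phi = 0
## with the local model v(x) = v0 + L (x - x0), and its two first spatial
## derivatives, all evaluated at x0:
##   phi_t + v0 . grad phi = 0
##   phi_tj + sum_a L[a,j] phi_a + sum_a v0_a phi_ja = 0   (j = 1, 2)
ofce_pair_systems <- function(stk1_a, stk1_b, stk2_a, stk2_b, dt, idx,
                              amp_thresh) {
  npx <- length(idx)
  A <- array(0, c(6, 6, npx))
  b <- matrix(0, 6, npx)
  ok <- rep(TRUE, npx)
  row0 <- 0L
  for (p in 1:2) {
    sa <- if (p == 1) stk1_a else stk2_a
    sb <- if (p == 1) stk1_b else stk2_b
    phi_t <- Arg(sb$w[idx] * Conj(sa$w[idx])) / dt
    av <- function(nm) (sa[[nm]][idx] + sb[[nm]][idx]) / 2
    phi_x <- av("phi_x"); phi_y <- av("phi_y")
    phi_xx <- av("phi_xx"); phi_xy <- av("phi_xy"); phi_yy <- av("phi_yy")
    phi_tx <- (sb$phi_x[idx] - sa$phi_x[idx]) / dt
    phi_ty <- (sb$phi_y[idx] - sa$phi_y[idx]) / dt
    ok <- ok & sa$amp2[idx] > amp_thresh[p] & sb$amp2[idx] > amp_thresh[p]
    A[row0 + 1, 1, ] <- phi_x; A[row0 + 1, 2, ] <- phi_y
    b[row0 + 1, ] <- -phi_t
    A[row0 + 2, 1, ] <- phi_xx; A[row0 + 2, 2, ] <- phi_xy
    A[row0 + 2, 3, ] <- phi_x;  A[row0 + 2, 5, ] <- phi_y
    b[row0 + 2, ] <- -phi_tx
    A[row0 + 3, 1, ] <- phi_xy; A[row0 + 3, 2, ] <- phi_yy
    A[row0 + 3, 4, ] <- phi_x;  A[row0 + 3, 6, ] <- phi_y
    b[row0 + 3, ] <- -phi_ty
    row0 <- row0 + 3L
  }
  ok <- ok & apply(is.finite(A), 3, all) & colSums(!is.finite(b)) == 0
  list(A = A, b = b, buildable = ok)
}

amp_threshold <- function(pseq) {
  (1e-6 * max(Mod(pseq$complex_frames[, , 1]), .Machine$double.eps))^2
}

#' Build the local optic-flow system at one pixel
#'
#' Assembles the 6 x 6 linear system for the unknowns
#' `(v1, v2, L11, L12, L21, L22)` of the first-order local motion model
#' `v(x) = v0 + L (x - x0)` inserted into the optic-flow constraint
#' `phi_t + v . grad phi = 0` of both phase images, using the constraint
#' and its two first spatial Gaussian-derivative equations at the given
#' scale (3 equations per phase).
#'
#' @param phases list of the two `phase_sequence` objects (orthogonal tag
#'   directions).
#' @param pixel integer pixel indices `c(i, j)` (1-based).
#' @param frame frame-pair index `k` (couples frames `k` and `k + 1`).
#' @param scale spatial derivative scale in mm.
#' @return List with `A` (6 x 6), `b` (length 6) and `buildable` (logical;
#'   `FALSE` when the phase is undefined within the filter support).
#' @export
build_ofce_system <- function(phases, pixel, frame, scale) {
  stopifnot(length(phases) == 2, inherits(phases[[1]], "phase_sequence"))
  p1 <- phases[[1]]; p2 <- phases[[2]]
  stk1a <- phase_stack(p1, frame, scale)
  stk1b <- phase_stack(p1, frame + 1L, scale)
  stk2a <- phase_stack(p2, frame, scale)
  stk2b <- phase_stack(p2, frame + 1L, scale)
  d <- dim(p1$complex_frames)
  idx <- (pixel[2] - 1L) * d[1] + pixel[1]
  sys <- ofce_pair_systems(stk1a, stk1b, stk2a, stk2b, p1$dt, idx,
                           c(amp_threshold(p1), amp_threshold(p2)))
  margin <- ceiling(3 * scale / p1$spacing[1])
  inb <- pixel[1] > margin & pixel[1] <= d[1] - margin &
         pixel[2] > margin & pixel[2] <= d[2] - margin
  list(A = sys$A[, , 1], b = sys$b[, 1],
       buildable = sys$buildable[1] && inb)
}

#' Select the best-conditioned scale and solve
#'
#' Among a family of local systems over a scale sweep, returns the
#' solution at the scale minimizing the 2-norm condition number of the
#' system matrix; ties break toward the smaller scale. Selection is per
#' pixel and independent across pixels.
#'
#' @param systems list over scales of `list(A, b, buildable)` entries
#'   ([build_ofce_system()] outputs); unbuildable or `NULL` entries are
#'   skipped.
#' @param scales the scale values (mm), same length as `systems`.
#' @param max_cond condition-number ceiling beyond which a solution is
#'   rejected rather than clipped (default `1e6`).
#' @return List with `scale`, `solution` (length 6), `cond`; or `NULL` if
#'   every system is unbuildable or singular.
#' @export
select_scale <- function(systems, scales, max_cond = 1e6) {
  best <- NULL
  for (s in seq_along(systems)) {
    sys <- systems[[s]]
    if (is.null(sys) || !isTRUE(sys$buildable)) next
    sv <- svd(sys$A)
    if (sv$d[6] <= 0) next
    cond <- sv$d[1] / sv$d[6]
    if (!is.finite(cond) || cond > max_cond) next
    if (is.null(best) || cond < best$cond) {
      x <- sv$v %*% (crossprod(sv$u, sys$b) / sv$d)
      best <- list(scale = scales[s], solution = as.numeric(x), cond = cond)
    }
  }
  best
}

#' Estimate the dense velocity gradient tensor field
#'
#' For every consecutive frame pair and every masked pixel, builds the
#' first-order optic-flow system from the two harmonic-phase sequences at
#' each scale of the sweep, selects the best-conditioned scale per pixel,
#' and solves for the local velocity `v` and velocity gradient tensor `L`.
#' Pixels whose best condition number exceeds `max_cond`, whose phase is
#' undefined, or whose filter support (3 scales) reaches the image border
#' at every scale are marked invalid.
#'
#' @param phase1,phase2 `phase_sequence` objects with linearly independent
#'   carriers (see [bandpass_harmonic()]).
#' @param sweep a [scale_sweep()]; default derives from the mean tag
#'   spacing of the two carriers.
#' @param mask logical ROI matrix; estimation is restricted to it.
#' @param max_cond condition-number ceiling (default `1e6`).
#' @return List of `T - 1` velocity-gradient fields; each is a list with
#'   `v` (`nx x ny x 2`, mm/s), `L` (`nx x ny x 2 x 2`, 1/s), `scale`
#'   (mm), `cond`, `validity` (logical), `spacing`.
#' @export
estimate_velocity_gradient <- function(phase1, phase2, sweep = NULL,
                                       mask = NULL, max_cond = 1e6) {
  stopifnot(inherits(phase1, "phase_sequence"),
            inherits(phase2, "phase_sequence"))
  d <- dim(phase1$complex_frames)
  if (!all(dim(phase2$complex_frames) == d))
    stop("the two phase sequences must have identical dimensions")
  if (abs(sum(phase1$carrier * phase2$carrier)) /
      sqrt(sum(phase1$carrier^2) * sum(phase2$carrier^2)) > 0.99)
    stop("carriers of the two phase sequences are not independent")
  Tn <- d[3]
  if (Tn < 2) stop("at least two frames are required")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!any(mask)) stop("ROI mask is empty")
  if (is.null(sweep)) {
    tagsp <- mean(2 * pi / c(sqrt(sum(phase1$carrier^2)),
                             sqrt(sum(phase2$carrier^2))))
    sweep <- default_scale_sweep(tagsp)
  }
  scales <- sweep$scales
  idx_all <- which(mask)
  npx <- length(idx_all)
  ij <- arrayInd(idx_all, d[1:2])
  athr <- c(amp_threshold(phase1), amp_threshold(phase2))
  npair <- Tn - 1L
  best_cond <- matrix(Inf, npx, npair)
  best_scale <- matrix(NA_real_, npx, npair)
  best_sol <- array(NA_real_, c(6, npx, npair))
  for (s in seq_along(scales)) {
    sc <- scales[s]
    margin <- ceiling(3 * sc / phase1$spacing[1])
    inb <- ij[, 1] > margin & ij[, 1] <= d[1] - margin &
           ij[, 2] > margin & ij[, 2] <= d[2] - margin
    if (!any(inb)) next
    stks1 <- lapply(seq_len(Tn), function(f) phase_stack(phase1, f, sc))
    stks2 <- lapply(seq_len(Tn), function(f) phase_stack(phase2, f, sc))
    for (k in seq_len(npair)) {
      sys <- ofce_pair_systems(stks1[[k]], stks1[[k + 1]],
                               stks2[[k]], stks2[[k + 1]],
                               phase1$dt, idx_all, athr)
      cand <- which(inb & sys$buildable)
      for (q in cand) {
        sv <- svd(sys$A[, , q])
        if (sv$d[6] <= 0) next
        cond <- sv$d[1] / sv$d[6]
        if (!is.finite(cond) || cond > max_cond) next
        if (cond < best_cond[q, k]) {
          best_cond[q, k] <- cond
          best_scale[q, k] <- sc
          best_sol[, q, k] <- sv$v %*% (crossprod(sv$u, sys$b[, q]) / sv$d)
        }
      }
    }
  }
  lapply(seq_len(npair), function(k) {
    v <- array(NA_real_, c(d[1], d[2], 2))
    L <- array(NA_real_, c(d[1], d[2], 2, 2))
    scl <- matrix(NA_real_, d[1], d[2])
    cnd <- matrix(NA_real_, d[1], d[2])
    val <- matrix(FALSE, d[1], d[2])
    okq <- is.finite(best_cond[, k])
    pii <- idx_all[okq]
    v[, , 1][pii] <- best_sol[1, okq, k]
    v[, , 2][pii] <- best_sol[2, okq, k]
    L[, , 1, 1][pii] <- best_sol[3, okq, k]
    L[, , 1, 2][pii] <- best_sol[4, okq, k]
    L[, , 2, 1][pii] <- best_sol[5, okq, k]
    L[, , 2, 2][pii] <- best_sol[6, okq, k]
    scl[pii] <- best_scale[okq, k]
    cnd[pii] <- best_cond[okq, k]
    val[pii] <- TRUE
    list(v = v, L = L, scale = scl, cond = cnd, validity = val,
         spacing = phase1$spacing)
  })
}
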