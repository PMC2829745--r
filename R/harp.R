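#' Detect the tag carrier frequency of a tagged sequence
#'
#' Finds the largest non-DC peak of the magnitude spectrum of the first
#' frame and refines it to sub-bin precision with a local quadratic fit of
#' the log-magnitude along each frequency axis. The peak is reported in
#' the half-plane with positive first component (or positive second
#' component on the axis), fixing the sign ambiguity of a real-valued
#' pattern.
#'
#' @param seq a [tag_sequence()].
#' @return Carrier wave vector in rad/mm (length 2).
#' @export
detect_carrier <- function(seq) {
  stopifnot(inherits(seq, "tag_sequence"))
  img <- seq$frames[, , 1]
  n1 <- nrow(img); n2 <- ncol(img)
  S <- stats::fft(img)
  mag <- Mod(S)
  w1 <- fft_omega(n1, seq$spacing[1])
  w2 <- fft_omega(n2, seq$spacing[2])
  # exclude the DC bin and its immediate neighbours (spectral leakage of
  # the mean), and restrict to the positive half-plane
  near_dc <- outer(abs(seq_len(n1) - 1) <= 1 | abs(seq_len(n1) - 1) >= n1 - 1,
                   abs(seq_len(n2) - 1) <= 1 | abs(seq_len(n2) - 1) >= n2 - 1,
                   `&`)
  half <- outer(w1 > 0, rep(TRUE, n2), `&`) | outer(w1 == 0, w2 > 0, `&`)
  cand <- mag
  cand[near_dc | !half] <- 0
  med <- stats::median(mag[!near_dc])
  pk <- unname(which(cand == max(cand), arr.ind = TRUE)[1, ])
  # a genuine tag harmonic towers over the median AND concentrates a
  # substantial fraction of the non-DC spectral energy in one bin; broad-band
  # noise can exceed a bare 3x-median rule by order statistics alone
  if (max(cand) < 3 * med ||
      max(cand)^2 < 0.05 * sum(mag[!near_dc]^2))
    stop("no tag harmonic found: spectral peak below 3x median magnitude or not concentrated")
  refine <- function(i, n) {
    # quadratic sub-bin refinement on log magnitude along one axis
    im <- ((i - 2) %% n) + 1L; ip <- (i %% n) + 1L
    c(im, ip)
  }
  sub_bin <- function(lm, lp, l0) {
    # neighbours at numerical-noise level (exact integer period): no shift
    if (l0 - max(lm, lp) > log(1e6)) return(0)
    d <- lm - 2 * l0 + lp
    if (d >= 0) 0 else 0.5 * (lm - lp) / d
  }
  lg <- function(i, j) log(mag[i, j] + .Machine$double.xmin)
  nb1 <- refine(pk[1], n1); nb2 <- refine(pk[2], n2)
  d1 <- sub_bin(lg(nb1[1], pk[2]), lg(nb1[2], pk[2]), lg(pk[1], pk[2]))
  d2 <- sub_bin(lg(pk[1], nb2[1]), lg(pk[1], nb2[2]), lg(pk[1], pk[2]))
  k1 <- (pk[1] - 1 + d1); k2 <- (pk[2] - 1 + d2)
  if (k1 > (n1 - 1) / 2) k1 <- k1 - n1
  if (k2 > (n2 - 1) / 2) k2 <- k2 - n2
  c(2 * pi * k1 / (n1 * seq$spacing[1]),
    2 * pi * k2 / (n2 * seq$spacing[2]))
}

#' Extract the harmonic-phase image sequence by Fourier band-pass
#'
#' Multiplies the discrete Fourier transform of every frame by an
#' isotropic Gaussian window centered at `+carrier` (single side-band) and
#' inverse-transforms, yielding a complex image whose argument
#' approximates the material tag phase `k_w . X(x, t)` modulo 2 pi. Pixels
#' whose harmonic magnitude is negligible (phase undefined) are flagged in
#' a per-frame validity mask.
#'
#' @param seq a [tag_sequence()].
#' @param carrier carrier wave vector in rad/mm (e.g. from
#'   [detect_carrier()]).
#' @param filter_sd Gaussian window width in rad/mm; default
#'   `|carrier| / 4`, a standard HARP compromise between side-band
#'   separation and tolerance of deformation-induced spectral broadening.
#' @return An object of class `phase_sequence`: list with
#'   `complex_frames` (`nx x ny x T` complex), `validity`
#'   (`nx x ny x T` logical), `carrier`, `filter_sd`, `spacing`, `dt`,
#'   `t0`.
#' @export
bandpass_harmonic <- function(seq, carrier, filter_sd = NULL) {
  stopifnot(inherits(seq, "tag_sequence"), length(carrier) == 2)
  if (all(carrier == 0)) stop("carrier must be nonzero")
  nyq <- pi / seq$spacing
  if (any(abs(carrier) > nyq))
    stop("carrier outside the Nyquist range of the grid")
  if (is.null(filter_sd)) filter_sd <- sqrt(sum(carrier^2)) / 4
  stopifnot(filter_sd > 0)
  d <- dim(seq$frames)
  n1 <- d[1]; n2 <- d[2]; Tn <- d[3]
  w1 <- fft_omega(n1, seq$spacing[1])
  w2 <- fft_omega(n2, seq$spacing[2])
  W <- exp(-(outer((w1 - carrier[1])^2, (w2 - carrier[2])^2, `+`)) /
             (2 * filter_sd^2))
  z <- array(complex(real = 0), d)
  for (k in seq_len(Tn)) {
    S <- stats::fft(seq$frames[, , k])
    z[, , k] <- stats::fft(S * W, inverse = TRUE) / (n1 * n2)
  }
  # phase is defined where the harmonic magnitude is an appreciable
  # fraction of the frame's intensity scale: a genuine first harmonic
  # carries ~ m/4 of it, while residual DC leakage through the window tail
  # sits orders of magnitude lower
  validity <- array(FALSE, d)
  for (k in seq_len(Tn)) {
    thresh <- 0.01 * max(mean(abs(seq$frames[, , k])), .Machine$double.eps)
    validity[, , k] <- Mod(z[, , k]) > thresh
  }
  structure(list(complex_frames = z, validity = validity,
                 carrier = as.numeric(carrier), filter_sd = filter_sd,
                 spacing = seq$spacing, dt = seq$dt, t0 = seq$t0),
            class = "phase_sequence")
}

## Demodulate one frame by the carrier: w(x) = z(x) exp(-i k_c . x).
## The residual phase psi = arg(w) varies slowly (it measures deformation,
## not the tag pattern), so Gaussian filtering of w is well conditioned at
## large scales where filtering z itself would destroy the carrier.
demodulated_frame <- function(pseq, frame) {
  d <- dim(pseq$complex_frames)
  xc <- pixel_coords(d[1], d[2], pseq$spacing)
  ph <- pseq$carrier[1] * xc$x1 + pseq$carrier[2] * xc$x2
  pseq$complex_frames[, , frame] * exp(-1i * ph)
}

## Complex Gaussian-derivative stack of a demodulated frame at a scale
## (mm). Returns smoothed w and its first and second derivatives in
## physical units.
w_derivatives <- function(pseq, frame, scale, second = TRUE) {
  w <- demodulated_frame(pseq, frame)
  spx <- scale / pseq$spacing[1]
  spy <- scale / pseq$spacing[2]
  if (abs(spx - spy) > 1e-9 * max(spx, spy))
    stop("anisotropic pixel spacing is not supported by the filter bank")
  s <- spx
  g0 <- gauss_kernel(s, 0L); g1 <- gauss_kernel(s, 1L)
  sp <- pseq$spacing
  out <- list(
    w = conv_sep(w, g0, g0),
    wx = conv_sep(w, g1, g0) / sp[1],
    wy = conv_sep(w, g0, g1) / sp[2]
  )
  if (second) {
    g2 <- gauss_kernel(s, 2L)
    out$wxx <- conv_sep(w, g2, g0) / sp[1]^2
    out$wxy <- conv_sep(w, g1, g1) / (sp[1] * sp[2])
    out$wyy <- conv_sep(w, g0, g2) / sp[2]^2
  }
  out
}

## Phase derivatives of a demodulated stack, wrap-free:
## psi_a   = Im(conj(w) w_a) / |w|^2
## psi_ab  = [Im(conj(w) w_ab) + Im(conj(w_a) w_b)] / |w|^2
##           - 2 Re(conj(w) w_a) Im(conj(w) w_b) / |w|^4
## Full phase derivatives add the carrier to the first order.
phase_derivs_from_w <- function(d, carrier, second = TRUE) {
  a2 <- Mod(d$w)^2
  psi_x <- Im(Conj(d$w) * d$wx) / a2
  psi_y <- Im(Conj(d$w) * d$wy) / a2
  out <- list(phi_x = carrier[1] + psi_x, phi_y = carrier[2] + psi_y,
              amp2 = a2)
  if (second) {
    rx <- Re(Conj(d$w) * d$wx); ry <- Re(Conj(d$w) * d$wy)
    ix <- Im(Conj(d$w) * d$wx); iy <- Im(Conj(d$w) * d$wy)
    out$phi_xx <- (Im(Conj(d$w) * d$wxx) + Im(Conj(d$wx) * d$wx)) / a2 -
      2 * rx * ix / a2^2
    out$phi_xy <- (Im(Conj(d$w) * d$wxy) + Im(Conj(d$wx) * d$wy)) / a2 -
      2 * rx * iy / a2^2
    out$phi_yy <- (Im(Conj(d$w) * d$wyy) + Im(Conj(d$wy) * d$wy)) / a2 -
      2 * ry * iy / a2^2
  }
  out
}

#' Spatial gradient of the harmonic phase without unwrapping
#'
#' Computes the phase gradient of one frame directly from the complex
#' band-passed image via `Im(conj(z) grad z) / |z|^2` (evaluated on the
#' carrier-demodulated image with Gaussian-derivative filters at the given
#' scale, then re-adding the carrier), which is exactly invariant to any
#' global phase offset and free of wrap artifacts.
#'
#' @param pseq a `phase_sequence` from [bandpass_harmonic()].
#' @param frame frame index.
#' @param scale Gaussian derivative scale in mm.
#' @return List with `grad` (`nx x ny x 2`, rad/mm) and `validity`
#'   (logical matrix; pixels with negligible harmonic magnitude are
#'   invalid).
#' @export
phase_gradient <- function(pseq, frame, scale) {
  stopifnot(inherits(pseq, "phase_sequence"), scale > 0)
  d <- w_derivatives(pseq, frame, scale, second = FALSE)
  pd <- phase_derivs_from_w(d, pseq$carrier, second = FALSE)
  thresh <- (1e-6 * max(Mod(pseq$complex_frames[, , frame]),
                        .Machine$double.eps))^2
  valid <- pd$amp2 > thresh & pseq$validity[, , frame]
  g <- array(NA_real_, c(dim(d$w), 2))
  g[, , 1] <- ifelse(valid, pd$phi_x, NA_real_)
  g[, , 2] <- ifelse(valid, pd$phi_y, NA_real_)
  list(grad = g, validity = valid)
}
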