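#' Metric specification for strain computation
#'
#' Metric tensors on the reference (domain) and deformed (codomain) charts.
#' `identity` mode (the single-Cartesian-chart case used for all outputs)
#' sets both to the identity. `carry_along` mode induces the codomain
#' metric from the reference metric by the deformation itself,
#' `h = F^{-T} g F^{-1}`, which nullifies the Lagrangian strain identically
#' and serves as a built-in correctness oracle. `custom` mode accepts
#' arbitrary symmetric positive-definite `g` and `h`.
#'
#' @param mode one of `"identity"`, `"custom"`, `"carry_along"`.
#' @param g,h `2 x 2` symmetric positive-definite matrices (covariant
#'   components); `h` is ignored in `carry_along` mode.
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(mode = c("identity", "custom", "carry_along"),
                        g = diag(2), h = diag(2)) {
  mode <- match.arg(mode)
  check_pd <- function(M, name) {
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-10)) ||
        any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop(name, " metric must be symmetric positive definite")
  }
  if (mode == "identity") { g <- diag(2); h <- diag(2) }
  check_pd(g, "domain")
  if (mode != "carry_along") check_pd(h, "codomain")
  structure(list(mode = mode, g = g, h = h), class = "metric_spec")
}

#' Lagrangian strain tensor from a deformation gradient
#'
#' Mixed components
#' `E_i^j = (g^{lj} F_l^a h_ab F_i^b - delta_i^j) / 2`, returned as the
#' matrix `E[j, i]`. With identity metrics this is the familiar
#' `E = (F^T F - I) / 2`. In `carry_along` mode the codomain metric is
#' first induced from `g` by `F` itself, so the result vanishes
#' identically (to roundoff) for any invertible `F` — the tensorial
#' consistency check of the construction.
#'
#' @param F `2 x 2` deformation gradient (`F[a, i] = dx^a / dX^i`).
#' @param metrics a [metric_spec()]; default identity.
#' @return `2 x 2` matrix of mixed strain components (dimensionless).
#' @export
lagrangian_strain <- function(F, metrics = metric_spec()) {
  stopifnot(is.matrix(F), all(dim(F) == 2))
  g <- metrics$g
  h <- if (metrics$mode == "carry_along") {
    Fi <- solve(F)
    t(Fi) %*% g %*% Fi
  } else metrics$h
  0.5 * (solve(g, t(F) %*% h %*% F) - diag(2))
}

#' Project the strain tensor onto a pair of directions
#'
#' Scalar `(u, E(w)) = g_jk u^k E_i^j w^i`, e.g. circumferential strain for
#' `u = w = e_c`, radial for `u = w = e_r`, shear for the mixed pair. The
#' value is symmetric in `(u, w)` when `E` comes from a consistent metric
#' construction.
#'
#' @param E `2 x 2` mixed-component strain matrix (`E[j, i]`).
#' @param u,w direction vectors, unit with respect to `g`.
#' @param g `2 x 2` reference metric (default identity).
#' @return Scalar strain component.
#' @export
project_strain <- function(E, u, w, g = diag(2)) {
  nu <- sqrt(as.numeric(t(u) %*% g %*% u))
  nw <- sqrt(as.numeric(t(w) %*% g %*% w))
  if (abs(nu - 1) > 1e-6 || abs(nw - 1) > 1e-6)
    stop("projection directions must be unit vectors in the g metric")
  as.numeric(t(u) %*% g %*% E %*% w)
}

#' Radial/circumferential direction frame
#'
#' For each reference position the outward radial unit vector
#' `e_r = (X - center) / |X - center|` and the counterclockwise
#' circumferential unit vector `e_c` obtained by rotating `e_r` by +90
#' degrees. The frame is undefined at the center point, which is flagged.
#'
#' @param points `2 x m` matrix of reference positions (mm) or length-2
#'   vector.
#' @param center polar center (mm), typically the ROI midpoint.
#' @return List with `e_r`, `e_c` (`2 x m`) and `defined` (logical, length
#'   m).
#' @export
polar_frame <- function(points, center) {
  pts <- as_points(points)
  U <- pts - center
  r <- sqrt(colSums(U^2))
  defined <- r > 0
  e_r <- U / rep(pmax(r, .Machine$double.eps), each = 2)
  e_r[, !defined] <- NA_real_
  e_c <- rbind(-e_r[2, ], e_r[1, ])
  list(e_r = e_r, e_c = e_c, defined = defined)
}

#' Principal strains and directions
#'
#' Eigen-decomposition of a symmetric (identity-metric) strain matrix.
#' Eigenvalues are returned ordered (`E_min <= E_max`); eigenvector signs
#' are fixed so the first nonzero component is positive. In the eigenframe
#' the shear projection vanishes identically.
#'
#' @param E `2 x 2` strain matrix; must be symmetric to `1e-8` (a larger
#'   asymmetry indicates a metric misuse and raises an error).
#' @return List with `E_min`, `E_max`, `dir_min`, `dir_max`.
#' @export
strain_eigensystem <- function(E) {
  stopifnot(is.matrix(E), all(dim(E) == 2))
  if (max(abs(E - t(E))) > 1e-8)
    stop("strain matrix is not symmetric; use identity metrics for eigenanalysis")
  Es <- (E + t(E)) / 2
  ev <- eigen(Es, symmetric = TRUE)
  fix_sign <- function(v) {
    nz <- which(abs(v) > .Machine$double.eps)[1]
    if (!is.na(nz) && v[nz] < 0) -v else v
  }
  list(E_min = ev$values[2], E_max = ev$values[1],
       dir_min = fix_sign(ev$vectors[, 2]),
       dir_max = fix_sign(ev$vectors[, 1]))
}

#' Mask-aware Gaussian regularization of a scalar field
#'
#' Normalized (masked) Gaussian convolution: invalid pixels carry zero
#' weight and the result is renormalized by the smoothed validity mask, so
#' values never bleed across the mask. Pixels with essentially no valid
#' support within the kernel (total weight below the 4-sigma tail mass)
#' stay flagged. `sigma = 0` returns the input unchanged.
#'
#' @param field numeric matrix.
#' @param sigma Gaussian scale in pixels.
#' @param validity logical matrix, same shape (default all valid).
#' @return List with `field` (smoothed matrix, `NA` on flagged pixels) and
#'   `validity`.
#' @export
regularize_scalar_field <- function(field, sigma = 1,
                                    validity = NULL) {
  stopifnot(is.matrix(field), sigma >= 0)
  if (is.null(validity)) validity <- !is.na(field)
  if (!any(validity)) stop("scalar field has no valid pixels")
  if (sigma == 0) {
    out <- field
    out[!validity] <- NA_real_
    return(list(field = out, validity = validity))
  }
  f0 <- field
  f0[!validity] <- 0
  k <- gauss_kernel(sigma, 0L)
  num <- conv_sep(f0, k, k)
  den <- conv_sep(validity * 1, k, k)
  # weight threshold: everything beyond the 4-sigma tail counts as "no
  # valid neighbour"
  wmin <- exp(-8) # Gaussian at 4 sigma relative to peak
  ok <- den > wmin
  out <- matrix(NA_real_, nrow(field), ncol(field))
  out[ok] <- num[ok] / den[ok]
  list(field = out, validity = ok)
}

#' Scalar strain maps from an integrated deformation field
#'
#' Computes, for one frame of a [integrate_deformation()] result whose
#' seeds are the pixels of a reference-grid mask, the Lagrangian strain
#' per pixel (identity metrics) and its radial, circumferential, shear and
#' principal-value projections in the polar frame about `center`, then
#' regularizes each scalar field.
#'
#' @param def a `deformation_field`.
#' @param frame frame index, 1-based over `1..(n_steps + 1)` (1 is the
#'   reference frame).
#' @param seeds `2 x m` matrix of the seed positions (mm), matching `def`.
#' @param seed_idx `m x 2` integer matrix of pixel indices of the seeds.
#' @param dims image dimensions `c(nx, ny)`.
#' @param center polar center (mm).
#' @param sigma regularization scale in pixels (default 1; 0 disables).
#' @return An object of class `strain_field`: list of matrices `E_cc`,
#'   `E_rr`, `E_cr`, `E_min`, `E_max` (NA outside validity), `validity`,
#'   and the raw (unregularized) fields in `$raw`.
#' @export
strain_maps <- function(def, frame, seeds, seed_idx, dims, center,
                        sigma = 1) {
  stopifnot(inherits(def, "deformation_field"))
  m <- dim(def$F)[3]
  F11 <- def$F[1, 1, , frame]; F12 <- def$F[1, 2, , frame]
  F21 <- def$F[2, 1, , frame]; F22 <- def$F[2, 2, , frame]
  # E = (F^T F - I)/2, componentwise
  E11 <- 0.5 * (F11^2 + F21^2 - 1)
  E22 <- 0.5 * (F12^2 + F22^2 - 1)
  E12 <- 0.5 * (F11 * F12 + F21 * F22)
  pf <- polar_frame(seeds, center)
  rx <- pf$e_r[1, ]; ry <- pf$e_r[2, ]
  cx <- pf$e_c[1, ]; cy <- pf$e_c[2, ]
  quad <- function(u1, u2, w1, w2)
    E11 * u1 * w1 + E12 * (u1 * w2 + u2 * w1) + E22 * u2 * w2
  vals <- list(
    E_cc = quad(cx, cy, cx, cy),
    E_rr = quad(rx, ry, rx, ry),
    E_cr = quad(cx, cy, rx, ry)
  )
  mid <- (E11 + E22) / 2
  dd <- sqrt(((E11 - E22) / 2)^2 + E12^2)
  vals$E_min <- mid - dd
  vals$E_max <- mid + dd
  valid_seed <- def$valid[, frame] & pf$defined
  vimg <- matrix(FALSE, dims[1], dims[2])
  vimg[seed_idx] <- valid_seed
  raw <- lapply(vals, function(v) {
    img <- matrix(NA_real_, dims[1], dims[2])
    img[seed_idx] <- ifelse(valid_seed, v, NA_real_)
    img
  })
  reg <- lapply(raw, regularize_scalar_field, sigma = sigma,
                validity = vimg)
  out <- lapply(reg, `[[`, "field")
  out$validity <- reg[[1]]$validity
  out$raw <- raw
  out$raw_validity <- vimg
  structure(out, class = "strain_field")
}
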