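---
title: "Myocardial deformation and strain from tagged cine MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocardial deformation and strain from tagged cine MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagstrain)
```

# The problem

SPAMM tagging imprints sinusoidal intensity stripes on the myocardium at a
reference time (end-diastole); the stripes are material and deform with the
tissue, so a pair of cine sequences with orthogonal tag directions encodes
the full in-plane motion of a short-axis slice. `tagstrain` turns such a
pair into dense Lagrangian strain maps in four stages:

1. **HARP extraction** — each tagged sequence is Fourier band-pass filtered
   around its first spectral harmonic; the argument of the resulting complex
   image is, modulo 2&pi;, the material tag phase $k_w \cdot X(x,t)$, a
   scalar quantity that is advected with the tissue and insensitive to tag
   fading.
2. **Velocity-gradient estimation** — the two phase images are scalars
   transported by the flow, so each satisfies the optic-flow constraint
   $\partial_t\varphi + v\cdot\nabla\varphi = 0$. Writing the local
   first-order model $v(x) = v_0 + L\,(x - x_0)$ and differentiating the
   constraint once in space gives, per phase, three equations; two phases
   give an unambiguous $6\times 6$ linear system for
   $(v_0, L)$ — no regularization prior is needed, because the phase pair
   resolves the aperture problem by construction. All image derivatives are
   Gaussian-derivative filters evaluated at a spatial scale selected **per
   pixel** to minimize the 2-norm condition number of that system.
3. **Deformation integration** — the deformation gradient
   $F(t, t_0) = \partial x / \partial X$ obeys the linear matrix ODE
   $\dot F = L F$, $F(t_0,t_0)=I$. Its solution is the time-ordered
   *multiplicative integral*, approximated on the frame grid as an ordered
   product of per-interval factors, either $(I + L\,\Delta t)$
   (`linear_product`, the cheap default) or $\exp(L\,\Delta t)$
   (`exp_product`, exactly area-preserving for divergence-free flows since
   $\det\exp A = \exp\operatorname{tr}A$). A truncated matricant
   (iterated-integral) series is provided as an independent cross-check.
   $L$ is sampled along tracked material trajectories, so $F$ is a genuine
   Lagrangian quantity referred to end-diastole.
4. **Strain** — the Lagrangian strain tensor has mixed components
   $E_i^{\ j} = \tfrac12\,(g^{\ell j} F_\ell^{\ \alpha} h_{\alpha\beta}
   F_i^{\ \beta} - \delta_i^{\ j})$ under reference/deformed chart metrics
   $g, h$; with a single Cartesian chart this is
   $E = \tfrac12(F^{\mathsf T} F - I)$. Scalars are obtained by projection
   onto the polar frame about the ROI midpoint
   ($E_{cc}, E_{rr}, E_{cr}$) and onto the eigenframe
   ($E_{\min}, E_{\max}$), then regularized by masked Gaussian smoothing.

Two exact identities are wired in as correctness oracles: strain vanishes
identically for isometries (rigid motions), and it vanishes for *any*
invertible $F$ when the deformed-chart metric is the one carried along by
the deformation itself, $h = F^{-\mathsf T} g\, F^{-1}$
(`metric_spec("carry_along")`). Both are enforced in the test suite at
$10^{-12}$ and $10^{-10}$ respectively.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass width `filter_sd` | $\lVert k_w\rVert/4$ | rad/mm | separates the side band from DC while tolerating deformation-induced spectral broadening |
| scale sweep | 8 log-spaced, $0.5$–$3\times$ tag spacing | mm | brackets the scale at which two full tag periods fall inside the derivative support |
| condition ceiling `max_cond` | $10^6$ | — | pixels beyond it are invalidated, not clipped: fail loudly |
| integration method | `linear_product` | — | one multiply-add per step; `exp_product` available when exact volume behavior matters |
| evaluation point $t_k^\*$ | right endpoint $k\,\Delta t$ | s | piecewise-constant $L$ per frame interval, matching a constant frame-interval acquisition |
| regularization $\sigma$ | 1.0 | pixels | light smoothing of the displayed/reported scalar fields only |
| tag period (phantom) | 7 | mm | typical clinical SPAMM spacing of 6–8 mm |

Conventions that matter for reproducibility: pixel-center 0-based
coordinates with physical position = index $\times$ spacing; the
circumferential unit vector is the **counterclockwise** rotation of the
outward radial one (this fixes the sign of $E_{cr}$, which is otherwise
convention-free); eigenvector signs are fixed by a positive first nonzero
component; the shear scalar is computed as $(e_c, E(e_r))$, which equals
$(e_r, E(e_c))$ by the symmetry of $E$ under consistent metrics.

# The synthetic phantom

Clinical tagged series are not distributed with the package, so every stage
is validated against an analytic phantom
(`annulus_phantom()`): an annulus of inner/outer radii 25/45 mm on a
128&times;128 grid at 1 mm spacing, deformed by the area-preserving map
$r = \sqrt{R^2 + \lambda(t)},\ \theta = \Theta + \phi(t)$ with half-cosine
ramps to $\lambda = -150$ mm$^2$ and $\phi = 0.15$ rad over a 0.5 s,
21-frame simulated systole. This mimics systolic contraction with torsion:
mid-wall circumferential shortening of about $-6\%$ and radial thickening
of about $+7\%$, with $\det F \equiv 1$ and a divergence-free velocity
field — both used as machine-precision oracles. Tags are rendered as
single-harmonic material cosines painted at $t_0$ and passively advected,
which is what the HARP front end actually consumes; additive white Gaussian
noise and exponential tag fading are optional.

What the phantom does **not** emulate: MR acquisition physics (k-space,
$T_1$ relaxation dynamics, through-plane motion), Rician noise statistics,
papillary muscles and trabeculation, partial-volume edges, and breathing or
gating artifacts. Passing the phantom tests therefore demonstrates the
correctness of the mathematical chain and its discretization, not clinical
robustness.

# Numerical choices

* **No phase unwrapping anywhere.** Spatial phase derivatives come from the
  complex image via $\operatorname{Im}(\bar z\,\nabla z)/|z|^2$ and its
  second-order analogue; temporal derivatives from
  $\arg(z_{k+1}\bar z_k)/\Delta t$. These are exactly invariant to global
  phase offsets and free of wrap ridges. Internally the band-passed image
  is first demodulated by the carrier ($w = z\,e^{-i k_c\cdot x}$) and the
  Gaussian filters act on the slowly varying $w$; the carrier is re-added
  analytically. This is algebraically the same quantity, but it remains
  well conditioned at derivative scales several times the tag period,
  where filtering the raw carrier-bearing $z$ would attenuate it to
  numerical dust.
* **Filtering.** All convolutions are separable Gaussians with reflect
  (mirror) padding; derivative kernels are discretely renormalized (unit
  response to a ramp, respectively to $x^2/2$). A guard band of $3\sigma$
  pixels at the image border is excluded per scale; a pixel is estimated
  whenever at least one scale of the sweep keeps its support inside the
  image.
* **Scale selection** is per pixel and independent across pixels, with ties
  broken toward the smaller scale. The conditioning functional is the
  plain 2-norm condition number of the $6\times6$ matrix; this is a
  documented stand-in for more elaborate selection criteria and is
  exposed as configuration.
* **Temporal structure.** One velocity-gradient field per consecutive frame
  pair, treated as constant on its interval; spatial derivatives are
  averaged between the two frames (mid-interval estimate). Material
  tracking is explicit Euler with bilinear interpolation — one velocity
  sample per interval, mirroring the piecewise-constant-$L$ assumption.
  Both product solvers are first-order accurate in $\Delta t$; the test
  suite verifies the observed convergence order on the phantom.
* **Matrix exponential.** Closed Cayley–Hamilton form for $2\times2$
  matrices, $e^{\mu}(c(\delta) I + s(\delta) B)$ with a series branch near
  the degenerate discriminant $\delta = 0$; exactness on nilpotent and
  antisymmetric generators is tested.
* **Degenerate inputs.** Trajectories that leave the valid region are
  frozen and flagged, never extrapolated; pixels with undefined phase
  (harmonic magnitude below 1% of the frame's mean intensity) are flagged;
  an all-invalid field is an error; masked regularization gives invalid
  pixels zero weight and keeps pixels with no valid support within
  roughly $4\sigma$ flagged.
* **Carrier detection** takes the largest non-DC spectral peak of the first
  frame (positive half-plane), refined to sub-bin accuracy by a local
  quadratic fit of log-magnitude; it requires the peak to exceed three
  times the median spectral magnitude *and* to concentrate at least 5% of
  the non-DC energy — the median rule alone cannot reject broad-band noise,
  whose expected max/median ratio already exceeds three for kilopixel
  spectra.

# Design decisions taken where the design was open

* The multiscale optic-flow front end follows the stated structure
  (first-order closure on $n$ phase images, conditioning-driven scale
  choice) with concrete commitments chosen here: Gaussian-derivative
  filtering, central/one-sided temporal differences, the log-spaced sweep
  above. Whether a temporal scale should also be selected is left as
  configuration; the default uses the native frame interval.
* $L$ is sampled at tracked material positions (Lagrangian sampling). The
  cheaper Eulerian shortcut — sampling at the fixed seed pixel — is
  available via trajectories with zero velocity, but is not the default,
  because material sampling is what makes the ordered product converge to
  $F(t, t_0)$ of the seed.
* Statistics are computed on the regularized fields by default (matching
  how the maps are displayed), with `regularized = FALSE` giving the raw
  fields; the standard deviation uses the sample ($n-1$) denominator.
* Rendering uses a single-harmonic cosine rather than a full product-of-
  cosines SPAMM pattern: the pipeline consumes one band-passed harmonic per
  direction, so additional harmonics would only lower the usable SNR of
  the fixture without exercising any additional code path.

# Problem sizes used in the validation suite

The end-to-end check runs the full default pipeline (128&times;128, 21
frames, 8 scales, ~4400 ROI pixels) once and asserts a median absolute
end-systolic strain error below 0.05 against the analytic oracle together
with the systolic sign pattern ($E_{cc} < 0$, $E_{rr} > 0$ mid-wall);
observed errors on this configuration are typically below 0.01.
Unit-level properties (equivariance under quarter-turns, noise
monotonicity, conditioning) use 64&times;64 grids with 3–5 frames;
integrator convergence studies use analytic velocity-gradient fields on
65&times;65 grids with up to 80 time steps.

# Known limitations

* Planar (2D + time) only: contracts are dimension-agnostic but only
  $n = 2$ is implemented and tested; through-plane motion aliases into the
  in-plane estimates on real data.
* First-order accuracy in time throughout (tracking and both product
  solvers); halving the frame interval halves the deformation error, and
  the matricant series is available as an independent check rather than a
  higher-order solver.
* The selected-scale map is spatially uncorrelated by construction; no
  spatiotemporal regularization of scale selection is attempted.
* Segmentation is an input: the ROI mask must be supplied (the phantom
  provides its own).
* CSPAMM complementary-pair subtraction, DENSE/velocity-encoded inputs and
  k-space simulation are out of scope.
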