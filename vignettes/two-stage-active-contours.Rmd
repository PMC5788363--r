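---
title: "Two-stage region-edge active contours: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage region-edge active contours: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acseg)
```

## The segmentation model

`acseg` addresses a failure mode of classical region-based active
contours: when a smooth multiplicative shading (a *bias field*, common in
MRI and dermoscopy) makes one object span a wide intensity range, a
global two-phase model such as Chan–Vese — which explains the image by
two constants $c_1, c_2$ — misclassifies the object's tails. Local
fitting models (LBF) fix this by replacing the constants with
Gaussian-window local means $f_1(x), f_2(x)$, but their energy is riddled
with local minima, so the result depends strongly on where the initial
contour is placed.

The method implemented here runs two stages that share one structure: a
region-fitting force and a geodesic edge force, balanced by a weight
$w \in [0,1]$, with every region quantity *edge-scaled* by the stopping
function

$$g(|\nabla I|) = \frac{1}{1 + |\nabla G_{\sigma_{edge}} * I|},$$

computed once per stage from the input image. $g \approx 1$ in flat
regions and drops toward 0 at strong edges, so edge pixels contribute
little to the region statistics (they would otherwise drag the means)
while the geodesic term $g\,\mathrm{div}(\nabla\phi/|\nabla\phi|) +
\nabla g \cdot \nabla\phi/|\nabla\phi|$ attracts and pins the contour at
boundaries.

**Stage 1 (GREAC)** uses edge-scaled *global* means and runs for a fixed
number of iterations, producing a coarse contour near the object from a
generic initialization. **Stage 2 (LREAC)** is initialized with the
stage-1 level set and uses edge-scaled *local* fits, refining the
boundary under intensity drift; it runs until the contour stops moving.
The two-stage split is the point of the method: the global stage removes
the initialization sensitivity of local fitting, and the local stage
supplies the inhomogeneity robustness the global stage lacks.

The level-set function is a binary step at $t = 0$: $+\rho$ strictly
inside the initial region, $-\rho$ strictly outside, $0$ on the region's
one-pixel boundary ring. We fix the convention *inside* $\Leftrightarrow
\phi > 0$, so the regularized Heaviside $H_\varepsilon(\phi)$ is the
soft inside-indicator. (Formulations in this family sometimes write the binary step with the
opposite sign while still using $H_\varepsilon$ as the inside indicator
in the energies; the two conventions conflict, and we fix the one
consistent with the energies.)

Instead of periodically re-initializing $\phi$ to a signed distance
function, $\phi$ is convolved with a small Gaussian after every step.

## The evolution flows, exactly as formulated

Both stage flows multiply *all* force terms — including the
Dirac-weighted region and area terms — by $|\nabla\phi|$:

$$\phi_{t} = |\nabla\phi|\Big[ w\big(-g(I-c_1)^2 + g(I-c_2)^2\big)
\delta_\varepsilon(\phi) + (1-w)\big(g\,\kappa + \nabla g \cdot
\tfrac{\nabla\phi}{|\nabla\phi|}\big) - v\,\delta_\varepsilon(\phi)
\Big]$$

for stage 1, and for stage 2 the analogous flow with the local
squared-residual integrals $\int K_\sigma(x-y)\,|I(x)-f_i(y)|^2\,dy$ in
place of $(I-c_i)^2$ and a length term
$+v\,\delta_\varepsilon(\phi)\,\kappa$ in place of the area term. We
implement the flows verbatim, $|\nabla\phi|$ prefactor included, rather
than "correcting" them to the conventional $\delta_\varepsilon$-only
form; `stage_config(strict_flow = FALSE)` provides the conventional form
for comparison. One consequence of the verbatim form is worth knowing:
with a binary-step initialization, $|\nabla\phi| = 0$ away from the
contour, so the front propagates only where the per-step Gaussian
regularization has spread $\phi$ — about 2–3 px per iteration. The
stage-2 formulation also shows an area term in its energy but a length
term in its flow; the flow is what defines the algorithm, so we follow
the flow.

The local integrals expand into three Gaussian filterings,
$I^2(K*1) - 2I(K*f) + K*(f^2)$, turning an $O(N^2)$ double sum into
$O(N)$ work; the tests verify the expansion against direct summation at
$10^{-10}$, and every step function against an independently coded
term-by-term oracle.

The baselines are implemented from their own formulations: Chan–Vese
($\delta_\varepsilon$-weighted global region force, curvature length
term with weight $\mu$, Gaussian level-set regularization in place of
re-initialization) and LBF (local fitting force, length term, and its
own distance-regularization penalty $\mu(\Delta\phi - \kappa)$, which
replaces Gaussian smoothing for that method).

## Parameters

All intensity-dependent constants follow the conventional 0–255 scale,
so values quoted on that scale can be entered verbatim; internally images live in
$[0,1]$ and region residuals are multiplied by
`intensity_scale^2 = 255^2`. Per stage (`stage_config()`):

| parameter | meaning | default (stage 1 / stage 2) |
|---|---|---|
| `w` | region-vs-edge balance, dimensionless in $[0,1]$ | 0.08 / 0.01 |
| `v` | area (stage 1) or length (stage 2) weight | 1 / 1e-5 |
| `lambda1`, `lambda2` | inside/outside region weights | 1 / 1 |
| `sigma_local` | local fitting kernel σ, px | — / 3 |
| `sigma_edge` | pre-smoothing σ of the edge map, px | 1.5 |
| `epsilon` | Heaviside/Dirac width, φ-units | 1 |
| `rho` | binary-step magnitude, φ-units | 2 |
| `dt` | explicit Euler time step | 0.1 |
| `max_iter` | fixed stage-1 count / stage-2 cap | 10 / 200 |
| `tol`, window | convergence: flip fraction < tol for 5 consecutive iterations | 1e-4, 5 |
| `sigma_reg` | per-step Gaussian regularization σ, px | 1.0 / 0.5 |

The `ph2` preset (dermoscopy: $v_1 = 0.0001\cdot255^2$,
$v_2 = 0.00001\cdot255^2$, $\sigma = 0.3$, $w_1 = 0.9$, $w_2 = 0.001$)
and `brats` preset (brain MRI: $v_1 = 1$, $v_2 = 0.0001\cdot255^2$,
$\sigma = 3$, $w_1 = 0.6$, $w_2 = 0.751$) carry the reference values for
those image classes. The Chan–Vese baseline's length weight defaults to
$\mu = 0.1\cdot255^2$ (the customary value for that model) and LBF's
penalty weight to $\mu = 1$.

Two defaults deserve their rationale:

* **`sigma_edge` = 1.5 px.** The pre-smoothing width is a free choice.
  1.5 px suppresses pixel noise in the gradient while keeping the
  edge well 2–3 px wide, matching the localization the geodesic term
  needs on ~100-px-scale objects.

* **`sigma_reg` = 1.0 px (stage 1, Chan–Vese) but 0.5 px (stage 2).**
  Per-step Gaussian smoothing of $\phi$ is itself a curvature-like flow
  of strength $\approx \sigma^2/2$ per iteration, and with a binary-step
  $\phi$ whose negative side grows deeper than its positive side it
  drifts the zero set inward. Stage 1's forces (balance $w = 0.08$ on
  residuals of order $255^2$) dominate this drift, and the smoothing
  usefully regularizes the fast coarse stage. Stage 2's forces are two
  orders of magnitude weaker ($w = 0.01$, $v = 10^{-5}$), so a 1-px
  kernel erodes the converged contour faster than the stage's own terms
  can hold it — smoothing would dominate the energy it is meant to
  regularize. Halving the width quarters the drift and restores the
  intended balance: regularization strength should scale with the
  stage's force level, not exceed it.

## Convergence and termination

Stage 1 deliberately runs a *fixed* number of iterations with no
convergence test — its job is a coarse result, and its iteration count
is part of the procedure itself. Stage 2 and the baselines stop when
the fraction of pixels whose sign flipped stays below `tol` for `window`
consecutive iterations (defaults $10^{-4}$ and 5); the driver returns
`converged = FALSE` with the partial result if the cap is reached
instead of raising an error. The method does not come with a canonical
convergence criterion, so this sign-flip rule — scale-free, cheap, and directly
tied to "the contour stopped moving" — is the package's choice.

## Numerical choices

* Central differences for all first derivatives and curvature; replicate
  (Neumann) borders for derivatives and for the Gaussian filters applied
  to images and to $\phi$; grid spacing 1 px.
* $1/|\nabla\phi|$ divisions are floored by adding $10^{-8}$ to the
  norm, so a flat field has zero curvature rather than 0/0.
* All fit denominators carry a $10^{-10}$ guard. An empty inside/outside
  region makes the corresponding global mean fall back to the whole-image
  mean (with a warning); a locally vanishing fit denominator falls back
  to the corresponding global mean (reported once per call).
* The fit ratios $K*[wI] / K*[w]$ use zero-padded convolutions, making
  each fit a Gaussian-weighted mean over in-domain pixels only. With
  replicate padding the ratio would overweight border pixels and the
  large-$\sigma$ limit would not recover the global means.
* Gaussian kernels are truncated at radius $\lceil 4\sigma \rceil$ and
  renormalized.
* Explicit Euler stepping only, `dt` from the configuration; no CFL
  adaptation. Instability (a non-finite update) raises an error naming
  the offending term.
* Color input is converted to luminance before everything; images are
  normalized to $[0,1]$ on load.

## The phantom generator

`generate_phantom()` builds the study images: a piecewise-constant
object (disc, ring, blob, or two discs; base intensities 0.65 object /
0.25 background) multiplied by a smooth bias field and corrupted by
additive Gaussian noise (default sd 0.02), clipped to $[0,1]$, with the
exact object support as ground truth. Defaults emulate the synthetic
conditions the method targets: a linear bias ramp with gain 0.5–1.5
across the image (gradient < 0.02/px, so the inhomogeneity stresses the
region terms, not the edge term), base intensities chosen so the full
gain range stays clip-free. The radial model is a Gaussian bump tight
enough that the object spans nearly the full gain ratio; it is
deliberately steeper than the default and exercises the local fits. The
object sits off-center (row 0.40, column 0.62 of the grid) so that
generic initializations — including the driver's default centered
rectangle — do not coincide with the ground truth; a centered object
would make the coarse stage trivially correct and the second stage's
contribution unmeasurable. Generation is seeded, bit-reproducible, and
restores the caller's RNG state.

What the phantoms do **not** emulate: Rician MRI noise, partial-volume
boundaries, dermoscopic texture, multi-class anatomy. Passing the
phantom suite shows the machinery behaves as designed under smooth
multiplicative inhomogeneity; it is not evidence about any particular
clinical dataset.

`generate_init_grid()` provides five deterministic initial regions at
varied offsets and scales relative to the object (centered, shifted,
object-corner, enclosing, strictly interior) for
initialization-sensitivity experiments. All five lie within the capture
envelope of the 10-iteration global stage: because the verbatim flow
carries the $|\nabla\phi|$ prefactor, the front travels only ~2–3 px per
iteration, so an initial contour everywhere farther than ~25 px from the
object boundary cannot be captured within the fixed stage-1 budget
regardless of the method's other properties. Placements beyond that
envelope measure the iteration budget, not the local-minimum sensitivity
the protocol is designed to contrast with LBF.

## Known limitations

* The fixed-length global stage bounds how far the contour can travel;
  segmenting objects far from the initialization needs either more
  stage-1 iterations or `strict_flow = FALSE`.
* The global stage resolves intensity *clusters*: if the bias field
  pushes background intensities into the object's range, inits that
  cover much of the offending background can converge to a wrong
  two-means split that the weak local stage cannot undo.
* Explicit Euler with the default `dt` is stable for the default
  force scales but is not unconditionally stable; halving `dt` and
  doubling iterations reproduces the default masks to within 1% of
  pixels (tested).
* 2-D single-channel only; no narrow-band optimization, no
  signed-distance re-initialization (by design).
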