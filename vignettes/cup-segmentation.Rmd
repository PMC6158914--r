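---
title: "Optic cup segmentation by vessel inpainting and local Chan-Vese level sets"
author: "cupseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic cup segmentation by vessel inpainting and local Chan-Vese level sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupseg)
```

## The problem

The optic disc of a fundus photograph contains a bright central depression,
the optic cup, surrounded by the neuroretinal rim.  The ratio of the
vertical diameters of cup and disc (the vertical cup-to-disc ratio, CDR)
is a standard indicator of glaucoma risk: as nerve fibers are lost the cup
enlarges relative to the disc.  Automatic cup segmentation is hard mainly
because retinal blood vessels cross the cup boundary and locally destroy
the intensity contrast the boundary would otherwise provide.

`cupseg` implements a fully automatic cup segmentation pipeline built
around that observation: the vessels are detected and *removed by
inpainting* before the boundary is sought, so the segmentation model sees
an approximately vessel-free cup.

The pipeline, in order:

1. **Green channel.** Of the three color channels the green one carries
   the best cup contrast; the red and blue channels are discarded.
2. **Morphological enhancement.** With a flat 5 x 5 square structuring
   element, `U = (U_G + tophat(U_G)) - bottomhat(U_G)`.  The top-hat adds
   small bright structure, the bottom-hat subtracts small dark structure
   (vessels), sharpening the cup rim.  The result is clipped to [0, 255].
3. **Vessel extraction.** `U_sub = median_9x9(U) - U`; a pixel is vessel
   when `U_sub` exceeds a threshold `tau` (vessels are dark and thin, so
   the median overshoots them).  Components smaller than 10 px are
   dropped, and the mask is dilated by a Euclidean disc of radius 2 px
   into the band the diffusion step acts on.
4. **BSCB inpainting.** The vessel pixels are filled by an explicit PDE
   scheme that alternates isophote transport with curvature-driven
   diffusion (details below).
5. **Local Chan-Vese (LCV) level set.** A contour seeded automatically at
   the centroid of the brightest region evolves under a two-region energy
   with a local fitting term (`alpha = 0.1`, length weight
   `mu = 0.1 * 255^2`), yielding the cup mask.
6. **Evaluation.** Pixel precision/recall/F-score, mean radial boundary
   distance between contours, and the vertical CDR against a disc mask.

The optic disc itself is an *input*: in the clinical workflow it is
delineated manually (disc segmentation is much easier than cup
segmentation), and the CDR denominator needs it anyway.

## The inpainting scheme

Let `Omega` be the vessel mask and `Omega^eps` its dilation.  Writing `L`
for the propagation information and `T` for the unit isophote direction
(perpendicular to the intensity gradient), the scheme alternates, in
blocks of 15 transport sweeps followed by 2 diffusion sweeps:

* **transport** (inside `Omega`):
  `U <- U + (dt/255) * (grad L . T) * |grad U|_sl`
* **diffusion** (inside `Omega^eps`):
  `U <- U + dt * g * kappa * |grad U|`

`L` is the discrete Laplacian of `U` *averaged over the 3 x 3
neighborhood* of each pixel: transporting neighborhood-mean second
differences instead of single-pixel values is intended to make the
transferred information robust to pixel noise.  The single-pixel variant
is available (`bscb_params(propagation = "single_pixel")`), as is a
product form of combining the two second differences
(`laplacian_mode = "product"`); the default is the sum, which is the
discrete Laplacian.  `kappa` is the curvature of the isophotes (the
divergence of the normalized gradient, magnitude regularized by `1e-8`)
and `g` is a Gaussian-smoothed indicator of the band (`sigma = 1` px),
renormalized to [0, 1] and exactly zero outside it, so diffusion fades
out at the band boundary.

Two numerical choices matter and are worth stating explicitly:

* **Upwind transport.** The transport coefficient
  `beta = grad L . T` multiplies a *slope-limited* upwind gradient norm
  (backward/forward differences selected by the sign of `beta`), the
  discretization used throughout the inpainting literature this scheme
  descends from.  A plain central product `dt * grad L . T` is degenerate
  — on a perfectly straight dark strip both PDE terms vanish identically,
  so nothing fills — and we found it violently unstable under noise,
  because the unit direction field amplifies gradient noise in flat
  regions.  The upwind norm scales the update by the actual local
  contrast and keeps the explicit scheme stable.
* **Intensity normalization of the transport rate.** `beta * |grad U|` is
  quadratic in intensity, so the improvement rate is applied per unit
  intensity range (`dt/255`), equivalent to running the classical scheme
  on intensities normalized to [0, 1].  The diffusion term is linear in
  intensity and uses `dt` unchanged.  With `dt = 0.1` the scheme is
  stable on everything we generate.

Iteration stops at `total_iters` (default 3000) sweeps or when the mean
absolute change per `Omega` pixel and sweep over a whole
transport/diffusion block falls below `stop_tol` (default `1e-4`
intensity units).  Pixels outside the band are returned bit-identical to
the input.

### What the neighborhood averaging does and does not buy

The package exposes both propagation variants precisely so the claim
behind the neighborhood-mean design can be measured.  On noisy phantoms
(sigma = 8) with the true vessel mask as `Omega`, we find the
neighborhood-mean variant converges more *slowly* than the single-pixel
variant at a fixed sweep budget (the 3 x 3 average smears the propagation
information across a 3-px-wide vessel), and the two are statistically
indistinguishable at deep convergence.  The paired mean-absolute-error
comparison in `tests/testthat/test-acceptance.R` runs this experiment at
the defaults and reports it honestly; users wanting the fastest fill
should prefer `propagation = "single_pixel"`; the neighborhood-mean
design remains the default.

## The level-set stage

The LCV energy of a field `phi` (positive inside) on an image `I` is

```
E(phi) = mu * Length(phi)
       + int_in (I - c1)^2  + int_out (I - c2)^2
       + alpha * [ int_in (Id - d1)^2 + int_out (Id - d2)^2 ]
```

with `Id = boxmean(I, 15) - I` the local difference image, `c1, c2, d1,
d2` the region means that minimize each term, in/out defined through the
smoothed Heaviside `H(z) = (1 + (2/pi) atan(z/1.5)) / 2`, and the length
measured with the matching smoothed Dirac.  The global term drives the
two-phase partition; the local term tolerates the smooth intensity
inhomogeneity of a real cup; `alpha = 0.1` and `mu = 0.1 * 255^2` are the
settings for a single, inhomogeneous target on 8-bit intensities.

Evolution is explicit gradient descent (`dt = 0.1`) with signed-distance
reinitialization every 50 iterations, computed from exact Euclidean
distance transforms with a half-pixel offset so the discrete gradient
magnitude stays near one across the front.  The per-iteration
displacement is clamped to `max_step = 3` px: at the top of the
length-weight range (`mu = 255^2`) the explicit curvature term violates
its CFL bound and the front chatters without the clamp, inflating
contour perimeters.  Evolution stops early once the sign pattern of
`phi` changes by at most `max(2, 0.02%)` of the domain over a block; on
phantoms this happens after 150-850 iterations.  The cap is 2000
iterations — several times more than the textbook few hundred, because
with the statistics restricted to the disc the outside mean starts near
the rim level for large cups and the front creeps before it accelerates.

Seeding is automatic: the image is thresholded at its 97th intensity
percentile, the largest connected bright component is taken (the cup is
the brightest structure of the disc), and a circle of radius
`0.15 * min(H, W)` around its centroid initializes `phi`.

### The working domain

The level-set statistics are restricted to the optic-disc *domain*
(`domain =` argument of `select_seed()`, `lcv_energy()`, `evolve()` and
`segment_cup()`; the pipeline also crops the frame to the disc bounding
box padded by `roi_margin = 24` px for speed).  This is not an
optimization but a correctness requirement of the two-phase model: with
the whole frame in play, the dark retinal background drags the outside
mean `c2` far below the rim level, the two-phase threshold
`(c1 + c2)/2` lands at or below rim intensity, and the model prefers the
disc/retina partition over the cup/rim one — small cups then expand
catastrophically to the disc boundary, and bright inpainting scars near
the cup edge become energetically "inside" (we measured vertical CDR
overshoots of +0.18 that way).  With the statistics confined to the
disc, `c2` is the rim mean and the threshold sits halfway up the cup
rim ramp, where the true boundary is.  Full-frame behavior remains
available (`roi_margin = 0`, `domain = NULL`).

## Vessel threshold on noisy imagery

The extraction rule, taken literally, is strictly `U_sub > 0`.  On noise-free
imagery it is exact, and `vessel_params()` keeps `tau = 0` as the module
default.  Under *any* additive continuous noise, however, the rule fires
on about half of all pixels in flat regions (`P(U_sub > 0) ~ 0.5`), which
is above the 8-connected site-percolation threshold (~0.41): the false
positives form one giant connected component that no small-component
cleanup can remove — we measured the mask at ~47% of the frame with the
inpainting band at ~99.6% on a sigma = 4 phantom.  The pipeline default
is therefore `tau = "auto"`: twice the robust noise scale of the
difference image, `2 * 1.4826 * MAD(U_sub)`.  Vessels occupy a small
fraction of the frame, so the MAD measures the noise floor, and on
noise-free imagery the MAD is zero and the rule reduces exactly to the
strict literal one.

## The phantom generator

`make_phantom()` renders the structures the method depends on, with exact
ground truth:

* a bright elliptical disc (intensity 140) on a darker background (60),
  with a fixed 2-px edge ramp;
* a brighter elliptical cup (210) strictly inside it, whose rim ramp
  (smoothstep over `rim_softness = 6` px) is *centered on the true cup
  boundary*, so an unbiased segmenter crosses at the ramp midpoint;
* dark quadratic-Bezier vessels (width 3 px, depth 70) running from
  outside the disc across the cup boundary into the cup — the exact
  failure mode the method addresses;
* i.i.d. Gaussian noise (`sigma = 4`), then clipping and rounding to
  whole intensities, emulating 24-bit capture.

Ellipse membership uses a half-pixel-shifted center, so an integer
vertical semi-axis `a` covers exactly `2a` pixel rows and the true
vertical CDR of a centered phantom is exactly the semi-axis ratio; the
stored `true_cdr` is always computed from the masks with the same
`vertical_cdr()` the evaluation uses.  The green channel carries the full
signal; red and blue are fixed fractions (0.8, 0.4) of it.  One integer
seed drives everything; `make_suite(n, base, seed)` derives phantom seeds
as `seed * 1000 + i` and sweeps the target CDR linearly across
[0.32, 0.78] with ±10% axis and ±10 px center jitter, so a 20-phantom
suite spans the clinically relevant range deterministically.

What the phantoms do *not* emulate: vessel trees with branching and
varying caliber, the peripapillary atrophy and pallor textures of real
discs, non-elliptical cup shapes, illumination gradients across the
frame, and compression artifacts.  Passing the phantom suite therefore
demonstrates the pipeline's mechanics — vessel removal, boundary
recovery, CDR measurement — not clinical-grade accuracy.

## Problem sizes and runtime

Default phantoms are 480 x 480 with disc semi-axes (120, 132); the
pipeline processes the ~330 x 350 disc crop in roughly 5-8 s (about 1 s
median filtering, 2-4 s inpainting at <= 3000 sweeps, 1-3 s level-set
evolution).  The test suite runs its module tests on 192 x 192 phantoms
and the regression gate on the default 20-phantom suite; the acceptance
script reruns that suite end to end (with the inpainting ablation, 40
pipeline runs) in a few minutes.

## Evaluation conventions

* **F-score**: harmonic mean of pixel precision and recall; `F = 0` when
  there are no true positives, an error when both masks are empty.
* **Boundary distance**: rays from the centroid of the *reference*
  contour at 360 equally spaced angles (1° sampling; the count is a
  parameter); per ray, the absolute difference of the distances to the
  farthest intersection with each contour; averaged.  The farthest-hit
  rule makes the measure well defined for mildly non-convex boundaries.
  When a ray misses a contour entirely `boundary_distance()` errors; the
  pipeline-level report records `NA` instead, since a grossly misplaced
  prediction has no meaningful radial distance.
* **Vertical CDR**: inclusive row extent (`max - min + 1`) of cup over
  disc, measured independently (containment is not required).  The
  inclusive convention makes CDR exactly 1 for identical masks.
* Contours are traced at the 0.5 iso-level of the zero-padded mask
  (marching squares), oriented counter-clockwise, with the foreground
  pixel centroid attached.

## Known limitations

* The transport term cannot, even in principle, fill a perfectly
  straight, translation-invariant vessel on a constant background (both
  PDE terms vanish); filling proceeds from curvature and from intensity
  variation along the vessel, which real vessels and phantoms always
  provide, but convergence on long straight segments is slow.
* The two-phase level set assumes the cup is the single brightest
  structure within the disc; bright pathology (exudates) inside the disc
  would defeat the automatic seed.
* The CDR is measured on the raw row extents of the masks, so single-
  pixel protrusions move it; the length penalty keeps boundaries smooth
  enough in practice.
* All parameters were chosen on synthetic data; on real fundus
  photographs the enhancement and median window sizes interact with
  vessel caliber in pixels, i.e. with image resolution, and the sweep
  harness (`parameter_sweep()`) exists to re-examine them.
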