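---
title: "Membrane signal modelling and geometry analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane signal modelling and geometry analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryomem)
```

This vignette is the package's account of its models, parameter choices
and numerical decisions. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The bilayer model

A lipid bilayer seen edge-on projects to two dense headgroup bands
separated by a lighter tail region. `bilayer_profile()` parameterizes the
cross-section as a function of the normal offset $n$ from the bilayer
mid-plane:

$$ f(n) = A_h\!\left[e^{-(n-t/2)^2/2\sigma_h^2} +
          e^{-(n+t/2)^2/2\sigma_h^2}\right] +
          A_t\, e^{-\tfrac12 (n/\sigma_t)^4} $$

with head-to-head thickness $t = 40$ Å (the ~4 nm bilayer of
mitochondrial inner membranes), head band width $\sigma_h = 5$ Å, head
amplitude $A_h = 1$, and a *flat-topped* (fourth-order super-Gaussian)
tail plateau of amplitude $A_t = 0.35$ and half-width $\sigma_t = 8$ Å.
The profile is even in $n$ and decays to zero. The functional form is a
package choice — the cross-sectional density of a phospholipid projection
is not prescribed anywhere more precisely than "two bands" — and all five
parameters are exposed in `bilayer_profile_spec()`.

A 2D template is this profile rendered along a circular arc of constant
signed curvature $\kappa$ (in nm⁻¹) through the image centre, tangent
horizontal there; $\kappa > 0$ bends towards +y. A single-arc (constant
curvature) model is used because one local curvature per 2D average is
being estimated; multi-arc or spline membranes are out of scope.
Rendering integrates the profile over each pixel (3×3 subpixel
quadrature), which keeps the rendered mass independent of curvature and
pixel phase to <1% — a property the template bank's correlation
normalization relies on. `make_template_bank()` spans
$\kappa \in [0, 0.02]$ nm⁻¹ with 21 templates by default (grid spacing
0.001 nm⁻¹, within the 15–30 range that matched-filter practice uses for
this curvature span); negative curvatures are obtained by the up–down
flip symmetry rather than stored.

### Angles, folding, and the sign of curvature

Membrane lines are unoriented, so tangent angles live on
$[0°, 180°)$. The pair $(\theta, \kappa)$ and $(\theta + 180°, -\kappa)$
describe the same arc; `arc_segment()` therefore flips the curvature sign
whenever it folds an angle by 180°, and `canonical_arc()` maps any pair
to the representative with $\theta \in (-90°, 90°]$ so that estimates and
ground truth can be compared unambiguously. Getting this fold wrong
silently mirrors the bend direction — it is the single most error-prone
convention in the pipeline and is pinned by dedicated tests.

## 2. Detection

`match_templates()` computes, at every pixel, the maximum locally
normalized cross-correlation over the bank × a rotation grid (default
5°). Normalization follows the fast NCC scheme: the image's local mean
and power are computed once per image by FFT over a *circular* support
window (rotation-invariant, so one window serves all template angles),
and each rotated template is zero-meaned and unit-normalized within that
disc. Scores are therefore in $[-1, 1]$ and invariant to affine intensity
changes. `pick_segments()` takes local maxima above a threshold (default
0.4 — a toolkit choice; no canonical value exists) with greedy
non-maximum suppression and a lexicographic (row, col) tie-break for
bit-reproducibility.

Detection hands candidate centres to the curve-fitting stage; its own
localization is limited by the rotation grid and template/target
curvature mismatch (a few pixels for strongly curved segments at coarse
angle steps), which is why the recall suite scores a hit within half a
bilayer thickness (4 px at 4 Å/px) while the *refined* centre contract
below is 2 px.

## 3. Per-average curve estimation

**Orientation.** $\hat\theta$ maximizes the variance of the 1D projection
profile over projection angles (a Radon-transform criterion). Variance is
used instead of peak amplitude because it is robust to blobs crossing the
membrane. Two numerical details matter: (i) projections are taken inside
a circular aperture, otherwise the square frame's corners skew the
criterion by over a degree towards the diagonals; (ii) a coarse scan
(default 2°) is followed by a fine local re-scan (step/8) and three-point
parabolic interpolation. The centre offset along the membrane normal is
the positive-part intensity centroid of the profile at $\hat\theta$.

**Curvature.** The average is rotated to canonical orientation and
correlated against every bank template with a frequency-domain
translation search; because the canonical rotation is ambiguous by 180°,
both the rotation and its flip are scored, giving a signed curvature
axis from $-\kappa_{max}$ to $+\kappa_{max}$. Each template's score is
the *sub-pixel* correlation peak (separable parabolic refinement) — with
integer-pixel peaks the score-versus-$\kappa$ curve is quantization-lumpy
and interpolation lands up to 1.5 grid steps off. $\hat\kappa$ is the
parabolic interpolation of the smooth score curve around its maximum;
this interpolation is the resolution limit of the estimator, about half a
grid step (0.0005 nm⁻¹) in the worst case.

**Centre refinement.** The projected-centroid centre is biased for curved
membranes (the arc's mass centroid sits a sagitta-like offset
$R(1-\sin a/a)$, $a = L/2R$, from the arc midpoint — 13 Å at
$\kappa = 0.02$ nm⁻¹, $L = 400$ Å). `fit_membrane_curve()` removes the
bias by rendering the fitted arc and refining the shift by NCC against
the average (`refine_center()`, sub-pixel by parabolic interpolation).
Refinement warns when the peak sits on the search boundary or the
correlation is weak (<0.2).

On the standard synthetic suite (single arcs, random orientation and
±2 px centre offsets, 160² px at 4 Å/px, arc length 400 Å) the
end-to-end contract verified by the tests is: $\theta$ within 0.5°,
centre within 2 px, $\kappa$ within 0.0005 nm⁻¹ noise-free, and mean
$|\hat\kappa - \kappa| \le 0.002$ nm⁻¹ over 50 averages at SNR 0.5.

## 4. Membrane weakening

`estimate_membrane_signal()` realizes "local averaging along the membrane
curve" separably: the image is resampled into curve coordinates
$(s, n)$ — Catmull-Rom interpolation forward, on a grid oversampling the
raster (s: half-pixel, n: quarter-pixel) — a running average with window
$W = 150$ Å (edge-normalized) is applied along $s$ at each fixed $n$, and
the result is resampled back and multiplied by the soft mask. The $s$
grid stops at the arc termini: averaging across the terminus would mix in
empty background. Pixels outside the mask support are exactly zero, so
`weaken_membrane()` (`image − λ·estimate`) leaves them bit-identical.

The soft mask has a plateau $1.25 t/2 = 25$ Å half-width — 25% wider than
the bilayer — with a raised-cosine edge (default 10 Å). The end caps roll
off *inside* the arc, reaching zero at the terminus, because within half
a window of the end the estimate is extrapolated and the data's hard
terminus cannot be matched.

λ defaults to 0.7: the goal is *weakening*, not removal — partial
subtraction avoids overshoot where the single-arc model is imperfect —
and λ = 1 remains available (the subtraction contract is tested at
λ = 1, where ≤5% of in-mask power remains on noise-free fixtures).
Weakening fixtures are tested at 3 Å/px, typical of binned class
averages, where the 5 Å head bands are adequately sampled; at 4 Å/px the
double interpolation cost rises from ~0.6% to ~1.3% plateau RMS.

The *alignment benefit* suite constructs what the weakening exists for:
30 particles sharing one protein blob (amplitude half the head bands) at
varying positions alongside a membrane, SNR 2. Registering the blob by
NCC finds the membrane, not the blob, in every raw image; after λ = 1
weakening it finds the blob in every image. The suite's amplitudes are a
deliberately clean caricature — real protein signal overlaps the
membrane, so real gains are smaller.

## 5. 3D surface fitting and curvature

`sample_membrane_points()` binarizes a density map at a user threshold
(no canonical value exists; the synthetic fixtures use half the shell
maximum) and keeps voxel centres, carrying each voxel's density. The
reference plane is the total-least-squares plane (smallest principal axis
of the centred covariance); its normal is rotated to +z, with the sign
set by optional matrix-side markers, else by the skewness of the
out-of-plane coordinate, else by a fixed convention.

`fit_leaflet_surfaces()` fits the mid-surface as a Monge patch
$z(x, y)$ — single-valued by construction, which is why the plane
alignment comes first; folded membranes (vesicles, tubule caps) are out
of scope — by local quadratic (LOESS-style) regression, Gaussian kernel
bandwidth 30 Å, on a 10 Å grid. Two numerical choices matter:

* **Density weighting.** Points are weighted by their density values.
  With uniform weights, the voxel quantization of the shells produces
  terraces (at radius-of-curvature 1000 Å and 4 Å voxels the first
  terrace is ~90 Å wide) whose residual ripple corrupts second
  derivatives; density weighting recovers the sub-voxel shell centre and
  stabilizes the flattest fixtures.
* **Interior summaries.** Edge nodes are supported by one-sided data and
  truncated smoothing windows, which biases curvature low there;
  `curvature_summary()` therefore medians over the central 70% of the
  grid span.

Points are classified to leaflets by residual sign against the
mid-surface (robust at low point counts, unlike density bimodality), each
leaflet refitted with the same smoother, and a warning raised for
monolayer-like input (one leaflet under 10% of points, or leaflet
separation under a quarter of the nominal thickness).
`smooth_surface()` applies an NA-aware separable Gaussian (σ = 10 Å in
the validation suites — of the order of the regression bandwidth; larger
σ measurably attenuates curvature through boundary truncation, which the
tests quantify via the transfer function $e^{-2\pi^2\sigma^2/\lambda^2}$).

`surface_curvature()` evaluates H and K from the first and second
fundamental forms by central differences. Sign convention: **H > 0 is
convex towards +z** (the matrix side after alignment), so a dome is
positive and a bowl negative; H is reported in nm⁻¹, K in nm⁻². The
sphere-cap oracle (R = 300/500/1000 Å) recovers median H = 1/R within 5%
and K = 1/R² within 10%; a sinusoid fixture reproduces the qualitative
convex-crest / concave-trough signature that distinguishes the two ends
of a membrane-bound complex.

`make_planar_bilayer_lattice()` generates a hexagonal pseudo-lattice
(spacing 8 Å, head planes ±20 Å, two tail planes between) — an internal
stand-in for an external bilayer builder — and
`deform_planar_bilayer()` maps each atom at $(x, y, \delta)$ to the
surface point displaced $\delta$ along the local normal. Head atoms land
on the leaflet surfaces; lateral spacings are preserved to first order
(the residual $\delta\kappa$ stretch of a curved leaflet is real
geometry, ~4% for $\delta = 20$ Å at R = 500 Å, and is left in place).

## 6. Coordinate measurements

The membrane surface reference for ligand heights is a *scalar*: the mean
z of lipid-headgroup phosphorus atoms within a radius of a region centre
(the membrane region around the complex of interest), in the z-aligned
frame. The M-distance is the signed z of the ligand reference atom minus
that height; the reference atom is the quinone 1-carbonyl oxygen (`O1`),
falling back to the selection centroid. The E-distance needs a
channel-entrance landmark that has no operational definition in the
coordinate databanks, so it is a required user input. Group distances use
the minimum pairwise mode by default (the convention adopted for
iron–sulfur-cluster-to-ligand distances, with the fast evaluation made
bit-identical to the naive pairwise formula); centroid mode is available.
All distance operations are rigid-motion invariant, which the tests check
under random rotations.

Synthetic coordinate fixtures (`make_fixture_model()`) put phosphorus
pseudo-atoms on a jittered lattice and one ligand atom at a known height,
giving exact expected values (0 and 20 Å mirror the flush and
fully-bound quinone states; 2 Å jitter on ~440 atoms bounds the height
error by the standard error of the mean, ~0.1 Å).

## 7. Synthetic data: what it does and does not emulate

The 2D generator renders arcs with the package's own bilayer profile,
adds globular Gaussian blobs outside a one-thickness exclusion zone
(so subtraction tests have a clean "protein untouched" region), and adds
white Gaussian noise scaled so that var(signal)/var(noise) equals the
requested SNR (the suites use SNR 0.5 for micrographs — thick in situ
samples are low-contrast — and noise-free images for "class averages").
Identical spec + seed is bit-identical. Deliberately *not* modelled: CTF
modulation (the estimators operate on class averages where the CTF is
already mixed; the `em_dark` contrast flag is the only nod to raw-data
contrast), detector/Poisson noise, tilted-view membrane projections,
crossing membranes, and structured protein shapes. Passing these suites
therefore demonstrates the estimators' correctness and calibration on
clean geometry, not performance on real micrographs.

The 3D generator builds two Gaussian shells (σ = 4 Å) at ±t/2 along the
local normal of an analytic surface (plane, spherical cap, sinusoid),
optionally with a transmembrane cylinder; the analytic surface is
returned alongside and is the oracle for every 3D test.

## 8. Problem sizes and runtimes

The validation suites are sized to run on one CPU in a few minutes
total: 160²–256² px images at 3–4 Å/px, 20 noise-free plus 50 noisy
averages for 2D recovery, 10 micrographs for detection, 30 particles for
the alignment benefit, and 64³ voxel volumes at 4 Å for the 3D stage.
These sizes are the package's validation choices; every generator scales
to larger rasters.

## 9. Known limitations

* Single-arc membranes only; no splines, no crossing membranes.
* Monge-patch surfaces only; no closed or folded topology.
* The Radon orientation estimator assumes one dominant linear feature;
  two membranes in one average will bias it.
* Curvature resolution is set by the bank grid and parabolic
  interpolation (~0.0005 nm⁻¹); a finer bank buys resolution linearly in
  compute.
* The weakening estimate is separable (running average along s at fixed
  n); no per-frequency (Wiener) subtraction.
* Lipid category labels (structured / surface-associated / generic
  bilayer) are descriptive distance-shell labels, not chemical
  identifications.
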