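# cryomem

Membrane signal modelling and geometry analysis for in situ cryo-EM.

## The problem

Membrane-protein complexes imaged inside their native environment — for
example respiratory supercomplexes in intact mitochondrial inner membranes —
sit in lipid bilayers whose edge-on ("side view") signal is far stronger
than the protein signal. That membrane signal dominates 2D alignment and
classification, blurring the protein averages, while at the same time the
local geometry of the membrane around a complex (convex at one end, concave
at the other) is itself a quantity of biological interest. `cryomem`
implements the computational stages needed to work with both aspects:

1. **Template simulation.** 2D projections of a lipid bilayer are simulated
   as a density profile rendered along a circular arc: two Gaussian
   headgroup bands at ±t/2 (head-to-head thickness t ≈ 40 Å) over a lower
   tail plateau. A bank of 15–30 templates spans local curvature
   κ ∈ [0, 0.02] nm⁻¹.
2. **Detection.** Membrane side views are found by a matched filter: the
   maximum locally normalized cross-correlation (NCC) over all templates
   rotated through θ ∈ [0°, 180°), followed by non-maximum suppression.
3. **Curve fitting.** For each 2D average, the tangent angle θ̂ maximizes
   the variance of the Radon projection profile; the centre comes from the
   profile centroid plus an NCC refinement; the local curvature κ̂
   maximizes the NCC against the curvature-indexed bank, with parabolic
   interpolation between bank members.
4. **Membrane weakening.** The membrane's principal signal is estimated by
   resampling the image into curve coordinates (arc length s, normal
   offset n), running-averaging along s, and masking with a soft mask
   ~25% wider than the bilayer; the output is `image − λ·estimate`
   (default λ = 0.7), leaving pixels outside the mask bit-identical.
5. **3D surface modelling.** Points sampled from binarized membrane
   density are aligned by a total-least-squares plane fit (normal → z),
   fitted as a Monge patch z(x, y) by local quadratic regression into a
   mid-surface and two leaflet surfaces ~4 nm apart, Gaussian-smoothed, and
   differentiated into altitude maps, mean curvature H and Gaussian
   curvature K (sphere of radius R: H = 1/R, K = 1/R²). A planar
   phospholipid pseudo-lattice can be deformed onto the fitted surface.
6. **Coordinate measurements.** Membrane-surface height (mean lipid
   headgroup z in a region), the signed ligand height above that surface
   (M-distance, e.g. a quinone headgroup above the membrane), distance to a
   user-supplied channel-entrance landmark (E-distance), and minimum /
   centroid inter-group distances (e.g. Rieske [2Fe–2S] to quinone).

Everything is validated against seeded synthetic generators with exact
ground truth (module `simulate_micrograph` / `simulate_membrane_volume` /
`make_fixture_model`), so every stage has an analytic or constructed
oracle.

## Worked example

Fit a membrane curve to a synthetic class average and weaken it:

```r
library(cryomem)

bank <- make_template_bank(n_templates = 21, length = 400,
                           image_size = 128, pixel_size = 4)
seg  <- ground_truth_segment(centre = c(10, -20), theta = 25,
                             kappa = 0.012, length = 400)
avg  <- simulate_micrograph(sim_spec_2d(image_size = 160, pixel_size = 4,
                                        segments = list(seg),
                                        noise_model = "none"))$image
fit  <- fit_membrane_curve(avg, bank)
fit$kappa        # 0.01241  (truth 0.012 nm^-1)
fit$theta        # 25.01    (truth 25 deg)

est  <- estimate_membrane_signal(avg, fit$curve, weaken_config())
weak <- weaken_membrane(avg, est, lambda = 1)
```

The numbered drivers under `analysis/` run the full study on generated
data and print their findings; on the default seeds they report, among
others:

```
detect:  overall recall 96.7%, 0.10 false positives/image
weaken:  lambda 1.0: in-mask residual power 1.83%
weaken:  blob registration success: 0% before vs 100% after weakening
surface: R= 500 Å: median H 0.01976 nm^-1 (true 0.02000, -1.2%)
curvmap: crest H +0.0437 nm^-1 (convex), trough H -0.0498 nm^-1 (concave)
measure: fixture_ligand_20A.pdb: M-distance +19.94 Å (truth 20)
```

i.e. detection recovers nearly all membrane segments at SNR 0.5, full
subtraction removes ~98% of in-mask membrane power and rescues protein
(blob) registration that the membrane previously dominated, sphere-cap
fixtures recover 1/R within a few percent, and ligand-height measurements
are exact on constructed models.

## Layout

- `R/` — the package: generators, template bank, detection, curve
  geometry, weakening, 3D surfaces, measurements, MRC/STAR/OBJ/PDB I/O.
- `analysis/01…05_*.R` — numbered drivers running the study on synthetic
  data; outputs under `results/`.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/membrane-geometry.Rmd` — the methods vignette: models,
  parameter choices, numerical decisions, limitations.
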