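# spinocurve

Segmentation and curvature analysis of cervical flexion-extension
radiographs.

Flexion-extension radiographs — paired lateral X-rays of the neck bent
forward and backward — are the standard follow-up examination after
cervical fusion surgery, and they are hard to read by eye: the clinical
criteria track relative motion of fused vertebrae, and inter-observer
agreement is poor. spinocurve is for researchers and imaging engineers
who want a quantitative, reproducible description of such images. It
segments a radiograph into intensity clusters, extracts the spinolaminar
(SL) line (the smooth curve along the posterior vertebral arches), and
quantifies it by differential geometry; with a mirroring step, the same
pipeline extracts the contour of an implanted anterior cervical plate and
measures its in-situ lordotic radius.

The pipeline, for pixel domain Ω and tuning parameters (K, j, d, δ):

1. K-means on pixel intensities: Ω = S₁ ∪ … ∪ S_K, clusters ranked by
   mean intensity; S_j captures the bone outline.
2. Morphological erosion of the complement, M = S̄_j ⊖ H, with a disk H
   of diameter d — narrow intervertebral gaps seal, separating the
   posterior from the anterior background.
3. Two-pass connected-component labeling of M; among the three largest
   regions, the one nearest the upper-left corner is the reference R₁.
4. Boundary points of S_j within distance δ of ∂R₁ are the SL
   candidates; a manual rectangular ROI removes skull/T1 sections.
5. A sixth-order polynomial f(s) = a₆s⁶ + … + a₀ is fit to the ordered
   points; local curvature c(s) = f″ (1 + f′²)^(−3/2), average curvature
   κ̄ = (θ(s₂) − θ(s₁)) / arc length with θ = atan f′, and flexural
   rigidity EI(s) = M(s)/κ(s) for a user-supplied bending moment M(s).
6. Plate analysis mirrors the image, reruns the pipeline, and fits the
   osculating circle at the plate's arc-length mid-point; the radius is
   reported in multiples of the plate length L.

A phantom generator produces radiograph-like images (skull blob,
vertebra chain along a parametric curve, optional plate strip with a
built-in radius, Gaussian noise) with exact ground truth, so every stage
is testable without patient data.

## Worked example

Generate an arc phantom whose SL curve has radius 400 px, run the full
pipeline, and recover the curvature:

```r
library(spinocurve)

ph  <- generate_phantom(arc_phantom_spec(radius = 400, seed = 1))
cfg <- phantom_sl_config(ph)   # K=2, j=2, d=13, delta=18, ROI below skull
pts <- extract_landmark_points(ph$image, cfg)
fit <- fit_polynomial(order_points(pts, cfg$fit_axis))
prof <- curvature(fit)
prof
#> <curvature_profile> 200 samples, s in [138.8, 549.2]
#>   mean |c| = 0.002503 /px, kappa_bar = 0.002503 /px, total rotation = 1.094 rad
```

The mean curvature 0.002503 /px is 1/399.4 — the generating radius of
400 px recovered to 0.15% from integer pixel coordinates. Plate
analysis on a flexion/extension phantom pair with built-in radii 3.7 L
and 6.1 L:

```r
base <- phantom_spec(480, 170,
                     sl = list(shape = "line", col0 = 55, slope = 0),
                     plate = list(ratio = 3.7, length_px = 320, width = 6),
                     seed = 1)
pair <- generate_flexext_pair(base, 3.7, 6.1, what = "plate")
models <- lapply(names(pair), function(st) {
  pcfg <- phantom_plate_config(pair[[st]])
  fit_osculating_circle(extract_plate_contour(pair[[st]]$image, pcfg),
                        axis = pcfg$fit_axis, state = st)
})
models[[1]]
#> <plate_model> [flexion] L = 320.0 px
#>   osculating radius: 1174.1 px = 3.67 L; mean curvature 0.2726 1/L (lordotic)
compare_plate_states(models)
#>      state L_px osc_radius_L mean_curvature_invL
#>    flexion  320     3.668934           0.2725588
#>  extension  320     6.091659           0.1641589
#> curvature ordering (largest first): flexion > extension
```

The built-in radii are recovered to about 1% (3.67 L and 6.09 L), and
the flexion state shows the larger lordotic curvature, as generated.

## Command line

A thin Rscript front end is installed under `exec/`:

```sh
SPINO=$(Rscript -e 'cat(file.path(find.package("spinocurve"), "exec", "spinocurve"))')
Rscript $SPINO phantom --out-dir ph --sl-radius 300 --seed 5
Rscript $SPINO slline  --image ph/phantom.png --config ph/config.yaml --out-dir out
Rscript $SPINO plate   --image img.png --config cfg.yaml --out-dir out --state flexion
```

Subcommands: `segment`, `slline`, `plate`, `phantom`, `compare`.
Outputs are cluster masks and overlays (PNG), point and curvature tables
(CSV), plate reports (JSON) and a run manifest; exit codes are 0
(success), 2 (validation error), 3 (empty selection). Configs are YAML
or JSON with keys `K, j, d, delta, roi, plate_length_L, fit_axis, seed`.

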