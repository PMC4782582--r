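---
title: "Methods: segmentation and curvature analysis of cervical radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and curvature analysis of cervical radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinocurve)
```

## The problem

Flexion-extension radiographs — paired lateral X-rays of the cervical spine
taken with the neck bent forward and backward — are the standard follow-up
examination after cervical fusion surgery.  They are notoriously hard to
read: the clinical criteria compare relative motion of fused vertebrae
between the two views, and inter-observer agreement is poor.  spinocurve
implements a semiautomatic, quantitative alternative: segment the
radiograph into intensity clusters, extract the spinolaminar (SL) line —
the smooth curve along the posterior vertebral arches, a classical
"fingerprint" of vertebral alignment — and describe it by its local
curvature rather than by manually placed landmark angles.  Because
curvature is a second derivative of position, it is far more sensitive to
local motion abnormalities than the traditional Cobb angle; the same
sensitivity also amplifies segmentation errors, which is why every stage
of this pipeline is contract-tested against brute-force oracles and
synthetic phantoms with exactly known geometry.

With a simple left-right mirroring of the image the identical pipeline
extracts the *anterior* contour of the vertebral column, including an
implanted anterior cervical plate.  Plates are manufactured with a
built-in lordotic radius (commonly quoted as 2–5 plate lengths); fitting
an osculating circle at the plate mid-point measures the in-situ radius in
units of the plate length `L` and lets flexion, neutral and extension
states be compared.

## The pipeline

Let $\Omega$ be the pixel domain.  The stages are:

1. **Intensity clustering.**  K-means on the 1-D pixel intensities
   partitions $\Omega$ into clusters $S_1, \dots, S_K$ ordered by
   ascending mean intensity, $\Omega = \bigcup_k S_k$.  One cluster $S_j$
   captures the bone outline; $K$ and $j$ are per-image tuning parameters
   (clinical images typically need $K \in 4..7$, $j \in \{K-1, K-2\}$).
2. **Morphological erosion.**  The complement of $S_j$ is eroded with a
   disk structuring element $H$ of diameter $d$: $M = \bar S_j \ominus H$.
   Narrow dark channels — intervertebral gaps — are sealed, so the
   posterior background separates cleanly from the anterior background.
3. **Connected components.**  $M$ is labeled by the classical two-pass
   algorithm with union-find equivalence resolution.  Among the three
   largest regions, the one whose nearest pixel is closest to the
   upper-left image corner is the reference region $R_1$; its outer
   boundary $\sigma_1 = \partial R_1$ runs alongside the SL line.
4. **Proximity selection.**  The closed boundaries of $S_j$ are traced
   (Moore neighbor tracing); boundary points within Euclidean distance
   $\delta$ of $\sigma_1$ are kept as SL-line candidates.  A manually
   supplied rectangular ROI removes skull and upper-thoracic sections.
5. **Geometry.**  The points are ordered along the dominant coordinate
   ($s$), duplicates are averaged, and a sixth-order polynomial
   $f(s) = a_6 s^6 + \dots + a_0$ is fit by least squares.  The local
   curvature is
   $c(s) = \ddot f \, (1 + \dot f^2)^{-3/2}$,
   the tangent angle is $\theta(s) = \arctan \dot f$, and the average
   curvature over a segment is total tangent rotation divided by arc
   length: $\bar\kappa \cdot \mathrm{arclen} = \theta(s_2) - \theta(s_1)$.
   With a user-supplied bending moment $M(s)$, the beam-mechanics
   flexural rigidity is $EI(s) = M(s)/\kappa(s)$.
6. **Plate analysis.**  The pipeline runs on the mirrored image, the ROI
   brackets the plate rows, and a fresh degree-2 fit centered at the
   contour's arc-length mid-point gives the osculating radius
   $1/|c|$, reported in pixels and in multiples of the plate length
   (straight-line distance between the contour endpoints).

## Conventions and tunable parameters

* **Coordinates** are (row, col), 0-based, origin at the top-left pixel,
  rows increasing downward; "x" in fits means column, "y" means row.
  Anterior is toward larger column indices (a left-facing lateral view);
  mirrored runs return coordinates mapped back to the unmirrored frame.
* **Intensities** are min-max normalized to [0, 1] per image before
  clustering, so the parameter regimes transfer across bit depths; a
  constant image maps to zeros rather than erroring.  Whether clinical
  images should be histogram-equalized first is an open question; we fix
  plain min-max and document it.  RGB input collapses by unweighted
  channel mean.
* **K-means** uses Lloyd iterations (stats::kmeans, at most 300) with
  deterministic quantile seeding: centers start at the $(k-0.5)/K$
  intensity quantiles.  Cluster indices are only meaningful if labeling
  is reproducible, hence the deterministic default; seeded k-means++ is
  available for images whose intensity distribution defeats quantile
  seeding.  Features are intensities only — no spatial coordinates.
* **Disk element**: integer offsets with $dr^2 + dc^2 \le (d/2)^2$, so
  `d` is a true diameter and even `d` still gives a centered symmetric
  disk; outside-image pixels count as background (erosion shrinks at
  borders).  `d = 1` is the identity, `d = 3` the full 3×3 neighborhood.
* **Connectivity** is 8 for foreground throughout; labels are renumbered
  in raster order of each component's first pixel, and the region table
  is sorted by descending area with raster-order tie-breaks, making every
  downstream selection deterministic.
* **"Closest to the upper-left corner"** is resolved as nearest-pixel
  distance to pixel (0, 0); centroid distance is available behind
  `mode = "centroid"` in `pick_reference_region()`.
* **δ-selection** is per point (each boundary point is kept or dropped on
  its own distance); whole-loop acceptance is available via
  `whole_loop = TRUE`.  The distance is the exact Euclidean nearest-point
  distance, tested against dense pairwise brute force.
* **Polynomial fitting** happens in a centered frame with $s$ scaled to
  $[-1, 1]$: a raw degree-6 Vandermonde over pixel coordinates (up to
  thousands of pixels) is numerically unusable.  Coefficients are stored
  in both frames; evaluation and differentiation in pixel units are
  exact through the chain rule.  Duplicate $s$ values are merged by
  averaging the transverse coordinate (dropping them instead is the
  other defensible choice; averaging uses all measurements).
* **Endpoint trimming**: curvature profiles default to the central 90% of
  the fitted range, because polynomial edge oscillation makes the
  endpoints untrustworthy — the same drift that affects the C7 end of
  clinical extractions.  Curvature is stored signed (reflecting the
  points across the s-axis negates it exactly); overlays display the
  magnitude scaled by 5/L, a display convention only.
* **Osculating fit**: the degree-2 "truncation" is a fresh least-squares
  refit centered at the arc-length mid-point, not a zeroing of
  $a_3..a_6$ — coefficient zeroing of an ill-conditioned raw fit is
  frame-dependent (the literal truncation is available via
  `truncate = TRUE`).  Two numerical refinements matter: the refit uses
  arc length as abscissa (for a circle its quartic truncation bias is a
  third of the coordinate frame's), and it is restricted to an arc
  window of $\pm 0.25/|c|$ around the mid-point, iterated so the window
  uses the current curvature estimate.  A least-squares parabola over a
  wide arc is *not* the osculating parabola; the window keeps the
  truncation bias below the pixel-quantization noise.  Typical plates
  subtend less than 30°, where the window is slack and every point is
  used, so no precision is lost on real plate contours.  Lordosis is
  flagged when the center of curvature lies posterior of the mid-point.
* **Bending moments are never inferred**: `flexural_rigidity()` takes
  $M(s)$ as input and masks positions where $|\kappa|$ falls below
  $10^{-9}$ of its maximum.

## The phantom generator

Phantoms exist to make every pipeline contract testable without clinical
data.  They emulate the scene knowledge the segmentation relies on — a
dark background, a bright skull mass in the upper-left quadrant, a chain
of bright vertebra-like blobs whose posterior edges trace a smooth
parametric SL curve (circle arc, line, or polynomial), and optionally a
very bright anterior plate strip with a built-in radius expressed in
multiples of the plate length — plus additive Gaussian noise, clipped to
[0, 1].  They deliberately do **not** model radiographic realism: no
beam hardening, scatter, soft-tissue gradients, overlapping anatomy or
intensity inhomogeneity.  Passing phantom tests therefore demonstrates
that the pipeline's *contracts* hold (partition exactness, oracle-exact
morphology, curvature recovery under pixel quantization), not that the
tool segments arbitrary clinical radiographs; on real images the K, j,
d, δ parameters must still be tuned per image.

Design choices, fixed once:

* Intensity levels 0.08 (background), 0.52 (bone and skull), 0.92
  (plate), noise σ = 0.02.  The modes are far enough apart that K-means
  separability is guaranteed and noise never flips a pixel's cluster;
  the histogram-mode contract is tested.
* The vertebral chain is a slab 40 px deep anterior of the SL curve,
  carved by 4 px intervertebral notches that stop 13 px short of the
  posterior edge — a continuous laminar bridge, so the posterior
  boundary follows the SL curve exactly while the blobs stay visually
  distinct.  The bridge depth is measured along the local curve normal:
  on steep arc sections a fixed horizontal bridge would let notch-face
  pixels slip inside δ of the reference boundary and bias the fit.
* Matched configs use d = 13, δ = 18 — a parameter regime used for
  clinical images — with K = 2 (no plate) or K = 3 (plate) and j = K.
  The phantom's flat background needs fewer clusters than clinical
  radiographs, whose soft-tissue and metal gradations produce the
  K ∈ 4..7 regimes; with mass-quantile seeding, K-means on the phantom
  resolves {background-low, background-high, bright structures}.
* The default skull blob is sized and placed so the background corridor
  between skull and left image edge survives the erosion; otherwise the
  upper-left corner splits off as a separate region, and the reference
  region selection (nearest pixel to the corner, among the three
  largest) would latch onto a sliver.
* Arc phantoms are sized so the fitted span supports curvature recovery
  at pixel quantization: heights 340–580 px for radii 200–800 px
  (`arc_phantom_spec()`).  A degree-6 fit needs roughly 420 rows of
  support to recover a 800 px radius to 5% from integer coordinates.
* Plate phantoms use a 320 px plate (width 6 px) on a straight chain in
  a 480×170 px image; the plate's outer edge is a circle arc with a
  vertical chord of exactly L, touching the vertebral bodies, with the
  anterior edge tapered back to the bodies beyond the plate ends so the
  anterior contour is continuous and the extracted endpoints measure L
  correctly.  Radius recovery across the manufacturer grid
  {2L, 3.7L, 5L, 6.1L} is within ~1.5% at this geometry.
* All randomness (the noise field) flows from one integer seed;
  identical specs generate bit-identical phantoms, and ground truth
  (curve samples at ~1 px arc spacing with analytic curvature, plate
  edge samples, radius, L) is computed from the parametric forms, never
  from the raster.

## Numerical choices and degenerate inputs

* Lloyd iterations stop when assignments stabilize (at most 300
  iterations); images with fewer distinct intensities than K reduce K
  with a warning, or error in strict mode.
* Arc length uses adaptive quadrature (`stats::integrate`,
  rel.tol 1e-10) of $\sqrt{1 + \dot f^2}$; the identity
  $\bar\kappa \cdot \mathrm{arclen} = \Delta\theta$ holds to 1e-6 for
  every fit and is asserted.
* Rank-deficient designs (clustered $s$) raise a conditioning error with
  advice to widen the ROI; fewer than 8 distinct ordered coordinates is
  an insufficient-data error; grids outside the fitted range raise
  extrapolation errors rather than extrapolating silently.
* Collinear plate contours report an infinite radius with a "straight
  plate" flag instead of dividing by zero.
* CSV outputs are written with a fixed-format writer so that identical
  inputs and seed give byte-identical files; the run manifest records
  wall-clock timings and is therefore excluded from byte-identity
  checks.

## Known limitations

* Curvature recovery from integer pixel coordinates degrades sharply for
  small radii: a degree-6 fit on a quantized 90° arc of radius 30 px has
  ~7% curvature error (about 42 distinct support points against 7
  parameters), versus <2% at radius 120 px.  Sub-5% recovery at such
  small radii would need sub-pixel edge localization, which the pipeline
  does not attempt.  At radiograph-realistic SL radii (hundreds of
  pixels) with adequate fitted spans, recovery is well under 5%.
* The degree-6 polynomial is a global model: localized kinks spread into
  neighboring curvature estimates, and the untrimmed endpoints
  oscillate.  Spline or robust alternatives are deliberate non-goals.
* ROI selection is manual (config-supplied rectangle); automating it via
  the skull–C1 corner is future work, as is any clinical validation of
  curvature-based fusion criteria — this package measures geometry and
  attaches no diagnostic judgment.

## Problem sizes used in the test suite

The suite regenerates all fixtures in code: 50 random 24×24 images for
the partition contract, 200 random 32×32 masks for the erosion and
labeling oracles (d ∈ {3, 5, 13}, both connectivities), arc phantoms at
radii {200, 400, 800} px (images up to 580×270) for end-to-end recovery,
and four plate phantoms (480×170, L = 320 px) across the manufacturer
radius grid.  The full suite runs in about a minute on one CPU.
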