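---
title: "Designing porous fiber matrices in silico: model, metrics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing porous fiber matrices in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cellulose-based delivery matrices — mats of micro- and nanofibrillated
cellulose (MFC/NFC) with carboxymethylcellulose — release incorporated
biomolecules at a rate controlled by their porosity and pore-size
distribution. Tuning those properties experimentally is slow: every
candidate furnish and forming condition needs SEM imaging and image
analysis. `fibermat` implements the computational side of that design loop:

1. a voxel-based 3D fiber deposition simulator,
2. micrograph-style structure metrics (porosity, pore areas, fiber widths)
   applied identically to simulated top views and segmented micrographs,
3. a design-of-experiments layer that sweeps the fiber-parameter space,
   organizes the results with CART regression and classification trees, and
   selects the design with the best combination of porosity and pore
   uniformity inside a target pore-size window.

A synthetic-data module generates fiber populations and phantom images with
exactly known ground truth so that the entire pipeline is testable with no
external data.

## The deposition model

Fibers are straight ribbons of voxels on an `Nx x Ny x Nz` grid
(`z` = thickness direction, substrate at `z = 0`). A fiber is parameterized
by width `w`, length `l = aspect_ratio * w`, wall thickness (vertical solid
thickness `t = 2 * wall` for a collapsed lumen, `+ lumen` when open) and an
integer flexibility `F`. Fibers arrive sequentially at uniform random
positions and orientations. Each lands on the growing structure with bottom
surface `b(i, j)`, the minimal surface that

* rests on or above the current height map, and
* changes by at most `F` voxels between lateral neighbours inside the
  footprint (computed by fixed-point relaxation from the rigid solution).

`F = 0` gives rigid bridging — the fiber lies flat at the highest support
point, trapping voids under its overhangs; large `F` drapes the fiber fully
onto the surface, creating no new void. This is the classical voxel-mat
interpretation of an integer fiber-flexibility parameter, chosen because it
reproduces both limits exactly; the underlying simulator this re-implements
documents only that fibers are voxel chains with a flexibility input, so the
draping rule is a declared reconstruction. Deposition stops when the summed
footprint area reaches `target_layers` times the domain area ("number of
layers in the thickness direction"). No voxel is ever overwritten, so the
solid volume equals the sum of per-fiber voxel counts exactly — a
conservation law asserted on every simulated structure in the test-suite.

Two consequences of this model are worth stating because they are sometimes
assumed the other way around:

* **Bulk porosity rises with coverage for rigid mats.** The first layer
  lands on the flat substrate and is nearly dense; later fibers bridge over
  roughness and trap voids. Porosity therefore *increases* with
  `target_layers` (saturating), and *decreases* with flexibility.
* **Integer flexibility quantizes the drape.** Halving the voxel size leaves
  rigid-mat porosity essentially unchanged (< 1 pp) but shifts
  flexible-fiber porosity by a few points when fibers are only ~4 voxels
  wide; the scale-consistency test uses 8-voxel-wide flexible fibers.
  Sub-voxel fiber dimensions are clamped to one voxel: nano-scale furnishes
  must be simulated at nano resolution.

One desk-scale concession: a fiber longer than the periodic domain would
wrap onto itself and violate the no-overwrite invariant, so fiber length in
voxels is capped at `min(Nx, Ny) - w - 2`. At the default nano-run
resolution (0.1 µm/voxel, 256–512 voxel domains) the widest measured fibers
(9.8 µm wide, aspect 20) are therefore length-truncated; this compresses
the influence of aspect ratio for the micro mode and is the main reason the
sweep is labelled a scaled-down reconstruction.

## Structure metrics

All 2D measurements share one convention: solid = 1, pore = 0, with the
physical resolution attached to the image.

* **Surface porosity** is the void-pixel fraction.
* **Top views** of simulated structures mark a pixel solid iff its column
  holds a solid voxel within a visibility depth `d` of the global maximum
  height (an SEM depth-of-visibility surrogate); `d = Inf` gives the
  full-depth coverage view used by the calibrated configurations.
* **Pore areas** are connected components of the void phase, 8-connected
  (solid 4-connected — the complementary pair avoids topological
  paradoxes), border-touching components included, area = pixel count x
  resolution².
* **Fiber widths** come from a Zhang–Suen skeleton of the solid phase with
  width = 2 x Euclidean distance to the nearest void pixel at each skeleton
  pixel — the standard micrograph fiber-diameter morphometry. The sample is
  per skeleton pixel, so fibers weigh proportionally to their length.
* **Bulk porosity** is `1 - solid / (area x mean height)`. By default the
  area and mean height are taken over covered columns only (a half-covered
  slab of uniform thickness is 0% porous); `convention = "full"` uses the
  whole domain area instead (the same slab is 50% porous). Both are exposed
  because micrograph-derived porosities correspond more closely to the
  covered convention while Boolean-model arguments use the full one.

Segmentation of grayscale (SEM-like) images uses global Otsu thresholding by
default, followed by despeckling (components of either phase below 4 px are
merged into their surroundings). Otsu needs a genuinely bimodal histogram: a
single 25 px pore in a 10⁴ px frame is too small a class, and the
test-suite's round-trip check for that case uses the rendering's known
midpoint threshold instead. Accuracy on realistic multi-pore phantoms
(porosity recovered within ±0.02 at blur ≤ 2 px, noise ≤ 0.05) is asserted
in the suite with Otsu.

## The synthetic world

The generator states, once, the world the tests run in:

* **Fiber widths** span 0.0685–9.8 µm — the measured range for the
  MFC-NFC-CMC furnish. Only the range is known, so the default law is
  log-uniform across it (mass spread evenly over the two decades); a
  two-mode variant (log-uniform within each half of the log-range, nano
  fraction = `mixture_weight`) represents MFC/NFC mixtures. Aspect ratio
  defaults to 20 and wall thickness to 0.5 µm, typical of fibrillated
  cellulose; flexibility defaults to 1 (semi-conformable).
* **Phantom images** carve disc/rectangle pores from a solid (or
  fibrous-textured) background; ground truth is computed by direct pixel
  counting and is exact by construction. Phantoms exercise segmentation and
  morphometry; they do not emulate SEM contrast physics (charging, depth
  shading), so a green phantom test establishes correctness of the
  measurement chain, not robustness to every real-world imaging artifact.
* **SEM-like rendering** is binary → Gaussian blur → additive Gaussian
  noise, clipped to [0, 1], solid bright. That is sufficient to exercise
  thresholding; nothing more is claimed.

Every stochastic routine takes one seed; internal streams are derived
deterministically (`derive_seed()` mixes the master seed with stage/design/
replicate indices through a 31-bit congruential hash), so whole sweeps are
reproducible piecemeal.

## Calibration of the two reproduction targets

The reference study reports an experimental surface porosity of ~34%, a
computational surface porosity of ~36% for the simulator matched to the
measured fiber data, and an optimized best combination of 39.8% porosity
with pores inside 0.02–120 µm². The micrographs behind the 34% are not
deposited, so the experimental number is used only as a plausibility range.
The two computational numbers are reproduced by one-time calibration,
committed to the repository and never tuned per run:

* **Validation point (36%).** `inst/extdata/calibration_micro.yaml` fixes a
  log-uniform 0.0685–9.8 µm furnish (aspect 20, wall 0.5 µm, flexibility 1)
  at 0.1 µm/voxel on a 512² domain, full-depth top view. In this thin-mat
  regime surface porosity follows the Boolean-model law
  `porosity ~ exp(-coverage)`, so the committed `target_layers = 0.94`
  yields 36% ± 1 pp; 20 derived seeds bring the Monte-Carlo error of the
  mean below 0.5 pp. The calibration consisted of measuring the
  porosity–coverage curve once on a layer grid and committing the matching
  coverage — exactly the validation exercise the original workflow
  describes, since neither the simulator's internal settings nor its
  parameter values are published.
* **Sweep optimum (39.8%).** The default design space
  (`default_design_space()`) varies aspect ratio 10–30, wall 0.3–0.8 µm,
  flexibility 0–2, nano-mode fraction 0.5–0.9 and coverage 0.6–0.8 layers
  around the validation point, simulated at the same resolution with a
  two-mode furnish and measured at full depth. Suitability requires pore
  P5 ≥ 0.02 and P95 ≤ 120 µm² (percentiles rather than absolute extremes,
  which are unstable at desk-scale pore counts); among suitable designs the
  optimum minimizes the pore-area CV, pooled across replicates via moment
  combination (a lower-variance uniformity estimate than averaging
  per-image CVs). Ties break by porosity closest to the suitable-set
  median, then lowest design index. The coverage range was calibrated once
  by evaluating candidate ranges over several master seeds and committing
  the one whose selected optimum centres on the validated optimum porosity;
  across master seeds the selection then lands at 36–40% porosity, the
  dispersion reflecting that a minimal-CV selection over 200 noisy designs
  is an extreme-value statistic. A 1000-structure sweep at larger domains —
  the reference scale — is one configuration change away but exceeds the
  desk-scale budget.

What a green acceptance run does *not* establish: that the simulator's
absolute pore-size distribution matches the real matrix (the measured pore
areas extend to 494 µm², beyond a 25.6 µm desk-scale field), or that the
paper's process-condition mapping (stirring, filtration, temperature, time)
corresponds to any particular simulator parameters — that mapping is
experimental and out of scope.

## Trees

The sweep results are organized with in-package CART: greedy binary
recursive partitioning minimizing within-leaf SSE (regression on any
metric) or Gini impurity (classification on the suitability label), split
thresholds at midpoints of observed values, deterministic tie-breaks
(lowest feature index, then lowest threshold), stopping at `max_depth` /
`min_leaf`. Fits are in-sample and descriptive — the trees summarize which
parameters drive porosity and suitability; no validation split is performed
because the sweep is exhaustive over its own design, and this is stated in
the reports. A brute-force best-split oracle in the test helpers checks
depth-1 fits exactly.

## Numerical choices and degenerate inputs

* Otsu on a constant image is an error (no threshold exists); binarizing an
  already binary image uses threshold 0.5 and is the identity at
  despeckle 0; `binarize()` is idempotent for a fixed configuration.
* `fiber_widths()` errors on all-solid (width undefined without void) and
  no-solid images.
* Empty structures: `bulk_porosity()` errors; `render_top_view()` returns
  an all-void image; `top_height_map()` returns zeros.
* Empty suitable sets: `select_optimum()` errors with advice to widen the
  space; `explore()`/`report()` record and state the condition instead of
  failing.
* Quantile convention for P5/P95 is R's default type 7 throughout.
* Pore-area CVs with a single pore are 0 (one observation has no spread);
  designs whose images contain no pores at all have undefined percentiles
  and are unsuitable by definition.

## Known limitations

* Fibers are straight ribbons: no in-plane curl, no wet pressing, no
  fiber–fiber bonding mechanics, no swelling.
* One grid resolution per run: a truly multi-scale MFC + NFC furnish cannot
  be fully resolved and size-faithful simultaneously at desk scale; the
  committed configurations resolve the nano mode and length-truncate the
  largest micro fibers.
* The suitability window at desk scale operates on tens of pores per image;
  P5/P95 and CV carry corresponding sampling noise, which the replicate
  averaging and pooled CV reduce but do not remove.
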