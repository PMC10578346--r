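---
title: "Fractal vessel density on en-face OCTA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal vessel density on en-face OCTA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octafd)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow. In inflammatory systemic disease, capillary dropout in
the macula is subtle, regional, and layer-specific, so a useful biomarker
must (i) quantify how completely the vasculature fills a region of retina
and (ii) do so per anatomical subregion and per vessel caliber class.
`octafd` implements such a pipeline for 6 x 6 mm macular scans of the
superficial (SRL) and deep (DRL) retinal layers of two cohort groups
(controls vs. patients, `HC`/`RA` by default), plus a synthetic cohort
generator that makes every stage testable against known ground truth.

## Density as a box-counting fractal dimension

The density metric is the box-counting fractal dimension of the binarized
vessel mask. Tiling a region with boxes of side $\varepsilon$ and counting
the boxes $N(\varepsilon)$ that contain at least one vessel pixel, a
space-filling capillary bed follows $N(\varepsilon) \propto
\varepsilon^{-D_f}$, and

$$ D_f \;=\; \frac{\log N(\varepsilon)}{\log(1/\varepsilon)} $$

is estimated as the ordinary-least-squares slope of $\log N$ against
$\log(1/\varepsilon)$. $D_f$ ranges from about 1 (a sparse, line-like
network) to 2 (a plane-filling bed); healthy perifoveal plexuses sit near
1.7-1.8. The estimator is validated on analytic fixtures: a line
($D_f = 1$), a filled square ($D_f = 2$) and a depth-5 Sierpinski carpet
($D_f = \log 8/\log 3 \approx 1.8928$):

```{r fixtures}
sizes <- 3^(1:5)
carpet <- make_fractal_fixture("sierpinski_carpet", 729, depth = 5)
fit_dimension(sizes, box_count(carpet, sizes)$counts)
```

Numerical choices, all recorded per run:

* **Box schedule.** Powers of two from 2 px to a quarter of the region's
  bounding box (`box_size_schedule()`), requiring at least three scales.
  Tiling starts at the bounding-box top-left corner; partial edge boxes
  count. No multi-offset averaging: determinism and oracle-exact testing
  were preferred over the slight variance reduction.
* **ROI restriction.** For a subregion, counting applies to
  `mask & roi` over the region's tight bounding box. An empty intersection
  is flagged (`EMPTY_MASK`) rather than fatal, so one avascular region
  cannot abort a cohort run.
* **Df is the reported density.** The published per-region "density" values
  this pipeline mirrors lie in 1.0-1.9, the range of a fractal dimension
  rather than of a perfusion percentage. A conventional pixel-fraction
  column (`pixel_fraction`) is emitted alongside but is not the metric.
* A 2x change of raster resolution moves $D_f$ by less than 0.05 on the
  analytic fixtures. On 216 px stochastic vessel masks the usable scaling
  range is narrow (2-32 px), and resampling can shift $D_f$ by up to ~0.07;
  cohort comparisons are therefore always made at a fixed resolution.

## Preprocessing

**Denoising** uses a nonlocal-means filter
(`w = exp(-||P_i - P_j||^2 / (h^2|P|))`, patch 5 px, search window 11 px,
`h = 0.05` on the [0,1] intensity scale). The filter strength is the only
preprocessing parameter with real leverage; `h = 0` disables it exactly.

**Binarization** defaults to an Otsu threshold on a 256-level histogram
(vectorized over the histogram; verified in the tests both against a
brute-force search over all splits and against an independent library
implementation). Otsu was chosen because it is parameter-free and
oracle-testable; a fixed threshold is available where acquisition settings
are constant.

**Caliber separation** splits the total mask (TMI) into microvascular (MIR)
and macrovascular (MAR) parts. The mask is thinned to a skeleton
(Guo-Hall), the local diameter at each skeleton pixel is `2 x` the
Euclidean distance to background, skeleton segments between branch points
take their median diameter, and segment labels are propagated to every
vessel pixel by multi-source BFS -- so `MIR | MAR == TMI` and
`MIR & MAR == 0` hold pixel-exactly, for every input. The default diameter
cut is **0.13 mm**: at the 6 mm / 216 px sampling (27.8 um/px, ~22 um
optical resolution) capillary-scale vessels render 2-4 px wide (diameter
estimate <= ~110 um) while perifoveal arterioles and venules render >= 6 px
(>= ~165 um). A cut at true capillary caliber (~25 um) would be sub-pixel
at this resolution and would classify every vessel as macrovascular, which
is why the cut sits between the *rendered* caliber classes; it is a
config-level choice recorded in the run-record, not an anatomical claim.

## ROI partition schemes

All schemes live in physical mm coordinates about the fovea center, with
membership decided by pixel-center location and half-open radial/angular
intervals, so each scheme is a pixel-exact disjoint cover of its support:

* **ETDRS quadrants** S/I/L/R: 90 degree sectors bounded by the two
  diagonals (boundaries at +-45 and +-135 degrees).
* **Hemispheric quadrants** SL/SR/IL/IR: sectors bounded by the horizontal
  and vertical axes -- the ETDRS split rotated by 45 degrees.
* **Central annuli** C1-C6: six equal-width rings between the foveal
  avascular zone (0.6 mm diameter) and a 2.5 mm circle; ring width
  (2.5 - 0.6)/2/6 = 0.1583 mm, i.e. a 0.95 mm total radial band. The two
  published figures for this geometry ("0.16 mm" rings, "0.95 mm" band) are
  reconciled exactly by this reading, and both are echoed in the
  run-record.
* **Global** ALL: the whole annulus, used for the TMI/MIR/MAR summary
  densities.

Quadrant schemes default to the annulus 0.3-2.9 mm: the avascular center is
excluded uniformly (not only for the annuli scheme) so that central
avascularity does not depress quadrant densities, and 2.9 mm is the largest
radius safely inside a 6 mm scan allowing ~0.1 mm fovea-centering error.
`L`/`R` are image left/right; they are deliberately **not** remapped to
nasal/temporal, because eye laterality travels in the metadata and the
mirror convention differs between instruments. Boundary pixels are assigned
by half-open counterclockwise angle intervals ([-45, 45) -> R, [45, 135)
-> S, ...), which makes tie-breaking deterministic and gives the exact
label permutation S -> L -> I -> R under a 90 degree rotation.

## Statistics layer

Per region and layer the two groups are compared with the pooled-variance
(Student) t-test -- matching the conventional "independent samples t-test"
of clinical reporting; Welch is a config switch -- and discriminability is
summarized by the ROC AUC computed by the Mann-Whitney rank construction
with tie correction and a DeLong 95% interval. Orientation is fixed:
*lower* density in the disease group maps to AUC > 0.5. No multiplicity
correction is applied by default (mirroring common practice in the
emulated setting); Bonferroni/BH are config options. The unit of analysis
defaults to the eye, with a subject-averaging option; with one eye per
subject the two coincide exactly. Eye-level analysis of two eyes per
subject ignores inter-eye correlation -- a known limitation of the emulated
design, acknowledged rather than corrected here (see the generator notes).
Demographics use the pooled t for continuous covariates and Fisher's exact
test for small 2x2 tables (any expected cell <= 5 or n < 40), Pearson
chi-square otherwise. The conjunctival analysis is a Pearson correlation
between per-eye conjunctival capillary density and the superficial global
TMI density.

## The synthetic cohort generator

No public OCTA images accompany the emulated study, so the generator is a
first-class module rather than a test fixture. Per eye it grows stochastic
branching trees (random recursive trees with angle jitter) outward from
seeds on the rim of a 0.3 mm-radius avascular zone: 18 narrow "micro" trees
(half-width 0.7-1.1 px) and 4 wide "macro" trunks (half-width 2.4-3.2 px;
2 narrower trunks for the deep layer, which has a denser mesh and fewer
large vessels). Segments are rasterized as capsules, the avascular zone is
cleared, and the rendering adds Gaussian blur (sigma 0.8 px), a 0.12
background haze and additive Gaussian speckle (sigma 0.08). Hemodynamics
are deliberately not modeled: only the statistical structure the pipeline
measures (density, caliber mix, avascular zone, regional deficits) needs
emulating.

Design parameters and their defaults:

* `n_per_group = 12` subjects with 2 eyes each -- the emulated study
  design. Eyes are generated **independently** (no within-subject random
  effect), which makes the eye-level t-test exactly calibrated in the null
  studies below; real eyes correlate within subject, so real-data power
  claims should use the subject-level option.
* `base_density = 1.78` -- the target control-group superficial TMI
  $D_f$, matching healthy perifoveal values. The generator maps the target
  to a micro-segment retention probability through a fixed design-time
  calibration curve (`keep = 1` yields $D_f \approx 1.79$ at default
  structure).
* `regional_effects`, e.g. `c(S = 0.6)` -- disease eyes retain micro
  segments whose midpoints fall in the named region with the given
  probability (here a 40% branch-density deficit in the superior ETDRS
  quadrant). The midpoint rule localizes the deficit where intended;
  segments straddling a sector boundary produce a small spillover into
  adjacent sectors (about a tenth of the in-region effect), which is
  realistic for vessels crossing an arbitrary geometric boundary.
* `conj_rho = 0.7` -- conjunctival density is a per-eye scalar drawn by a
  Gaussian copula against the eye's *realized* (noise-free) superficial
  global $D_f$; only the correlation structure is emulated because the
  conjunctival acquisition itself is out of scope.
* Clinical covariates (age, visual acuity, IOP, ESR, CRP) are drawn from
  the published per-group summaries, so demographics tables behave
  realistically (e.g. ESR strongly separates groups).

Ground truth (per-eye realized global and ETDRS-sector densities of the
clean mask) is written beside the images, enabling parameter-recovery
tests at every stage. What the generator does **not** emulate: projection
and motion artifacts, signal-strength variation, layer-segmentation error,
inter-eye correlation, and instrument-specific speckle physics. Passing
the validation studies therefore demonstrates correctness of the
measurement chain, not robustness to every real-world artifact.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` rerun the whole chain
(synthesis, denoising, binarization, caliber split, per-region box
counting, statistics) as simulation studies. Replicate counts are the
package's chosen desk-scale sizes for a single-CPU run; all are seeded and
deterministic:

* box-counting equals a brute-force double-loop oracle exactly on 100
  random 64 x 64 masks at every box size 1-16;
* type-I calibration: 25 null cohorts (test suite) / 35 (acceptance
  script), 12 subjects x 2 eyes per group, superficial layer; the fraction
  of regions flagged at alpha = 0.05 must lie in [0.03, 0.08] and the mean
  null AUC within 0.5 +- 0.03;
* power: 20 cohorts with a 40% superior-quadrant deficit; the S comparison
  must be significant in >= 90% of cohorts while the opposite-sector (R)
  rejection rate stays <= 10%;
* correlation recovery: 100 unrendered 24-eye cohorts; the mean sample
  correlation between conjunctival density and realized superficial TMI
  density must fall within 0.7 +- 0.15;
* perfectly separated group densities must give AUC = 1.0 with a DeLong
  interval collapsing to [1, 1].

## Known limitations

* The caliber cut operates on rendered vessel width at scan resolution and
  below ~2 px it cannot distinguish capillary calibers.
* $D_f$ values depend on the box schedule and region size; densities are
  comparable only within a fixed geometry and resolution, which the
  pipeline enforces per run.
* The binarization threshold is global per image; strong shading would
  need a local method, out of scope here.
* Eye-level statistics treat eyes as independent; use
  `stats$unit = "subject"` when analyzing real two-eyed cohorts.
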