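---
title: "Stain-free sperm inspection by off-axis quantitative phase microscopy: models and methods"
author: "holosperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-free sperm inspection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosperm)
```

## The measurement problem

Staining is not allowed in human assisted reproduction, and an unstained
sperm cell is nearly transparent under bright-field microscopy. Quantitative
phase microscopy records, in a single off-axis interferogram, the per-pixel
*optical path delay* (OPD) of the cell,

$$\mathrm{OPD}(x,y) \;=\; \frac{\lambda}{2\pi}\,\varphi(x,y),$$

the product of the refractive-index difference and the local thickness.
Trapping each cell in a surfactant-stabilized microdroplet keeps it in the
field of view during and after its assessment; once covered with mineral
oil, the self-assembled hexagonal droplet rug flattens, so droplet curvature
contributes no visible background to the OPD map. On such maps the head,
acrosomal cap, midpiece, vacuoles and residual cytoplasm are quantifiable,
and a cell can be screened for fertilization suitability:

* the acrosome should comprise 40--70% of the head area,
* the head width-to-length (radii) ratio should be near the 3:5 norm,
* the midpiece should be approximately as long as the head and continue its
  axis,
* no large vacuole, at most two small ones, together at most 20% of the
  head,
* residual cytoplasm is an anomaly only when it exceeds one third of the
  head area.

No public raw acquisitions accompany this kind of experiment, so the package
is organized around a first-class synthetic-data module: every downstream
stage is validated against scenes whose ground truth is known analytically.

## Synthetic scenes

`phantom_spec()` describes one cell: an elliptical head (default 5 µm × 3
µm, matching the 3:5 norm) whose anterior cap -- the acrosome -- covers a
controllable area fraction at a reduced OPD (`acrosome_opd_scale`, default
0.6, giving the visibly bimodal head that real OPD maps show); a midpiece
capsule (default as long as the head, 1 µm wide, at 0.4 of the head OPD); a
thin 2-px tail at 8% of the head OPD (real tails are barely visible in OPD
and are excluded from all morphometrics); optional vacuole depressions and a
residual-cytoplasm disc tangent to the neck. The head OPD peak defaults to
300 nm: a plausible value for a flattened head which also keeps the phase
below the π wrapping limit of the 633 nm HeNe line, so that phase unwrapping
is exercised by dedicated tests rather than by every scene.

Two rendering choices matter for everything downstream:

* **Edges are analytic cubic smoothsteps one pixel wide, and structures are
  composited by coverage blending.** The raster is therefore a C¹ function
  of the cell position: moving a cell by a fraction of a pixel translates
  the sampled scene faithfully instead of re-aliasing it. This is what makes
  sub-100-nm inter-frame displacements (50 ms at 0.05--0.25 µm/s) resolvable
  by centroid tracking. The smoothstep is antisymmetric about the nominal
  boundary, so half-level contours and areas remain unbiased.
* **The finished scene is low-pass filtered with a Gaussian of
  `edge_sigma_um` (default 0.2 µm, ~1.25 px).** This anti-aliases the
  rasterization and keeps the scene spectrum well inside the demodulation
  passband; it is far below the diffraction-limited spot (~1.2 µm for a
  0.66 NA objective at 633 nm), so it does not smooth away anything a real
  system could resolve.

The default droplet-rug residual amplitude is 0 nm, reflecting the
oil-flattened rug; `generate_droplet_rug()` renders hexagonally tiled bumps
of any chosen amplitude for noise-contrast studies.

What the generator does **not** emulate: 3-D refractive-index structure
(scenes are pure projected-OPD), flagellar beating (tails are static),
shot-noise scaling (detector noise is additive Gaussian on intensity, which
matches std-based noise metrology), cell-to-cell texture, debris, and
overlapping cells. Passing tests therefore demonstrate the correctness of
the computations under the stated forward model, not segmentation robustness
on clinical imagery.

## Interferogram rendering and reconstruction

`render_interferogram()` implements the single-exposure off-axis model

$$I = A\left[1 + C\cos\!\big(2\pi(f_x x + f_y y) + \varphi\big)\right] + n,$$

with carrier default (0.25, 0.25) cycles/px -- maximal separation of the
cross-correlation term from DC below Nyquist. Reconstruction follows the
standard chain: FFT, selection of one cross-correlation term, inverse FFT,
2-D phase unwrapping of the argument, conversion to OPD, and polynomial
background flattening.

Numerical choices:

* **Demodulation** multiplies by the conjugate carrier exponential before a
  circular low-pass crop at DC; this re-centers sub-pixel carriers exactly.
* **Crop radius** defaults to 0.7× the carrier magnitude rather than the
  more conservative half. The optical band limit NA/λ (0.167 cycles/px at
  0.16 µm/px) already exceeds half the default carrier magnitude (0.177),
  so a half-magnitude crop would sit at the edge of the signal band; at 0.7×
  the noiseless phantom round trip is sub-nanometer (measured RMSE ~0.3 nm
  over a 512² field excluding a 16-px border) while the crop still clears
  both DC and the conjugate order.
* **Unwrapping** defaults to a reliability-sorting unwrapper
  (second-difference quality; edges merged in decreasing reliability with a
  union-find over pixel groups, implemented in C++), robust on low-residue
  fields; a row/column Itoh method is retained as a debugging fallback.
* **Sign**: only one of the two conjugate orders is cropped, so the phase
  sign depends on which one the carrier search picked; `reconstruct()`
  assumes non-negative-OPD objects and flips the map when its dominant
  features are negative.
* **Flattening** fits a 2-D polynomial (default order 2) to robustly
  selected background pixels and zeroes the background median; OPD is only
  defined up to a reference.

## Morphometric estimators

Segmentation thresholds connected components at the background median plus
five background robust standard deviations (15 nm floor for noiseless
maps). Within a component:

* the **head** is first the compact region above half the component's peak
  OPD, then refined with class-adaptive half-level thresholds: the anterior
  (acrosomal) boundary is cut at half the acrosome plateau and the posterior
  boundary at half the post-acrosomal plateau, which makes both boundaries
  unbiased under the symmetric edge blur;
* the **acrosome cut** comes from a two-level step fit of OPD against the
  head-axis coordinate (per-1-px bins, upper-quantile summaries against
  boundary-taper pixels, bin abscissae taken as the actual mean coordinate
  of each bin's pixels). The fraction of profile variance the step explains
  gates the fit: an enclosed depression (a large vacuole) shows a poor step
  fit and is not mistaken for an acrosome. For near-circular heads, whose
  mask axis is degenerate, the anterior direction is taken from the class
  geometry (head centroid → low-class centroid) instead;
* a **neck correction** re-thresholds the head/midpiece junction at the
  midpoint of the head and midpiece levels: there the head boundary
  half-level sits over the midpiece plateau rather than over background, and
  without the correction the mask bulges ~1 px into the midpiece and biases
  every area ratio;
* **vacuoles** are deficits below the local class plateau inside an eroded
  head interior, measured at half their maximum depth (insensitive to the
  detection threshold); a ±3 px band around the acrosome boundary is
  excluded because the class transition itself would register there;
* **midpiece length** is measured from the neck to the farthest projection
  of the half-level midpiece mask along its principal axis, minus half the
  midpiece width (compensating the rounded distal cap);
* **residual cytoplasm** is the half-level blob area beside the neck,
  outside the midpiece angular sector.

**Validity domain.** The estimators assume the head is resolved: at the
default 0.16 µm/px, heads with radii ratio below ~0.36 are under 12 px
across and acrosome-cap recovery degrades (errors up to ~6 percentage points
versus ≤~2.5 inside the domain). Vacuoles straddling the acrosome boundary,
or within ~0.7 µm of the head margin, are not reliably countable. The
validation sweep (`phantom_parameter_sweep()`) samples inside this domain,
and keeps every generative parameter at least one measurement tolerance away
from each selection boundary -- within a tolerance of a boundary the
measured and generative classifications could legitimately disagree, so
recovery there cannot be scored.

## Selection criteria

`selection_criteria()` encodes the screening windows as closed intervals;
residual cytoplasm fails only strictly above one third (a blob of exactly
one third is not an anomaly). Two defaults are package judgments:

* the **radii window** [0.48, 0.72] brackets the 3:5 norm widely enough
  that the built-in reference cells (ratios 0.48--0.7) fail only on the
  acrosome criterion, reproducing the reference selection pattern of cells
  a, b, c. Note the asymmetry this implies: a cell at ratio 0.70 passes this
  window even though it is well off 3:5;
* the **midpiece window** [0.8, 1.4] operationalizes "approximately the
  length of the head" and admits all reference values (1.11--1.32).

An indeterminate measurement (for example an acrosome ratio without class
contrast) blocks selection with a distinct status -- conservative for a
fertilization context -- while the axis-continuation criterion is evaluated
only when axis data exist, since reference tables carry no such column.

## Tracking and motility

`detect_centroids()` weights head-core pixels by a soft-saturating excess
OPD $s^2/(1+(s/c)^2)$ with $s = (\mathrm{OPD} - 0.45\,\hat P)_+$: zero with
zero slope at the core boundary and nearly flat on both head plateaus, so
the centroid is smooth under sub-pixel motion while staying within ~0.4 µm
of the head center. A 1.2-px Gaussian pre-smoothing of the frame further
stabilizes the interpolation. Linking is greedy nearest-neighbor with a 5
µm/frame default gate -- ample for sub-µm/s swimmers.

`track_velocity()` defaults to the mean of per-step speeds over the tracking
window (10 frames at 50 ms), matching the way such videos are evaluated; the
net-displacement-over-total-time statistic is available via `method =
"net"`. The motile threshold defaults to 0.02 µm/s: below the slowest
reported swimming velocity (0.05 µm/s) and above the centroid jitter of
immotile cells.

## Noise metrology

The spatial noise level of a map is the standard deviation across its
pixels; the temporal noise level is the standard deviation per
diffraction-limited spot across a recorded stack, where a spot is
$1.22\lambda/\mathrm{NA}$ rounded up to whole pixels (8 px at the default
calibration). "Per spot" is implemented as non-overlapping block averaging
before the per-tile std over frames; for iid per-pixel noise of std σ the
per-spot std is σ/spot. Per-frame spatial stds are averaged over the stack
to one "average spatial std" (the aggregation is a package choice).
Histograms use Freedman--Diaconis binning with recorded edges, falling back
to Sturges when the IQR degenerates.

The reference fold-changes between droplet and empty-plate noise levels
(spatial 12.428/2.51 nm, temporal 2.64/0.72 nm) are retained as worked
examples; note the reported temporal ratio 3.66 differs from the quotient
of the reported averages (3.667) by a rounding residue, documented in the
tests.
Reproducing the absolute noise numbers would require the original recorded
stacks, which are not deposited.

## Validation problem sizes

The shipped validation uses: 20 noiseless 512² phantoms for the
reconstruction round trip (RMSE < 1 nm, 16-px border excluded); a 50-phantom
sweep at 256² for parameter recovery (acrosome ±3 percentage points, radii
ratio ±0.05, midpiece ratio ±0.15, vacuole counts exact, classification
agreement 100%); 250 synthetic 96² frames of iid Gaussian OPD noise (σ = 2.5
nm) for noise-estimator calibration within 5%; and rendered 10-frame
sequences at 0.05--0.25 µm/s for velocity recovery within 10% plus a
1000-cell track population with a known motile proportion of 0.2. These
sizes are the package's validation design and run in well under a minute
each.

```{r quick-example}
spec <- phantom_spec(image_shape = c(256, 256), acrosome_fraction = 0.5)
scene <- generate_sperm_phantom(spec)
opd <- reconstruct(render_interferogram(scene$opd, carrier_spec()))
measure_cells(opd)[, c("acrosome_head_ratio_pct", "radii_ratio",
                       "midpiece_head_ratio", "vacuole_count")]
```

## Known limitations

* The acrosome partition needs OPD contrast; uniform heads are reported
  indeterminate (and unselected) rather than guessed.
* A vacuole centered on the acrosome boundary falls in the exclusion band
  and is missed; a vacuole larger than roughly half the head interior is no
  longer a "depression in a plateau" and the plateau reference becomes
  unreliable.
* Greedy linking is not a global assignment; it is adequate while per-frame
  displacements are far below cell spacing, which holds at the speeds
  studied here.
* The pipeline is validated on its own forward model; real acquisitions add
  aberrations, partial coherence artifacts and biological variability that
  the generator does not emulate.
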