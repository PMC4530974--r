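---
title: "Segmentation model, parameters and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation model, parameters and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`octrima3d`: the boundary-detection model and its assumptions, the
parameters that matter, what the synthetic phantoms do and do not emulate,
and the numerical choices made where the method leaves room.

## The boundary model

A retinal layer boundary in a B-scan is modelled as a left-to-right path
through a graph with one vertex per pixel of a gradient image, arcs between
8-neighbours, and arc weights

$$ w(a,b) = 2 - (g_a + g_b) + w_{\min}, $$

where $g \in [0,1]$ is the normalized directional gradient and
$w_{\min} > 0$ keeps all weights positive so Dijkstra's algorithm applies.
Two *virtual columns* with $g = 1$ are appended on either side; vertical
moves inside them cost only $w_{\min}$, so the path may enter and leave the
real image at any row — no endpoint initialization is needed. The gradient
is the convolution of the frame with an 11 × 5 kernel whose every lateral
column is $(1,1,1,1,1,0,-1,-1,-1,-1,-1)^T$ — a matched filter for a
horizontal step edge under speckle, used in a dark-to-bright and a negated
bright-to-dark orientation. Negative responses are clamped and the frame is
min–max normalized; where biasing or masking reduce contrast, each column
of the region of interest is additionally min–max normalized on its own.

The model's central assumption is that after *flattening* — integer
per-column vertical shifts that render a reference boundary horizontal —
the target boundary changes by at most about one row per column, so the
8-connected path can trace it. Flattening against the previous frame's
boundary (inter-frame) rests on a second assumption: adjacent B-scans at
120–140 µm spacing differ by less than 10 px axially, which also justifies
restricting each search to a ±10 px band around the previous frame's
result.

## The detection schedule

Per frame, in order: IS-OS (the most prominent dark-to-bright edge; first
frame searched over the whole image with a depth-ramp bias suppressing the
shallower ILM, later frames flattened by the previous ILM and restricted to
the band around the previous IS-OS); ILM (first frame: above the flattened
IS-OS; later frames: inter-frame flattening, which removes the foveal
curvature that otherwise defeats the path); OS-RPE and RPE-CH in the 40-px
band below the flattened IS-OS (RPE-CH first on dark-to-bright, then the
band is masked below it and OS-RPE found on bright-to-dark); the inner
triplet IPL-INL / INL-OPL / OPL\_o in the rectangle between the lowest
flattened-ILM point and the flattened IS-OS (bias selects OPL\_o, masking
below it isolates IPL-INL, and INL-OPL is searched strictly between the
two). After the first pass, an enface projection

$$ E_{n,x} = \frac{1}{z_8 - z_6 + 1}\sum_{z=z_6}^{z_8} I^n_{z,x}
           - \frac{1}{30}\sum_{z=z_1}^{z_1+29} I^n_{z,x} $$

flags vessel-shadowed A-scans, and a second per-frame pass detects RNFL\_o
between the flattened ILM and the highest IPL-INL point with the gradient
of flagged columns set to 1, so the path bridges shadow gaps at minimal
cost. Vessel shadowing *lowers* $E$ (the outer-band term is attenuated, the
sub-ILM term brightened), so columns are flagged where $E < -0.1$; the
negative threshold fixes the sign convention unambiguously.

Before segmentation, the fovea is localized as the (frame, column) with the
smallest ILM-to-RPE-CH distance over frames 21–40 (all frames for shorter
volumes), and the volume is cropped to 6 mm × 6 mm around it.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `w_min` | 1e-5 | – | arc-weight stabilizer; must be ≪ gradient contrasts and > 0 |
| `interframe_margin` | 10 | px | half-height of the inter-frame search band |
| `rpe_band_height` | 40 | px | band below the flattened IS-OS for the RPE pair |
| `downsample_factor` | 2 | – | lateral down-sampling of the graph |
| `smooth_window` | 5 | columns | moving average applied to interpolated boundaries |
| `enface_threshold` | −0.1 | intensity | vessel-shadow flag level |
| `crop_extent_mm` | 6 | mm | macular crop side length |
| `fovea_frame_range` | 21–40 | frames | fovea search window |
| `edge_exclusion_px` | 5 | px | see below |

`edge_exclusion_px` is a choice this implementation makes explicit: when a
search band is bounded by an already-detected boundary whose kernel
response has the same orientation as the target (the RPE-CH band starts at
the IS-OS edge; the bootstrap ILM region ends at it; the RNFL\_o region
ends at the IPL-INL; the IPL-INL search sits above the masked OPL\_o), the
bounding edge's response shoulder — half the 11-row kernel, 5 px — would
otherwise be the strongest ridge in the band and capture the path on *any*
input. Those 5 + 1 rows are therefore excluded or masked. For the same
reason the masking step that removes an already-detected boundary from a
region widens the zeroed zone by 6 rows toward the boundary.

Two further refinements of the same kind: (1) the inter-frame search band
for the IS-OS is applied per column rather than as one rectangle — after
flattening by the previous ILM, the IS-OS carries an inverted copy of the
foveal pit, and the rectangular hull of its ±10 px bands would admit the
RPE-CH, which runs nearly flat across that anti-pit; (2) the bias map used
to select the OPL\_o multiplies adjacent rows by a ratio of about
$1 + 1/z$, enough to displace the path by one row where the boundary steps,
so the biased search only *selects* a corridor and the final OPL\_o path is
re-searched on the unbiased gradient within ±5 rows of it.

## Numerical choices

* **Indexing** is 1-based throughout (R convention), with depth $z$
  increasing toward the choroid. The bias map is $(z-1)/(M-1)$ for a region
  of $M$ rows: 0 at the top row, 1 at the bottom.
* **Convolution borders** use edge replication, so a frame keeps its size
  and the image top/bottom produce no spurious edges (zero padding would).
  The separable implementation (axial difference of running sums, lateral
  running sum) is exact and is tested against a naive double-loop
  convolution; responses below 1e-9 are treated as zero to keep
  running-sum round-off from polluting constant regions.
* **Tie-breaking.** Among equal-gradient paths, an infinitesimal penalty of
  $w_{\min}/1000$ per row of vertical travel prefers the geometrically
  straightest path — without it, a uniform region (a vessel gap with its
  gradient set to 1, or an empty corner of a region) admits arbitrary
  equal-weight zigzags and the reported path shape is an accident of heap
  order. Remaining ties settle toward the smaller row index. Both rules are
  implemented identically in the Dijkstra engine and in the exhaustive
  test oracle, and both make the output fully deterministic.
* **Flattening** aligns the reference to its rounded maximum, so all shifts
  are downward-or-zero and the retina is never pushed off the top; vacated
  pixels are filled by edge replication. Shifts are integers, making
  boundary flatten/unflatten round-trips exact.
* **Down-sampling** keeps columns $1, 1+f, 1+2f, \dots$; detected rows are
  linearly interpolated back (nearest value beyond the last sample) and
  smoothed with a centered moving average, truncated at the edges, in the
  flattened region coordinates (smoothing after un-flattening would smear
  the flattening staircase itself into the boundary).
* **Degenerate inputs.** A constant frame yields an all-zero gradient; a
  constant column under per-column normalization maps to 0 (a featureless
  column must not attract the path); a single-frame volume runs entirely in
  intra-frame modes; ordering violations between detected boundaries abort
  with the frame and boundary named — they are never silently clamped,
  because a clamp would hide exactly the failures the test-bench exists to
  surface.
* **Error metrics.** SSE is the population (n-denominator) standard
  deviation; E95 is the order statistic at $\lceil 0.95\,n\rceil$ — the
  largest unsigned error after discarding the top 5% — rather than an
  interpolated quantile.

## The synthetic phantoms

`generate_phantom()` renders nine constant-reflectivity bands between eight
integer-valued surfaces, with a one-pixel blended transition row at each
boundary (the discrete step edge the kernel is matched to), multiplies by
unit-mean gamma speckle, and plants vessel shadows (a brightened 10-px band
just below the ILM, everything beneath attenuated). Band reflectivities are
chosen so that each boundary has the transition direction the detection
schedule expects — dark-to-bright at the ILM, INL-OPL, IS-OS and RPE-CH,
bright-to-dark at the RNFL\_o, IPL-INL, OPL\_o and OS-RPE — with the IS-OS
the most prominent edge, as in healthy retina.

Surface geometry is the sum of separately rounded terms: a shared lateral
sinusoid (retinal curvature), a shared frame-wise axial shift (bulk eye
motion between B-scans), and a Gaussian foveal depression of the five inner
boundaries. The separate rounding is deliberate ("rounding-coherent"): the
segmenter flattens frames by integer shifts derived from one surface, and
if two surfaces carried independently rounded copies of a shared smooth
term, their difference would acquire one-column ±1 blips that no
8-connected path can trace — an artifact of the discretization, not of the
anatomy.

The pit comes in two regimes. The *exact-recovery* regime
(`fovea_clean`: pit constant across frames, wall slope < 1 px/column,
integer taper offsets between the inner surfaces) keeps every flattened
target boundary an isolated-step staircase, so the pipeline at
`downsample_factor = 1, smooth_window = 1` recovers every boundary with an
unsigned error of exactly zero — the identity test of the whole chain. The
*realistic* regime (`fovea_speckle`, `vessels_speckle`, `full_volume`: pit
fading across frames with σ = 2.2 frames, walls steeper than 1 px/column)
reproduces the regime where intra-frame flattening demonstrably fails at
the pit while inter-frame flattening keeps the residual within the path's
reach; here pixel rounding leaves ±1 px residuals at step columns and
recovery is tested against a ~1 px mean-error budget instead. The pit is
narrower than a typical human pit so that its wall slope exceeds
1 px/column at this axial/lateral anisotropy; depth (30 px ≈ 120 µm) is
anatomically plausible.

Speckle is modelled as multiplicative gamma noise with shape 20
(σ/μ ≈ 22%), the residual contrast expected after the 5-frame eye-tracked
averaging of the emulated acquisition; fully developed single-shot speckle
would be about √5 stronger. Vessel shadows are laterally sharp; because the
5-column kernel then contaminates the gradient of the two columns
neighbouring a shadow edge, the pipeline dilates the detected vessel mask
by 2 columns for the RNFL\_o pass.

What the phantoms do **not** emulate: inner-layer pinch-out at the fovea
(layers thin but never vanish, so detection near the pit is easier than in
real anatomy), pathology (edema, drusen), curved vessel tracks in the
enface plane, depth-dependent signal roll-off, and motion artifacts other
than rigid axial shifts. A passing test-bench therefore demonstrates the
mechanics of the pipeline — graph search, flattening, region logic, vessel
bridging, metrics — under controlled OCT-like statistics, not clinical
accuracy.

## Problem sizes

The test suite runs the full pipeline on 10-frame, 496 × 644 px phantoms
(five seeds for the speckle conditions) and one 51-frame full-geometry
volume; the exhaustive path-search oracle is exercised on 200 random grids
up to 6 × 6. The complete suite finishes in under two minutes on one CPU
core; a full 51-frame volume segments in roughly 20 s plus 3 s of phantom
generation.

## Known limitations

JPEG/PNG intensities are treated as linear (the export's transfer function
is not modelled). The fovea localizer uses single-frame detectors, whose
intra-frame flattening underestimates steep pits; on the steep synthetic
pit this can shift the selected frame by about two frames — immaterial for
the 6 mm crop, but a caveat for reusing it as a pit-depth measure. Vessel
columns are bridged, not measured: boundaries inside shadows are
interpolations by construction. Volumes with pathology-scale deformation
of the outer bands (e.g. drusen) violate the flat-IS-OS assumption of the
RPE band and are out of scope.
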