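# octrima3d

Automatic segmentation of the eight intraretinal layer boundaries in macular
spectral-domain OCT volume data, built for near-real-time use: a whole
496 × 644 × 51 voxel volume segments in well under a minute on one CPU core.

The package is aimed at retinal image analysis — extracting layer thickness
maps (RNFL, plexiform and nuclear layers, photoreceptor bands) from
volumetric B-scan stacks exported as image files — and ships with everything
needed to exercise and validate the pipeline without clinical data: a
synthetic layered-phantom generator with exactly known geometry, speckle
noise and vessel shadows, plus the standard segmentation error metrics.

## Method

Each boundary is detected in a 2-D B-scan as the minimum-weight path through
an 8-connected pixel graph built on a directional gradient image
(Dijkstra's algorithm). For neighbouring pixels *a*, *b* with normalized
gradient values *g<sub>a</sub>*, *g<sub>b</sub>* the arc weight is

    w(a, b) = 2 − (g_a + g_b) + w_min,      w_min > 0 small,

so bright gradient ridges attract the path; two virtual columns of gradient
1 appended at the ends make the endpoints free. Gradients come from an
11 × 5 matched filter for horizontal step edges, in a dark-to-bright and a
bright-to-dark orientation; speckle is handled by the filter's averaging,
with no diffusion-style denoising.

What makes the full eight-boundary schedule fast and robust is the
exploitation of spatial coherence:

* **flattening** — A-scans are shifted so a reference boundary becomes
  horizontal; the reference is the previous frame's boundary
  (*inter-frame*) where curvature (e.g. the foveal pit) would otherwise
  defeat the path search, or a boundary of the same frame (*intra-frame*);
* **search-region refinement** — each boundary is searched only inside an
  axial band derived from the previous frame (± 10 px) or from already
  detected boundaries of the same frame;
* **biasing and masking** — closely spaced boundaries of the same edge
  orientation in one region are separated by a depth-ramp bias map
  (selects the lowest) and by zeroing the gradient on the wrong side of
  already-found boundaries;
* **vessel handling** — A-scans shadowed by retinal vessels are found by
  thresholding an enface projection (mean intensity between IS-OS and
  RPE-CH minus the mean of the 30 px below the ILM) at −0.1, and their
  gradient is set to 1 so the path bridges the disrupted outer RNFL edge
  at minimal cost;
* **lateral down-sampling** — the graph is built on every 2nd column and
  the result interpolated and smoothed, halving the node count.

Accuracy against ground truth is reported as mean signed error (MSE ± SSE),
mean unsigned error (MUE) and the 95th-percentile unsigned error (E95), in
pixels or microns.

## Worked example

Generate a noisy foveal phantom, segment it, and score the result against
the known truth:

```r
library(octrima3d)

ph  <- generate_phantom(phantom_fixture("fovea_speckle"), seed = 42)
seg <- segment_volume(ph$volume)
print(seg)
#> OCT segmentation of phantom:fovea_speckle:seed42
#>   input: 10 frames x 496 x 644 px; segmented grid: 644 columns x 10 frames
#>   fovea: frame 3, column 323 (ILM to RPE-CH 118.6 px)
#>   vessel-shadowed A-scans: 11 of 6440
#>   elapsed: 4.93 s (fovea 1.94, first_pass 2.51, enface 0.07, rnflo 0.41)

compare_surfaces(seg$surfaces, ph$truth)
#> Surface agreement (pixels):
#>  boundary    mse   sse   mue e95    n
#>       ILM  0.002 0.260 0.078 0.7 6440
#>    RNFL_o -0.070 0.665 0.480 1.4 6440
#>   IPL-INL -0.031 0.354 0.170 0.9 6440
#>   INL-OPL  0.021 0.370 0.190 0.9 6440
#>     OPL_o -0.014 0.277 0.093 0.7 6440
#>     IS-OS  0.058 0.907 0.152 1.0 6440
#>    OS-RPE  0.020 0.544 0.123 0.7 6440
#>    RPE-CH  0.014 0.418 0.238 1.0 6440
#> Overall: MSE 0.000 +/- 0.519, MUE 0.191, E95 1.000 px (n = 51520)
#>          MUE 0.74 um at 3.90 um axial resolution
```

The fovea is localized to within one frame and one column of the planted
pit; every boundary is recovered with a mean unsigned error well below one
pixel (sub-4 µm at this axial sampling), with the low-contrast outer RNFL
boundary the hardest, as expected. `plot(seg, ph$volume, frame = 5)`
overlays the eight boundaries on a B-scan; `coef(seg)` and
`as.data.frame(seg)` expose the surfaces.

Real volumes load from an exported image stack the same way:

```r
vol <- load_volume("path/to/export/")   # PNG/JPEG/TIFF + JSON or XML sidecar
seg <- segment_volume(vol)
write_surfaces(seg$surfaces, "surfaces.csv")
```

A command-line interface wraps the same functions
(`exec/octrima3d segment|evaluate|synth`); `synth` writes a phantom as an
image-stack directory with its ground truth, directly consumable by
`segment` and `evaluate`.

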