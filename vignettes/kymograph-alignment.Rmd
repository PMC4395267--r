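---
title: "Weighted-path kymograph alignment: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-path kymograph alignment: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoalign)
```

## The problem

A kymograph from a nanochannel optical DNA mapping experiment is an `m x n`
image: each row is one fluorescence snapshot of a stretched DNA molecule,
each column a position along the channel. Because the confined molecule is
extended to only about half its contour length, it keeps moving — its centre
of mass diffuses and local segments stretch and compress — so the bright and
dark bands of its sequence-dependent intensity profile (its *barcode*)
wander horizontally from frame to frame. A naive column-wise time average
then blurs neighbouring bands together. Kymograph alignment warps each frame
horizontally so the bands run straight, mimicking a molecule held at fixed
extension, after which the time average is a low-noise 1D barcode.

`kymoalign` implements a recursive weighted-path alignment:

1. **Detect** the most pronounced bright ridge or dark valley as a complete,
   continuity-constrained trajectory `F(y)` (one column per row,
   `|F(y+1) - F(y)| <= k`), found as a minimum-cost path through a cost
   landscape derived from a Laplacian-of-Gaussian (LoG) filter response.
2. **Straighten** it: each row is resampled with a piecewise-linear
   coordinate map that pins `F(y)` at its rounded time-mean position `c*`
   (its thermodynamic-equilibrium position) while the row ends stay fixed;
   intensities at fractional positions come from a natural cubic spline fit
   to the row.
3. **Recurse** on the sub-images left and right of the aligned feature,
   excluding `w` columns on each side of the split from further search,
   until regions are narrower than a typical feature (`2w`) or contain no
   distinct feature.

Because each split permanently consumes `2w + 1` columns of search width,
termination is guaranteed, and because the path search is a row-by-row
dynamic program over an implicit layered DAG, the total work grows close to
linearly with kymograph width.

## Cost landscape and path search

The image is first smoothed with an anisotropic Gaussian (`sigma_h = 10` px
along the channel, `sigma_v = 3` px along time) and an isotropic LoG
(`sigma_log = 10` px) is applied to the smoothed image, in that order. The
response `K` is positive in dark bands and negative in bright bands; positive
values are rescaled by the largest positive response and negative values by
the magnitude of the most negative one, so `K` spans `[-1, 1]`. Two cost
images are derived so that a single feature cannot be half ridge and half
valley: `K_B = 1 + K` where `K < 0` (else 1) for bright features and
`K_D = 1 - K` where `K > 0` (else 1) for dark ones. In both, the strongest
feature locations approach cost 0 and everything else sits at the barrier
value 1. This affine barrier mapping is the package's own concrete choice
among mappings with those properties and can be replaced via the `strategy`
argument of `cost_images()`.

The implicit graph has one node per pixel plus a source and a sink; each
pixel connects to the `2k + 1` admissible pixels in the next row and every
edge costs the pixel it points to (`source_edge_scheme = "unit"` makes the
first row cost-neutral instead; the sink edges' constant weight cannot
change the argmin). Pixels at the barrier value are excluded from the graph
entirely: barriers are obstacles a feature cannot cross, not merely
expensive pixels. This matters because the cost of hopping across a barrier
of width `d` is spent once (`~d/k` rows) while the benefit of a slightly
cheaper valley accrues on every row, so with long time axes a purely
cost-based search would happily splice two different physical bands into one
"feature" and shear both when straightening. A region in which barriers
block every complete path — a flat stretch, or the large dark gaps of
low-labelling-density experiments — yields a rejection, and the recursion
stops there.

The winning polarity is the cheaper of the bright and dark paths (exact ties
go to dark), accepted only if its cost per row is below `theta = 0.9`. DP
tie-breaks prefer the straightest step (smallest horizontal displacement,
then the smaller column): this keeps paths vertical across exact-cost
plateaus, where a lexicographic tie-break would let them drift sideways at
`k` pixels per row.

During recursion, two refinements apply relative to a standalone
`detect_best_feature()` call. Sub-region responses are rescaled by the
*global* normalisation constants of the full kymograph's LoG rather than by
the region's own extremes — otherwise a featureless region would have its
numerical noise amplified to full contrast and `theta` could never reject
it. And sub-region convolutions are padded with the surrounding image
content instead of reflection (reflection remains at the true image edges),
since reflecting at an interior cut manufactures artificial curvature
extrema exactly where the image was split.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sigma_h` | 10 | px | channel-axis smoothing; suppresses intensity noise |
| `sigma_v` | 3 | px (frames) | time-axis smoothing |
| `sigma_log` | 10 | px | LoG scale; matched to band width |
| `k` | 2 | px/frame | continuity constraint on feature motion |
| `w` | 5 | px | feature half-width; split guard band and width floor `2w` |
| `theta` | 0.9 | — | acceptance threshold on path cost per row |
| `chi` | 1 | — | information-score regulariser |

`k` should scale with molecule length: longer molecules diffuse less per
frame. `choose_k()` implements `max(1, round(k_ref * L_ref / L))` with
`k_ref = 2` at `L_ref = 24` um. The underlying diffusion argument (diffusion
length per frame `dL` with `dL^2` proportional to `D t` and `D` inversely
proportional to length) taken literally gives `dL` proportional to
`1/sqrt(L)`, which would suggest `k_ref * sqrt(L_ref / L)`; both readings
are offered (`mode = "linear"` and `"sqrt"`), the linear rule being the
default. The discrepancy is documented here rather than resolved.

## Quality metrics

`time_trace()` computes the column-wise time average (the barcode), the
column-wise variance with the population (`1/m`) convention, and its mean
over columns — the package's scalar noise measure. `barcode_information()`
scores a barcode by summing, over the robust intensity contrasts `|dI_k|`
between neighbouring peaks and valleys of the trace, the self-information of
a Gaussian model in `log|dI|` with variance `log(sigma2 + chi)`:

    IS = sum_k [ 0.5*log(2*pi*log(sigma2 + chi))
                 + log(|dI_k|)^2 / (2*log(sigma2 + chi)) ]

with natural logarithms and `sigma2` the aligned kymograph's mean column
variance. The score grows with peak/valley contrast (for `|dI| >= 1`) and
falls with noise. Two readings of the squared-log term are possible;
`(log|dI|)^2` is used because it makes the summand an exact Gaussian
negative log-density in `log|dI|`, consistent with the self-information
framing. Below `|dI| = 1` the score is non-monotone in the contrast, so it
is meaningful for intensity units in which real band contrasts exceed 1 —
the monotonicity property tests are restricted accordingly. A noiseless
trace with `chi = 1` has zero log-variance; the score is then reported as
`Inf`. The "robust extrema" extraction is a documented stand-in: the trace
is smoothed (Gaussian, 2 px), all interior direction changes plus the
endpoints form an alternating extremum sequence, and adjacent pairs with
contrast below `0.5 * sqrt(sigma2 + chi)` (the noise scale) are pruned,
smallest first. Both parameters are exposed and logged in reports.

## The simulator and what it does (not) capture

`generate_barcode()` builds a ground-truth profile: baseline 100 (camera
units) plus Gaussian bands of FWHM 10 px (the typical feature width), with
centres at least two feature widths apart and at least two feature widths
from the frame edges, and amplitudes uniform in 50–100. The edge margin
exists because a band drifting out of the field of view is an anomalous
event (like molecule breakage) that alignment deliberately does not model;
the simulated crop, like an experimental one, follows the molecule.

`generate_kymograph()` warps this profile per frame with (a) a centre-of-mass
random walk with 0.5 px/frame steps, centred on its time mean (the crop
tracks the molecule's mean position), and (b) a smooth zero-mean local
displacement field of magnitude 1 px and correlation length 40 px, clamped
to keep every warp strictly increasing; i.i.d. Gaussian camera noise of
5 units is then added. The 0.5 px/frame step is the right order of magnitude
for centre-of-mass diffusion of a ~24 um molecule imaged at 10 Hz with
0.16 um pixels; 5-unit noise on a 100-unit baseline is a typical
fluorescence SNR. Default frames and width, 200 x 170, mirror the standard
experiment. All generators are pure functions of their seeds.

The simulator is a test harness, not polymer physics: it has no Rouse/Zimm
dynamics, no photobleaching, no shot-noise scaling with intensity, and its
bands are smooth Gaussians rather than the plateau-edged bands of real melt
maps. Passing tests therefore demonstrate correct mechanics and realistic
noise behaviour, not performance on any particular experimental dataset.

## Numerical choices

* `c*` and `choose_k` round half away from zero, so results do not depend
  on the platform's rounding of `.5`.
* Spline resampling uses natural boundary conditions; the coordinate maps fix
  both row ends, so no extrapolation ever occurs.
* Warps are applied feature by feature in recursion order (each row is
  resampled once per enclosing feature alignment); recursion order cannot
  change the result because sibling regions are disjoint.
* Degenerate warp geometry (feature on a region edge, or `c*` on an edge)
  collapses to a one-sided map; a side with no source pixels passes through
  unchanged.
* An LoG response whose magnitude is below `1e-11` of the image scale is
  flushed to zero before rescaling, so constant images produce an exactly
  zero response instead of amplified round-off.
* Filtering pads by symmetric reflection (period `2n`), valid even when the
  kernel is wider than the region.

## Validation design and known limitations

The test suite checks the DP against exhaustive path enumeration (hundreds
of random instances up to 8 x 8), the filters against dense direct
convolution, the warps against closed-form spline evaluation, and the whole
pipeline against the simulator's stored ground truth: band-centre constancy
after alignment, variance reduction, determinism, idempotence, and the
near-linear growth of wall time with width (exponent fitted over widths
200–10000 px at 200 frames). Efficacy runs use ten seeded default
simulations; the frame-count study uses 20–200 frames with five seeds per
setting.

Known limitations, visible in the validation runs:

* **Resolution floor.** With `sigma_h = sigma_log = 10` the effective blur
  is ~14 px, so bands closer than roughly 30 px merge into one blob whose
  ridge the search tracks faithfully — but that ridge can migrate between
  the two true band centres as their relative heights fluctuate, and
  straightening it then shears both bands. The simulator's minimum spacing
  (20 px) sits below this resolving scale, so close pairs are the dominant
  error source in the efficacy runs.
* **Temporal smoothing lag.** The path tracks the valley of the
  time-smoothed response (`sigma_v = 3` plus the LoG's own time-axis
  smoothing), so motion components faster than that window — e.g. the
  white-noise part of a random walk — are invisible to it. Under the
  default dynamics this leaves a residual band jitter of just under 1 px
  RMS, which bounds the achievable variance reduction.
* Paths are integer-valued by construction; sub-pixel refinement is out of
  scope. A consequence is that a band whose true centre sits near a
  half-integer column makes the detected path flip between neighbouring
  columns, and aligning an otherwise perfectly straight noisy kymograph can
  slightly *increase* its variance. Aligned kymographs (bands pinned at
  integer columns) are much closer to fixed points, but marginal wandering
  paths in merged-band regions can still be re-accepted on a second pass,
  so alignment is only approximately idempotent under the default
  acceptance threshold.
* Molecules entering or leaving the field, breakage, and other anomalies
  are outside the model, as is matching aligned barcodes to references.
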