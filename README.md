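# kymoalign

Weighted-path alignment of nanochannel optical DNA mapping kymographs.

## The problem

Optical DNA mapping in nanochannels images a single stretched, fluorescently
patterned DNA molecule over time. The result is a *kymograph*: an `m x n`
matrix whose rows are time frames and whose columns are positions along the
channel, in which the molecule's sequence-dependent intensity profile (its
*barcode*) appears as a set of bright and dark bands. Because the confined
molecule keeps diffusing and locally stretching, the bands wander
horizontally, and the column-wise time average — the quantity downstream
analyses need — is blurred. Alignment warps each frame so the bands run
straight, as if the molecule had been held at fixed extension.

`kymoalign` is for researchers processing such data who need alignment that
scales: the core search is a dynamic program over an implicit layered DAG,
so wall time grows near-linearly with barcode width.

## The method

Each round of the recursion detects one feature and straightens it:

1. Smooth the image with an anisotropic Gaussian (σ_h = 10 px, σ_v = 3 px)
   and apply a Laplacian-of-Gaussian filter (σ = 10 px), giving a response
   K ∈ [−1, 1], positive in dark bands, negative in bright ones. Split it
   into two non-negative cost landscapes, K_B = 1 + K (K < 0) for bright
   and K_D = 1 − K (K > 0) for dark features, with barriers at 1.
2. Find the feature F(y) — one column per row, |F(y+1) − F(y)| ≤ k — as the
   minimum-cost complete path through each landscape (barrier pixels are
   impassable); keep the cheaper polarity, and accept it if its cost per
   row is below θ = 0.9.
3. Pin F(y) at its rounded time-mean column ⟨F⟩ by per-row piecewise-linear
   stretching with natural cubic-spline resampling, split the image at the
   aligned feature, drop w = 5 columns on each side of the split from
   further search, and recurse until regions are narrower than 2w.

The aligned kymograph is summarised by its time trace ⟨I(x)⟩ = (1/m) Σ_y
I(x,y), the column variance σ²(x) = (1/m) Σ_y [I(x,y) − ⟨I(x)⟩]², and an
information score that rates barcode quality from the contrasts |ΔI_k|
between neighbouring trace peaks and valleys:

    IS = Σ_k [ ½·log(2π·log(σ² + χ)) + log(|ΔI_k|)² / (2·log(σ² + χ)) ]

with χ = 1 and natural logarithms. A seeded simulator generates kymographs
with known ground-truth warps so the whole pipeline is testable without any
experimental data.

## Worked example

```r
library(kymoalign)

bc  <- generate_barcode(seed = 42)                 # 170 px, 4 bands
sim <- generate_kymograph(bc, seed = 42)           # 200 frames + dynamics
res <- align_kymograph(sim$kymograph)
res
#> kymograph alignment: 200 x 170, 15 feature(s), 0 region(s) rejected
#>   dark feature at column 1 (region 1..133, cost/row 0.277)
#>   ...
#>   bright feature at column 139 (region 1..170, cost/row 0.058)
#>   ...

tt_raw <- time_trace(sim$kymograph)
tt_al  <- time_trace(res$aligned)
c(raw = tt_raw$mean_variance, aligned = tt_al$mean_variance)
#>    raw  aligned
#>  160.9     63.1
```

Alignment cut the mean column variance from 160.9 to 63.1 (×2.5): the time
trace of the aligned kymograph is correspondingly sharper, and its
information score rises from 23.0 to 25.4. Checking against the simulator's
ground truth:

```r
alignment_error(res, sim$truth)[c("mean_center_rms", "match_fraction")]
#> $mean_center_rms
#> [1] 1.19
#> $match_fraction
#> [1] 1
```

All four true bands were matched by detected features and, after alignment,
each true band centre stays within 1.19 px RMS of a fixed column. The
per-row cost of each accepted feature (printed above) is its distinctness:
the strong band at column 139 cost 0.058 per row, while weaker
secondary structure sits closer to the θ = 0.9 acceptance threshold.

File-level drivers mirror these functions: `cli_simulate()`, `cli_align()`
and `cli_score()` read/write TSV/TIFF/PNG kymographs plus JSON reports, and
`inst/cli/kymoalign.R` exposes them as a shell command:

```sh
Rscript inst/cli/kymoalign.R simulate --output-prefix sim --seed 7
Rscript inst/cli/kymoalign.R align --input sim_kymograph.tsv --output-prefix out
Rscript inst/cli/kymoalign.R score --input out_aligned.tsv --output-prefix out
```

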