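# bstdmar — projection-domain bone/soft-tissue decomposition for metal artifact reduction

Metal objects inside a sample absorb low-energy X-rays so strongly that
cone-beam and parallel-beam micro-CT reconstructions develop star-shaped
beam-hardening streaks around them, obscuring exactly the regions one most
wants to see.  `bstdmar` removes the dense object *before* reconstruction:
every raw projection `f` (a 2D radiograph) is decomposed under the
image-formation model

    f(x,y) = U(x,y) * (1 - S(x,y)) + S(x,y)

into a soft-tissue transmittance image `S` and a hard-tissue image `U`.
`S` equals `f` outside a thresholded metal mask and, inside it, the
*membrane*: the smooth interpolant of the mask's boundary values — the
discrete solution of the Laplace problem ΔS = 0 with S = f on ∂M,
computed as inverse-distance (Shepard, d⁻³) interpolation and accelerated
to linear time with convolution pyramids (small fitted kernels h1, h2, g).
Reconstructing −log S with FBP/FDK yields a metal-free soft-tissue volume;
reconstructing the hard-tissue transmittance `f/S` yields a
dense-object-only volume with strongly enhanced contrast (the "bone
image").  The package is aimed at micro-CT users and MAR researchers: it
also ships the standard sinogram-inpainting baselines (LI-MAR, NMAR), a
polychromatic Beer–Lambert phantom simulator producing paired
with/without-metal scans, and SSIM/PSNR evaluation tools.

## Worked example

Simulate the paired phantom experiment (structured plastic/wood phantom,
titanium-alloy rod, 360 projections, Poisson noise), run the pipeline with
and without the decomposition, and compare both reconstructions against
the metal-free reference:

```r
library(bstdmar)

none <- runPipeline(list(simulate = list(), method = "none", seed = 1))
bstd <- runPipeline(list(simulate = list(), method = "bstd",
                         component = "both", seed = 1))
rbind(none$metrics, bstd$metrics)
#>        volume   ssim  psnr mean_abs_diff
#> 1 uncorrected 0.2081  4.54       0.00586
#> 2        soft 0.3126 12.46       0.00426
#> 3        hard 0.0188  4.89       0.00727
```

Read: against the metal-free reference slice, the uncorrected
reconstruction scores SSIM 0.21 / PSNR 4.5 dB; reconstructing the
soft-tissue projections instead raises this to SSIM 0.31 / 12.5 dB and
shrinks the mean absolute difference map by about a quarter — the streaks
radiating from the rod are gone and the empty space it occupied is
restored.  The `hard` volume scores poorly against the *soft* reference by
construction: it contains only the rod, at high contrast, and is meant for
visualizing the dense object itself.

The mask-size study behind the choice of threshold:

```r
thresholdSweep(list(simulate = list(), seed = 1),
               thresholds = c(5000, 6000, 7000, 8000, 9000, 10000))
#>   threshold coverage    ssim  psnr mean_abs_diff
#> 1      5000    0.819  0.0646  9.03       0.00572
#> 2      6000    0.899 -0.0138  9.39       0.00572
#> 3      7000    0.954 -0.0316  9.42       0.00572
#> 4      8000    0.987 -0.0144  9.78       0.00554
#> 5      9000    0.999  0.0778 10.80       0.00503
#> 6     10000    1.000  0.3126 12.46       0.00426
```

`coverage` is the fraction of the rod's detector shadow covered by the
mask: it grows monotonically with the threshold, and the best SSIM/PSNR
are reached at full coverage — an under-covering mask leaves
artifact-generating pixels in the projections.

A thin command-line front-end with `simulate` / `run` / `sweep` /
`evaluate` subcommands over YAML configs lives at
`inst/cli/bstdmar.R`.

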