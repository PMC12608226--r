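# viband

Spectral band optimization for vegetation-index (VI) based estimation of
leaf chlorophyll and carotenoid content.

Two-band vegetation indices — NDVI, SR, SAVI and friends — are the
workhorse of non-destructive pigment monitoring, but the number a device
reports depends on *its* spectral channels: the central wavelength λ and
bandwidth (FWHM) Δλ of each band, plus the index formula and the regression
wired into the calibration. viband is for people designing or evaluating
such instruments: it models a channel as a Gaussian transmission function,
evaluates all seven common two-band index forms over every ordered
wavelength pair in 450–950 nm (250,500 pairs per bandwidth setting at 1 nm
resolution), calibrates an exponential pigment~VI regression
`y = a·exp(b·x)` for each configuration, selects optima by the coefficient
of determination, and quantifies how much accuracy is lost when channels
shift, bands broaden, or formulas are swapped.

The calibration ground truth is classical extract spectrophotometry:

    Chl = 6.1·D665 + 20.04·D649        (mg/L)
    Car = 4.695·D440.5 − 0.268·Chl     (mg/L)

Because no per-sample spectra ship with the package, a synthetic leaf
generator provides populations with the right structure: bivariate-normal
pigment draws matching published crop statistics ("cucumber-like",
"lettuce-like" presets), Beer–Lambert-style spectra with pigment-dependent
absorption features and a chlorophyll-driven red edge, per-leaf structural
variability, and extract optical densities that invert the reference
equations exactly. See the methods vignette
(`vignettes/band-optimization.Rmd`) for the model and its limits.

## Worked example

```r
library(viband)

# 50 synthetic cucumber-like leaves, low noise
ss <- simulate_samples(50, "cucumber-like", noise = "low", seed = 1)
head(ss$pigments, 3)
#>   sample_id       chl      car
#> 1        S1  9.621852 1.942601
#> 2        S2  7.361161 1.927178
#> 3        S3 10.200310 2.005223

# exhaustive search: 5 nm grid, bandwidths {1, 10, 50} nm, all 7 formulas
opt <- optimize_bands(ss, "chl",
                      grid_config(step = 5, bandwidths = c(1, 10, 50)))
opt$overall
#>   formula pigment lambda1 dl1 lambda2 dl2        a         b        r2
#> 1      SR     chl     695  10     915  10 22.80995 -2.875624 0.9983062
#>         rmse re_percent n_valid
#> 1 0.09385358   0.955146      50
```

The optimum lands where it should: one channel on the red-edge shoulder
(695 nm, the steepest pigment-sensitive region of the synthetic spectra),
one on the insensitive NIR plateau, with R² = 0.998 and an RMSE of
0.094 mg/L (≈1% relative error). Shifting both channels off the optimum
degrades the re-fitted calibration:

```r
shift_profile(ss, opt$overall, max_shift = 20, step = 10)
#>   offset1 offset2        r2       rmse re_percent max_dev_percent
#> 1     -20     -20 0.9515950 0.50172529   4.151042       26.676749
#> 2     -10     -10 0.9878684 0.25117727   2.104718       13.317851
#> 3       0       0 0.9983062 0.09385358   0.955146        3.446757
#> 4      10      10 0.9909910 0.21645133   1.899237       12.950763
#> 5      20      20 0.9745693 0.36366360   3.096308       22.763306
```

— a 20 nm displacement already produces individual-leaf prediction errors
above 25% of the mean concentration. Keeping the channels fixed and
changing only the formula splits the field in two:

```r
formula_comparison(ss, 695, 10, 915, 10, "chl")
#>   formula     r2    rmse re_percent rank
#> 1      SR 0.9983 0.09385     0.9551    1
#> 2     mSR 0.9938 0.17891     1.6967    2
#> 3    mNDI 0.9845 0.28351     2.6652    3
#> 4    NDVI 0.9833 0.29456     2.4341    4
#> 5    SAVI 0.9707 0.39053     4.1172    5
#> 6      DI 0.7912 1.04206    11.1811    6
#> 7     TVI 0.7893 1.04670    11.2236    7
```

Ratio-type indices tolerate the per-leaf gain and plateau variability of
the population; difference-type indices (DI, TVI) do not — an R² spread of
0.21 at identical channels, which is why reporting "the NDVI" of a leaf
without the channel and calibration details is not reproducible.

A thin command-line wrapper with `simulate`, `optimize` and `sensitivity`
subcommands lives at `inst/cli/viband.R`.

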