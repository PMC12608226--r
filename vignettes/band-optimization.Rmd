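---
title: "Optimizing spectral channels for VI-based leaf pigment estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing spectral channels for VI-based leaf pigment estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viband)
```

## The measurement problem

Non-destructive estimation of leaf chlorophyll (Chl) and carotenoid (Car)
content from reflectance rests on a simple chain: a sensor measures
reflectance in two (or a few) spectral channels, the values are combined
into a vegetation index (VI), and a calibration curve converts the index
into a concentration. Every link of that chain carries instrument-specific
choices — which central wavelengths $\lambda$, which bandwidths (FWHM)
$\Delta\lambda$, which index formula, which regression — and devices in the
field differ in all of them. viband implements the full design loop: it
simulates channels, searches every two-band configuration exhaustively,
calibrates pigment–index regressions, and quantifies how fragile the
resulting estimates are to wavelength shifts, bandwidth changes and formula
substitution.

The ground truth against which everything is calibrated is the classical
spectrophotometry of ethanol extracts:

$$Chl = 6.1\,D_{665} + 20.04\,D_{649}, \qquad
  Car = 4.695\,D_{440.5} - 0.268\,Chl,$$

with $D_\lambda$ the extract optical densities (`chl_from_od()`,
`car_from_od()`). Negative carotenoid outputs are possible for inconsistent
inputs and are returned with a warning rather than clipped, so calibration
code always sees the formula's raw behaviour.

## The processing pipeline

1. **Reflectance**: $R(\lambda) = I_{obj}(\lambda) / I_{ref}(\lambda)$
   against a uniform reference panel (`compute_reflectance()`), then
   Gaussian denoising with $\sigma = 20$ nm (`gaussian_smooth()`). That
   $\sigma$ is heavy relative to the 1 nm grid; it is the conventional
   setting and an explicit argument, not a constant.
2. **Channel model**: each sensor channel is a Gaussian transmission
   function with center $\lambda$ and FWHM $\Delta\lambda$, converted via
   $\sigma_{ch} = \Delta\lambda / (2\sqrt{2\ln 2})$, truncated at
   $\pm 4\sigma_{ch}$, renormalized to sum one on the grid, and applied as a
   weighted mean (`band_reflectance()`). Channels whose truncation window is
   clipped by the 450/950 nm boundary are renormalized over the visible part
   rather than excluded — optimal configurations at the very edge of the
   range (e.g. 451 nm with a 50 nm width) are legitimate and must remain
   searchable.
3. **Index computation**: seven two-band forms (SR, DI, mSR, mNDI, TVI,
   SAVI, NDVI; `vi_formulas()`, `compute_vi()`).
4. **Calibration**: a two-parameter exponential
   $y = a e^{b x}$ fitted per configuration (`fit_exponential()`), with
   $R^2$, RMSE (mg/L) and mean relative error RE (%) evaluated in the
   original concentration space (`evaluate_metrics()`).
5. **Search**: all ordered wavelength pairs $\lambda_1 \ne \lambda_2$ on a
   1 nm grid over 450–950 nm (250,500 per bandwidth pair), for every
   bandwidth pair from $\{1, 5, 10, 30, 50\}$ nm, for every formula
   (`optimize_bands()`); selection by maximum $R^2$ with RMSE and
   lexicographic tie-breaks (`select_optimal()`), and a dual-criterion
   report (`compare_criteria()`) for the robustness check that switching to
   RMSE-minimization moves optima by at most a nanometer or two.

## Design choices in the index library

The seven formulas are implemented in two-searched-band form. Published
optimum tables assign exactly two searched wavelengths per index, so the
three forms that classically involve a third band keep it **fixed**: mSR and
mNDI use an auxiliary band at 445 nm, TVI a green band at 550 nm, all
configurable per call (`aux_centers`). This is the major formula ambiguity
in the literature — the same index name covers several algebraic variants —
and the registry (`vi_formulas()`) therefore exports the exact expressions
used.

Two further conventions: the auxiliary band inherits the FWHM of the first
searched channel by default (`aux_fwhm`), and because the default spectral
grid starts at 450 nm, an auxiliary center of 445 nm is clamped to the grid
edge before integration (a narrow 445 nm channel would otherwise have no
support at all on the grid). Band-slot orientation ("red" vs "NIR") is not
hard-coded: the optimizer searches ordered pairs, so orientation is absorbed
by the search. Denominators below $10^{-9}$ in magnitude yield `NA`, which
the map machinery masks, rather than infinities.

## Calibration and metrics

The exponential is fitted by closed-form least squares of $\ln y$ on $x$ —
exact on noiseless exponential data and cheap enough to run 250,500 times
per map. An optional refinement (`refine = TRUE`) re-fits in the original
space with `minpack.lm::nlsLM()`; it is off by default because the log-space
fit is what makes full-scale maps affordable, and on the synthetic data the
two agree closely. The form has no offset term, keeping the map fit
closed-form.

Metrics follow the standard definitions:
$R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2$,
$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (\hat y_i - y_i)^2}$, and
$\mathrm{RE} = \tfrac{100}{\bar y}\cdot\tfrac1n\sum_i |\hat y_i - y_i|$ — one
aggregate percentage per model, normalized by the mean measured
concentration. Non-standard historical variants (an uncentered first-order
$R^2$ ratio and an RMSE computed about $\bar y$) are available behind
`literal = TRUE` purely for auditing; they are never used by the optimizer.

Numerically, predictions are computed as $\exp(\ln a + b x)$ in the centered
form $\exp(\bar z + b(x - \bar x))$, which stays finite at near-degenerate
cells where the index barely varies and $a = \exp(\bar z - b \bar x)$ alone
would overflow. Cells with fewer than 3 valid samples, zero index variance,
zero pigment variance, or non-finite parameters are masked. The vectorized
map engine accumulates the same centered sums the scalar per-cell path uses,
so the two agree to ~1e-12 and are cross-checked in the tests.

## The synthetic leaf population

No per-sample spectra are shipped; the generator replaces them with a
population whose statistical structure matches what the analysis assumes.

**Pigments** are drawn from a bivariate normal, truncated at zero by
resampling, with preset moments from reference spectrophotometry of real
crops: `cucumber-like` (Chl $7.88 \pm 2.77$, Car $1.86 \pm 0.31$ mg/L, a
juvenile high-variability group) and `lettuce-like` (Chl $3.94 \pm 0.83$,
Car $1.13 \pm 0.17$ mg/L, a low-pigment cultivar). The default pigment
correlation of 0.8 encodes the strong Chl–Car coupling seen in leaves.
Truncation makes the realized moments slightly approximate for presets close
to zero.

**Spectra** follow a Beer–Lambert-style attenuation of a smooth baseline:

$$R(\lambda) = \mathrm{clamp}\!\big(g \cdot B(\lambda)\,
  e^{-[Chl\,A_{chl}(\lambda) + Car\,A_{car}(\lambda)]}(1+\varepsilon_m)
  + o + \varepsilon_a,\ 0,\ 1\big)$$

with a flat NIR plateau plus a 550 nm bump as baseline $B$, and Gaussian
absorption components per pigment: Chl in the blue (430 nm) and red
(649/662 nm) with a red-edge shoulder at 700 nm; Car at 450/478 nm. This is
an invented functional form — the study design it supports used measured
spectra — chosen because it reproduces, with defaults, the qualitative
features the analysis exploits: a green reflectance peak, deep red
absorption anticorrelated with Chl ($r < -0.9$ at 670 nm), a red edge whose
midpoint crossing shifts monotonically to longer wavelengths with Chl
(`red_edge_position()`), and a pigment-insensitive NIR plateau (<5%
variation above 780 nm at zero noise).

**Variability** has two tiers, and the distinction matters. Wavelength-wise
measurement noise ($\varepsilon_m$, $\varepsilon_a$) averages out under band
integration: with it alone, every formula calibrates almost perfectly and
the analysis has nothing to compare. What limits calibration in real leaf
populations is sample-level variation uncorrelated with pigments — internal
leaf structure moving the NIR plateau, measurement geometry scaling the
spectrum, stray light offsetting it. The model draws these per sample
(`plateau_sd = 0.04`, `gain_sd = 0.03`, `offset_sd = 0.004`), which is what
makes ratio-type indices (SR, NDVI, mSR, mNDI) visibly more robust than
difference-type ones (DI, TVI) and produces an $R^2$ spread across formulas
of roughly 0.2–0.4 at a fixed channel pair — the qualitative regime the
analysis is about. These SDs were fixed once, as population realism, and are
exposed as model parameters. `noise_level()` maps `"none"`/`"low"`/`"high"`
onto all five SDs; `"none"` makes generation fully deterministic, which the
contract tests rely on.

What the generator does **not** emulate: radiative transfer
(PROSPECT-class leaf optics), water absorption beyond 950 nm, specular/BRDF
effects, canopy structure, or within-group developmental substructure. A
passing end-to-end test therefore demonstrates that the pipeline recovers
designed-in structure, not that any particular real crop behaves this way.

**Extract optical densities** are generated by algebraically inverting the
reference equations (`ods_from_pigments()`), splitting the summed red
chlorophyll signal between $D_{665}$ and $D_{649}$ with a fraction
`a_b_split` (default 0.7, an arbitrary value in the physiological range —
it does not affect the round trip, which is exact to machine precision).

## Sensitivity analyses

All three profiles re-fit the calibration at the perturbed configuration:
the question is how good the *best achievable* model is at the perturbed
channels, not how a frozen model decays (a `frozen = TRUE` mode exists for
simulating uncorrected device drift).

- `shift_profile()` displaces the centers by up to ±20 nm, jointly by
  default or over the full 2-D offset grid (`mode = "per_channel"`); offsets
  pushing a center outside 450–950 nm are dropped and counted. Because a
  jointly shifted pair is itself a member of the exhaustive search space, no
  probed offset can beat the search optimum — an internal consistency check
  the tests assert at every offset. Both the maximum and the mean per-sample
  prediction deviation (in % of $\bar y$, the RE normalization) are
  reported, since aggregation conventions differ between studies.
- `bandwidth_profile()` re-fits at each candidate FWHM with centers fixed
  and attaches a stability score per bandwidth:
  $\max |R^2(\lambda \pm 5\,\mathrm{nm}) - R^2(\lambda)|$. On data with a
  narrow (10 nm) absorption feature the score decreases as channels widen —
  broader channels trade peak sensitivity for shift tolerance.
- `formula_comparison()` evaluates all seven formulas on identical band
  reflectances at one fixed channel pair, each with its own calibration,
  with per-sample relative errors and a ranking.

## Problem sizes and reproducibility

Full-scale runs (1 nm grid, 250,500 pairs per map) complete in seconds per
map with the vectorized engine. The shipped test suite and the acceptance
script use a 5 nm search grid (10,100 pairs per map) with 50-sample
populations — small enough to run everywhere in seconds, large enough that
the end-to-end properties (optimum inside the designed informative region,
$R^2 \ge 0.8$, argmax dominance under shifts, bandwidth stability ordering)
hold with margin. All randomness flows through explicit seeds via
`withr`, so every number in the tests and the acceptance report is
bit-reproducible.

```{r example}
ss <- simulate_samples(30, "cucumber-like", noise = "low", seed = 1)
opt <- optimize_bands(ss, "chl",
                      grid_config(step = 10, bandwidths = c(1, 10),
                                  formulas = c("NDVI", "SR", "DI")))
opt$overall
```

## Known limitations

- The exponential calibration has no offset; pigment–index relations with a
  nonzero asymptote are fitted only approximately.
- The two-searched-band reading of mSR/mNDI/TVI is one of several published
  conventions; results for those indices are convention-dependent by
  nature, which is part of what the package demonstrates.
- Whether boundary-clipped channels should be renormalized or excluded is
  genuinely ambiguous in the field; viband renormalizes, and documents it.
- Synthetic spectra support method development and verification, not
  agronomic conclusions about real crops.
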