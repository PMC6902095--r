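---
title: "Quantitative dot-blot densitometry and cohort analysis with satblot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative dot-blot densitometry and cohort analysis with satblot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satblot)
```

## The assay and its model

Non-radioactive quantitative hybridization (NQH) measures the abundance of
a tandem repeat — here satellite III DNA of chromosome region 1q12,
reported as pg of repeat per ng of genomic DNA — by spotting a fixed mass
of denatured genomic DNA (50 ng) on a membrane, hybridizing with a
biotinylated probe, developing a colorimetric precipitate, and scanning
the membrane. Each DNA sample is spotted in triplicate; six genomic
standards of known repeat content and one spot of DNA non-homologous to
the probe (the background spot) are spotted alongside.

satblot models the integral intensity of a spot carrying content $q$ as

$$I(q) = \mathrm{clamp}\!\left(a + b\,\ln\frac{q}{q_{\mathrm{ref}}},\ 0,\ I_{\mathrm{sat}}\right) + I_{\mathrm{bg}},$$

a logarithmic law with saturation: the more precipitate already in a spot,
the less an extra unit of target adds, until the development saturates at
$I_{\mathrm{sat}}$. Every spot (including the background spot, which
carries no specific signal at all) receives the nonspecific level
$I_{\mathrm{bg}}$. The functional form is deliberately isolated behind
`fit_calibration()` / `invert_calibration()`, so a different saturating
law could be swapped in without touching densitometry or the statistics.

### Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `intercept_a` | integral units | 10000 | sets the working brightness; at 16-bit depth this keeps peak pixels near 1/200 of the raster maximum, far from clipping |
| `slope_b` | units per ln(pg/ng) | 2000 | a 5% content change moves the integral by ~100 units, well above quantization |
| `q_ref` | pg/ng | 1 | reference content at which $I = a + I_{bg}$ |
| `saturation_level` | integral units | 1e6 | far above the working range, so clamping only occurs when explicitly provoked |
| `background_level` | integral units | 500 | the non-homologous spot's level |
| `assay_cv` | relative SD | 0.05 | the hybridization step's own relative error (stated 5 ± 2%) |
| `extraction_cv` | relative SD | 0 | the DNA-isolation stage; ~0.10 reproduces the stated total error, $\sqrt{0.05^2+0.10^2}\approx0.112$ |
| standards | pg/ng | 6 values, log-uniform in 6–44 | the distribution family over the range is not stated for the real assay; log-uniform matches the logarithmic response (a design choice made once) |

## Noise model

Both wet-lab noise stages are multiplicative on the content scale and act
*before* the signal transform: extraction noise once per sample, assay
noise once per spot (standards skip extraction — they bypass DNA
isolation). Each stage is lognormal with $\sigma_{\log} = \ln(1 + cv)$,
which keeps contents positive and makes the requested coefficient of
variation an exact parameter (to first order $\sigma_{\log} \approx cv$;
at $cv = 0.05$, $\ln 1.05 = 0.0488$). On the raster, additive Gaussian
pixel noise and an optional smooth linear gradient model scanner noise
and uneven development.

## Rendering and densitometry

Spots are isotropic Gaussians truncated at $3\sigma$ inside a circular
footprint with $\sigma = r/3$, scaled so the *discrete* pixel sum equals
the forward-model integral exactly — which makes the generator a pixel-
level oracle for the densitometry stage. Note the truncation: a
$3\sigma$ disk holds $1 - e^{-4.5} \approx 98.9\%$ of an untruncated
Gaussian's mass, so closed-form checks against $2\pi A \sigma^2$ must
either include that factor or integrate out to $4\sigma$.

Measurement (`integrate_spot()`) sums pixels whose centres fall in the
disk (no anti-aliased edge weighting; the error is bounded by
perimeter/area and vanishes in the background-corrected difference) and
subtracts disk-area times the *median* of an annulus (default offsets
+2 to +6 px), which is robust to bleed from neighbouring spots. The real
scanner software's integration rule is not public; these are declared
replacements, not reconstructions, and the tested invariants (linearity,
offset invariance, translation equivariance, generator-oracle agreement)
are what define "correct" here. Saturation is flagged when more than 1%
of disk pixels sit at the raster maximum; flagged standards are excluded
from calibration fits. Grid refinement (`locate_spots()`) is an
intensity-weighted centroid in a square window, with a low-signal guard
that keeps the nominal centre.

## Calibration and inverse prediction

The standard curve is unweighted least squares of corrected standard
intensities on $\ln(q/q_{\mathrm{ref}})$ (each standard is itself a spot
average; no weighting scheme is given for the real assay). Before
fitting or inversion the background spot's corrected integral is
subtracted from every spot and the result floored at a small positive
epsilon. A fitted slope $b \le 0$ is a hard error (a non-monotone
calibration cannot be inverted meaningfully). Inversion is the closed
form $q = q_{\mathrm{ref}} \exp((I - a)/b)$; contents outside the span of
the standards are *flagged* extrapolated, never rejected. Triplicates are
aggregated arithmetically; the per-spot CV of recovered contents is
reported as `relative_sd` (this is the quantity the assay's "relative
standard error of 5 ± 2%" refers to), alongside the SE of the mean.
Inverse-prediction confidence intervals from the calibration covariance
are out of scope.

Copy-number conversion is the mass-fraction identity
$\mathrm{copies} = (q/1000) \cdot G / L$ for unit length $L$ and genome
size $G$ (default $3.2\times10^9$ bp): 1.55 pg/ng of a 13 kb unit is
~381 copies.

## Synthetic cohorts: the stated world

The cohort generator is first-class, tested code, and its defaults *are*
the published group moments (sample size, mean, SD in pg/ng DNA): healthy
controls 401/22.0/6.7, all patients 840/18.0/5.9, drug-naive 283/17.0/5.9,
medicated 271/18.4/5.8, hypoxia-history 143/22.7/5.4, no-hypoxia
143/14.7/3.0. The distribution family of real contents is not stated;
both a clipped normal (default — the published ranges put minima at
6 pg/ng, so clipping at 1 is negligible) and a moment-matched lognormal
(for the visible right skew) are provided. Birth years are uniform over
1935–2001; real birth-year structure (the generational disproportion in
controls) is *not* emulated, so a green stratified test establishes only
that the stratification mechanics are correct, not that the cohort
age-structure is realistic. PANSS severity follows
$\beta_0 + \beta_1 q + \varepsilon$ with defaults $(120, -1, 25)$, chosen
to give a weak negative correlation ($r \approx -0.2$) of the kind the
severity analysis expects, with plausible score levels (80–105 across the
content range).

The paired-therapy generator is the shrinkage (regression-to-setpoint)
model $\mathrm{post} = \mu + \kappa(\mathrm{pre} - \mu) + \varepsilon$.
With the defaults — baseline CV 0.31 (mean 17, SD 5.27), $\kappa = 0.45$,
$\varepsilon$-SD 1 — the closed form
$CV_{\mathrm{post}} = \sqrt{\kappa^2\sigma^2 + \sigma_\varepsilon^2}/\mu
\approx 0.15$ reproduces the published halving of the CV, and low/high
baselines move up/down respectively. The OLS slope of
$(\mathrm{post}-\mathrm{pre})$ on baseline recovers $\kappa - 1$.

The brain panel draws eight regions from a two-component satellite
mixture (3 regions at 7.3 ± 2.5, 5 at 26.8 ± 4.8 pg/ng — subgroup ratio
3.7), ribosomal repeat tightly at 381 ± 7 copies, and a telomere repeat
decreasing linearly in satellite content. Only two individual region
values of the real panel are in print, so the example panel used in tests
(`{5.0, 7.4, 9.5, 21, 25, 27, 29, 32}`) is synthetic, constructed to hit
the printed subgroup means exactly.

## Statistics

Group comparisons use the Mann–Whitney U test (midranks for ties; exact
two-sided p by enumeration when $\max(n,m) \le 8$ without ties, otherwise
the normal approximation with tie-corrected variance and continuity
correction) and the two-sample Kolmogorov–Smirnov statistic. $D$ is
*signed*: the value of $F_x - F_y$ at the point maximizing the absolute
difference, first sample minus second, so a negative $D$ means the first
sample is stochastically larger. The reported "α" is the asymptotic
Kolmogorov tail probability at $|D|\sqrt{nm/(n+m)}$ — a p-value, kept
under its traditional name. All p-values are two-sided, significance is
fixed at $p \le 0.01$, and no multiple-testing adjustment is applied (the
pair list is explicit, not all-vs-all).

The bimodal brain-panel partition is 1-D two-means by exhaustive
threshold scan over the $n-1$ cuts between consecutive order statistics —
the unrestricted within-SS optimum over all two-subset partitions is
always contiguous in sorted order, a property the tests assert by brute
force to $n = 10$. A Mann–Whitney p between the subgroups is reported as
descriptive context only: at 3-vs-5 the test is underpowered to certify
bimodality.

## Numerical choices and degenerate inputs

* CVs are never rounded internally; report rounding is 2 decimals for
  CVs, 1 for contents and subgroup ratios.
* With all noise off and a continuous raster, the full pipeline
  (simulate → measure → calibrate → invert) returns true contents to
  1e-6 relative error (tested). With 16-bit quantization, rounding a
  smooth profile to integer counts biases spot integrals by a few counts,
  which at the default signal scale is up to ~1% in content — the reason
  the exact round-trip contract is stated on the continuous raster.
* Inversion at the domain edges carries a 1e-9 relative slack on the
  extrapolation flag so floating-point jitter cannot flag an in-domain
  content.
* Degenerate cases are errors, not NaNs: empty samples, all-flagged
  replicates, fewer than 3 distinct standards, non-positive contents,
  all-equal values in the partition, zero-variance correlation inputs.
* Generators are pure functions of (spec, seed); child seeds in the demo
  are derived with a fixed linear-congruential step and stay below
  $2^{31}$.

## What a green suite does and does not establish

The synthetic world reproduces the *stated* signal law, error magnitudes
and group moments. It does not emulate membrane-to-membrane batch
effects, spatially correlated development artifacts beyond a linear
gradient, real demographic confounding, ties from instrument rounding,
or the unknown true content distribution shape. Passing tests therefore
certify the measurement and analysis machinery against the declared
model, and the headline group separations under the published moments —
not the biology.

## File formats and CLI

Images are written as plain-text PGM (P2; a P5 reader is included) and
optionally 16-bit PNG when the `png` package is available — the
environment this package targets has no TIFF library, so the TIFF
interface common in blot scanners is intentionally not provided. Tables
are comma-separated UTF-8 CSV with header rows; reports and the demo
manifest are JSON. The `satblot` script under `inst/cli/` exposes
subcommands `simulate-membrane`, `quantify-image`, `calibrate`,
`quantify`, `simulate-cohort`, `compare`, `therapy`, `panss`,
`brain-panel` and `demo`; the demo chains every stage and writes a
manifest with per-file MD5 checksums, the seed, and a configuration hash,
and is byte-deterministic in its data products under a fixed seed
(figures are PDF and embed timestamps).
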