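---
title: "Serum Raman metabolomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum Raman metabolomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seraman)
```

## The measurement and its model

A dried-serum Raman measurement in the fingerprint region (600-1800
cm^-1^) is modeled throughout this package as

$$ I(\nu) \;=\; B(\nu) \;+\; \sum_{k} a_k\, \phi(\nu - \nu_k) \;+\;
\varepsilon(\nu) \;+\; \text{spikes}, $$

where $B$ is a smooth, strictly positive fluorescence background that
dominates the bands severalfold, $\phi$ is a narrow line shape of a few
cm^-1^ width, $\nu_k$ are the 40 panel band positions between 621 and
1682 cm^-1^ (amino acids, sugars, lipids and fatty acids, carotenoids,
nucleic-acid bands, Amide I/III), $\varepsilon$ is channel noise, and
spikes are rare 1-3-channel cosmic-ray artifacts specific to a single
detector read. Each serum sample contributes ~100 replicate point
spectra collected as line maps; replication is the lever for both noise
averaging and cosmic-ray identification.

The analysis currency is not the spectrum but the **ratiometric peak
table**: per sample, one dimensionless value per panel band, each band
height divided by the height of the 1448 cm^-1^ CH~2~-deformation band
of lipids and proteins. Ratios cancel the overall intensity scale,
which varies with focus, film thickness and laser power. Some sources
quote the reference band at 1447 cm^-1^; the +/-5 cm^-1^ extraction
window makes the 1-cm^-1^ discrepancy immaterial, and the panel uses
1448 cm^-1^ with the window-based extraction.

## The preprocessing chain

Stages run strictly in this order per sample; the whole chain is
invariant under positive affine transforms $aI+b$ of the raw
intensities (verified to 10^-8^ by the test suite).

**Cosmic-ray repair** (replicate consensus). Each channel of each point
is scored by a robust z against the per-channel median and MAD across
the sample's replicate points; runs of at most `cosmic_max_width = 3`
channels exceeding `cosmic_threshold = 8` are replaced by the
per-channel replicate median. Two numerical details matter. First, the
per-channel MAD from few replicates is itself noisy, so it is floored
at the pooled (median-over-channels) MAD; without the floor,
chance-tiny denominators flag clean channels. Second, the replacement
is the replicate median rather than a linear bridge: on a sharp band
flank an interpolated bridge can err by tens of noise standard
deviations, while the replicate median stays within a few. With fewer
than three replicates the detector falls back to a running-median
residual with interpolation repair.

**Savitzky-Golay smoothing** (order 5, frame 17 channels). A local
least-squares polynomial filter: any signal that is locally a
polynomial of degree <= 5 passes unchanged, so band shapes of width
comparable to the frame are preserved while white noise shrinks by the
filter's coefficient norm. Edges are handled by evaluating the
boundary-anchored full-window fit at the edge positions - no data are
fabricated beyond the measured range.

**Modified-polyfit baseline** (degree 9). The canonical fit-and-clip
iteration for fluorescence removal: fit a degree-9 polynomial to the
working signal, clip every working value above the fit down to the
fit, repeat. Peaks - which only stick up - are progressively excluded,
and the fit converges to the background beneath them. Numerical
choices: the fit uses an orthonormal polynomial basis on a channel
axis rescaled to [-1, 1] (a raw degree-9 Vandermonde on wavenumbers is
severely ill-conditioned), and because the basis is fixed, each
iteration is two matrix products with a precomputed orthogonal factor.
The stopping rule is the maximum change of the fit relative to the
fit's own *range* (not its magnitude), which keeps the criterion - and
therefore the iteration count - invariant under affine intensity
transforms; tolerance 10^-6^, cap 100 iterations. Hitting the cap is
recorded in the QC block, not raised: with noisy input the iteration
keeps digging into the noise floor long after the estimate has
stabilized for practical purposes, and the capped estimate is
empirically as close to the true background as the fully converged
one. Two caveats are documented rather than hidden: the per-iteration
sup-norm descent of the clipped residual is only approximate (the
polynomial wobbles locally right after clipping), and the estimate
carries a downward bias of roughly one smoothed-noise standard
deviation, the familiar cost of clipping symmetric noise from above.

**SNV normalization.** Per spectrum, subtract the mean and divide by
the standard deviation. A constant spectrum has no SNV image and is an
error.

Baselines are estimated per point spectrum (not on the sample mean):
fluorescence varies across the dried film, and per-point estimation is
the choice that does not assume otherwise. The alternative costs one
line to implement on the mean spectrum if a user prefers it.

## Peak quantification

Replicate point spectra are averaged *before* extraction (maximizing
SNR at the one place a single number per sample per band is formed),
then each band is read as the windowed maximum within +/-5 cm^-1^ of
its nominal position - robust to the few-cm^-1^ calibration drift seen
between acquisitions. One subtlety: after baseline removal the off-peak
level of an SNV-normalized spectrum sits at $-\mu/\sigma$, not at zero,
so raw windowed maxima are offset by a constant that would distort
ratios, most severely for weak bands. Heights are therefore measured
above the spectrum's 5th-percentile floor (the median is unsuitable:
forty bands of ~8 cm^-1^ width cover more than half the fingerprint
channels, so the median sits inside band tails). With the floor
subtracted, the ratio of two extracted heights recovers the ratio of
the underlying composite band heights.

"Composite" is deliberate: at the panel's band spacing (e.g.
992/1002/1011 cm^-1^) windowed maxima measure overlapping-band sums,
not deconvolved amplitudes, and the smoothing filter redistributes
overlapping maxima by several percent. Recovery tests therefore
compare against the analytic composite height of the generator's band
sum passed through independently constructed smoothing coefficients -
recovery is then within a few percent for resolvable bands, while the
weakest bands under heavy Lorentzian overlap carry a larger systematic
(documented, not corrected: deconvolution is out of scope).

## Cohort statistics

* **Volcano**: per band, fold change is the linear-scale ratio of group
  means (case over reference) and the p-value an unpaired two-sided
  pooled-variance t-test. Significance is raw p < 0.05 with *no*
  multiplicity correction by default - matching the reporting
  convention this workflow reproduces - with Benjamini-Hochberg behind
  a flag for users who want it. The constant denominator column is
  reported with p = 1 rather than erroring.
* **Correlations**: plain Pearson, pairwise over features; zero-variance
  features yield NA with a warning.
* **ROC**: AUC by midrank (Mann-Whitney) counting, ties credited one
  half; orientation is fixed by the declared positive class and never
  auto-flipped, so an AUC below 0.5 is reported as such. The 95% CI is
  a stratified percentile bootstrap (2000 resamples), resampling
  positives and negatives separately so class balance is preserved.
* **Embeddings**: PCA on centered, unit-variance-scaled features
  (bands and analytes live on different scales); PCA-tSNE reduces to 10
  components first, then runs exact t-SNE with perplexity
  `min(30, (n-1)/3)`, deterministic for a recorded seed.
* **PCA-SVM LOOCV**: for each held-out sample, PCA (2 components) and a
  linear SVM are refitted on the remaining samples only, and the cost
  parameter is chosen from a log-spaced grid inside [1, 100] by an
  inner leave-one-out loop nested within each training fold (ties to
  the smallest cost). The nested, per-fold design is the default
  because the leaky alternative - PCA fitted once on all samples -
  overstates accuracy; the leaky variant is available behind
  `leaky = TRUE` for comparison. The ratiometric denominator column is
  excluded from all scaled multivariate analyses (it is identically 1).
* **NAR stratification**: complete < 8, partial 8-14 inclusive, poor
  > 14. Where conventions conflict on boundary membership, the
  inclusive table convention is adopted; 8.0 and 14.0 are partial.
* **Rank metric**: $-\log_{10}(p)\cdot\mathrm{sign}(\log_2 FC)$ per
  protein, complete-over-poor ratio of means, with
  $\mathrm{sign}(0) = 0$ so FC = 1 can never be called directional.
  The differential cutoff |metric| > 1.30 is read as the alpha = 0.05
  line ($-\log_{10} 0.05 = 1.30$ to two decimals); comparison is
  strict on 4-decimal-rounded values, so p = 0.05 exactly is *not*
  differential. Set-level enrichment itself is not implemented - the
  package emits a `.rnk` file for external enrichment tools.

## The synthetic cohort generator

Patient sera behind the motivating analyses are not publicly
deposited, so every stage is validated against simulated cohorts whose
ground truth is fully recorded. The generator draws, per sample, band
amplitudes `base x group-factor x lognormal(cv 15%)` (multiplicative
biological variation keeps positivity and produces realistic volcano
behavior), a positive degree-6 baseline 5-20x the denominator band,
then per point adds Gaussian channel noise (default 1% of the
denominator amplitude) and Poisson-rate cosmic spikes (default 0.05
per point, 20-100x noise, 1-3 channels). Bands are pseudo-Voigt
(50/50) with 8 cm^-1^ FWHM - typical of serum fingerprint bands.
Protein panels are linear loadings on standardized log-amplitude
scores plus noise, optionally linked to the NAR latent score; NAR
scores are a linear model on those same scores, truncated at zero so
responder classes derived from them are always self-consistent. The
`pdac_vs_cp` preset encodes elevated sugar/glucose and aromatic
amino-acid bands with depressed carotenoids in the cancer group, with
pancreatitis sharing the carotenoid and glucose shifts but not the
852/828/805 cm^-1^ shifts; `larc_response` loads NAR positively on
glycine, sugar and carotenoid bands at pre-treatment and not at all at
post-treatment.

What the generator does *not* emulate: physically derived shot noise
(channel noise is homoscedastic Gaussian), instrument drift and
wavenumber miscalibration, Mie-scattering baseline shapes beyond
polynomials, and band-shape heterogeneity across metabolites. Passing
recovery tests therefore demonstrate that the pipeline inverts its own
stated model at realistic noise levels - not that it is robust to
every artifact of real instruments.

## Problem sizes and runtime choices

The shipped tests run cohorts of 3-20 samples per group with 2-10
points per sample on 1-2 cm^-1^ grids, baseline recovery on 50 spectra,
t-test calibration on 10,000 draws, volcano recovery on 100 simulated
cohorts, and the SVM permutation null on 50 repetitions - sizes chosen
so the full suite and the benchmark script each complete in a couple of
minutes on a laptop core while keeping every Monte-Carlo margin wide
relative to its tolerance. The generator's `n_points` default is 25
for the same reason; the full 100-point line-map protocol is one
argument away.

## Known limitations

* Band quantification is height-above-floor of composite maxima;
  heavily overlapped weak bands carry a few-percent systematic bias and
  no deconvolution is attempted.
* The modified-polyfit background is biased low by about one
  smoothed-noise standard deviation; all group comparisons are
  ratiometric, so the shared bias largely cancels, but absolute band
  heights should not be over-interpreted.
* Bootstrap percentile CIs are reported without DeLong or BCa
  refinements.
* With LOOCV on small cohorts, permutation-null accuracies sit slightly
  below 0.5 when the features carry no class structure (the well-known
  leave-one-out pessimism); the permutation checks here use clustered
  feature matrices where the null is centered.
* t-SNE is the exact quadratic algorithm: fine for cohort-scale n,
  wrong tool past a few thousand samples.
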