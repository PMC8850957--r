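---
title: "Models and methods behind pymbms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pymbms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pymbms)
```

This vignette explains the models the package implements, the assumptions
they make, the tunable parameters that matter, and the design choices taken
where more than one reasonable implementation exists. It also describes
precisely what the synthetic-data generator does and does not emulate, so
that passing tests are read for what they show.

## The measurement model

py-MBMS flash-pyrolyzes a few milligrams of milled biomass and records the
pyrolyzate as a unit-mass spectrum over *m/z* 30–450 (421 channels). The
working assumption throughout is *approximate linearity*: the spectrum of a
sample is close to a non-negative mixture of component ion patterns
(cellulose-derived C6 pyrolyzates, hemicellulose-derived C5 pyrolyzates,
syringyl and guaiacyl lignin pyrolyzates, plus everything else), weighted by
component abundance. Linear chemometrics (PLS, PCA, ion sums) is sensible
exactly to the extent this holds; pyrolysis matrix effects, in which one
component alters another's product distribution, violate it and are
discussed under limitations.

Two normalizations remove the arbitrary absolute ion yield of a pyrolysis
run: TIC normalization (divide by the channel sum) and mean normalization
(divide by the channel mean). They differ only by the constant factor 421,
so every scale-invariant statistic (S/G, correlations, PCA directions) is
identical under either. The package defaults to TIC throughout because unit
total ion current makes channel intensities read directly as fractions of
pyrolyzate signal. Replicates are normalized *first* and averaged *second*,
so duplicate pyrolyses with unequal total yields contribute equally to the
sample mean; the reverse order would weight replicates by yield.

## Ion-set estimators

The diagnostic ion sets are the field-standard ones, shipped as a versioned
YAML config: the 17-ion lignin set (unlabeled members 120, 152, 180, 181
count toward lignin but toward neither monolignol class), the S and G
sublabel sets, and the reduced C5/C6 sugar sets. The sets overlap (*m/z*
57 and 73 are in both C5 and C6); each estimator is applied independently
and no de-duplication is attempted, matching how the sets are used in
practice.

Single-point (response-factor) estimation scales a sample's ion sum by a
single reference material: `estimate = known_value * sum_sample /
sum_standard`. It is exactly linear in the sample's ion sum and correct
only when the diagnostic ions capture a fixed proportion of the target
component's signal and nothing else — the reason it degrades on a single
species, where cross-component correlations dominate the signal (see the
generator section).

S/G is the ratio of the S-ion to the G-ion sums. It is invariant to any
global rescaling of a spectrum (asserted by test), so the normalization
choice is immaterial for it.

## PLS1 by NIPALS

`fit_pls1()` implements single-response NIPALS on mean-centered data. X is
*not* variance-scaled by default: all channels share the same intensity
units, and scaling would inflate near-empty channels into noise directions
(unit-variance scaling is available as an option). For PLS1 the NIPALS
weight step needs no iteration — `w = X'y/||X'y||` is exact per factor.
Factor counts follow the convention for woody-biomass sugar calibrations: 4
for glucose, 5 for xylose.

Numerical contracts, asserted after every fit: unit-norm weight vectors
(1e-10), mutually orthogonal score vectors (1e-8 relative), and the
training-mean spectrum predicting exactly the training-mean response. When
the factor count equals the rank of centered X, the composite coefficients
`b = W(P'W)^{-1}q` coincide with least squares; the test suite checks this
against `lm()` on random full-rank designs. Rank exhaustion before the
requested factor count raises a classed error carrying the achieved count
rather than silently returning fewer factors.

Cross-validation defaults to leave-one-out for up to 150 samples and 10
random segments (seeded) beyond that, reflecting the calibration sizes this
method is used at (~90–120 samples). RMSECV is reported per factor count;
out-of-fold predictions reuse the per-factor decomposition of a single
maximal fit per fold rather than refitting per factor.

The reported R² is the squared Pearson correlation of measured and
predicted values. This convention keeps R² and PCC mutually consistent
(PCC 0.86 pairs with R² 0.74) and is how calibration R² is conventionally
quoted for these instruments. A constant measured or predicted vector makes
the correlation undefined; the report then carries `pcc = 0` with an
explicit `degenerate` flag instead of propagating `NaN`.

## PCA and correlation profiles

PCA is the singular value decomposition of the mean-centered spectrum
matrix; explained-variance fractions are normalized squared singular
values, identical to the covariance eigenvalues (oracle-checked).
Loading signs are fixed so each component's largest-magnitude element is
positive, and the factor-1 PLS loading sign is fixed so the factor-1
y-loading is positive — both conventions exist so that "positively
associated with the trait" reads directly off a plot. Correlation profiles
report per-channel Pearson correlations with a trait; constant channels
(e.g. never-populated m/z bins) are flagged rather than returned as `NaN`.

## Spatial correction and heritability

Field trials carry smooth microspatial trends (soil, moisture, edge
effects) that inflate apparent environmental variance and can bias
heritability. `tps_correct()` fits a thin-plate-spline surface
`f(row, col)` with `mgcv::gam` (basis dimension 60 by default, knots
thinned to at most 200 because the spline solve is cubic in the knot
count), chooses smoothing by GCV, subtracts the fitted surface and re-adds
the grand mean. GCV means spatially unstructured data are essentially
untouched (the null-simulation test bounds the variance removed at under
10%), and the grand mean is never changed. Correction happens at the
*trait* level (predicted phenotype per ramet); correcting individual
spectral channels before prediction is a possible alternative with the
same machinery (per-ion heritability in `heritability_pipeline()` does
exactly that for chosen channels).

Broad-sense heritability uses the one-way random-effects genotype model on
ramet-level records: clonal replication identifies total genotypic
variance directly. Ramet-level (rather than genotype-mean) phenotypes are
required to identify σ²_E at all. The moments estimator uses the ANOVA
expectations with the unbalanced-design coefficient
`n0 = (N − Σnᵢ²/N)/(k − 1)`; negative moment estimates of σ²_G truncate to
zero, keeping H² in [0, 1]. REML (via `lme4`) is the cross-check; on
balanced designs with many genotypes the two agree within 0.02. Bootstrap
confidence intervals resample whole genotypes with replacement, relabeling
resampled copies so they stay distinct groups.

One deliberate simplification: the estimator treats genotype effects as
exchangeable even when the genotypes come from a factorial mating design.
The *simulator* builds genotypic values with full GCA/SCA family structure
(below), but the *estimator* targets total genotypic variance, which is
what broad-sense H² measures. Family structure correlates genotype
effects, which slightly deflates the between-genotype mean square: in the
default 49-family design the mean recovered H² sits ≈ 0.02 below the
simulated truth. This conservatism is a property of the one-way ANOVA on
structured pedigrees, not of the implementation, and the recovery tests
account for it inside their stated tolerance.

Per-batch instrument drift can optionally be emulated/removed by treating
batch as part of the spatial surface (runs are loaded in field order); no
separate instrumental-correction formula is implemented because none is
standard.

## The synthetic-data generator

The generator exists so every estimator in the package can be exercised
against known truth. It emulates:

* **Compositions.** (glucose, xylose, lignin) from a multivariate normal
  with means 48/17/24.6 DW%, SDs 2.5/1.8/1.0, correlations −0.76
  (glc–xyl), +0.48 (xyl–lig), −0.61 (glc–lig), rejection-resampled into
  the ranges 43–57 and 11–20 DW% (rejection preserves correlations better
  than clipping; an acceptance rate below 1% is refused as infeasible).
  S/G is drawn independently at mean 2.1, SD 0.1. A user-edited
  correlation matrix that loses positive semi-definiteness is repaired by
  eigenvalue clipping, with a warning.
* **Spectra.** Linear mixtures of five basis spectra (C6, C5, S-lignin,
  G-lignin, background). Each component basis puts 80% of its mass on its
  annotated diagnostic ions and 20% on a shared low-mass background
  profile (m/z 30–56). The remainder of dry weight (100 − glc − xyl −
  lig) contributes background only, so total pyrolyzate mass is constant
  and TIC normalization is exactly linear in the abundances. The glucose
  allocation deliberately places much of its mass on m/z 69, 70, 84 —
  sugar pyrolyzates *outside* the reduced C6 set — and xylose on 103/114,
  with the glucose contribution dominating the shared channels 57/73.
  This reproduces the qualitative failure mode of reduced-ion single-point
  estimation within one species: the single-point sums remain correlated
  with the target but are confounded by the anti-correlated co-varying
  components, so PLS beats them decisively (the paired comparison is a
  test). The S/G intensity split of the lignin mass is solved per sample
  so the noiseless spectrum's S/G ion ratio equals the latent S/G exactly,
  i.e. the generator adopts the operational definition of the ratio.
* **Noise.** Per-channel multiplicative lognormal noise with sigma 0.05
  (typical duplicate reproducibility for summed-ion pyrolysis data), two
  replicates per sample, and Gaussian reference-measurement error of 1.0
  DW% (0.01 mg/mg) on the NMR-style sugar values.
* **Pedigree trials.** A full 7 × 7 factorial (49 families, 10 progeny
  each, so 490 genotypes) with 5 clonal ramets per genotype at random
  distinct positions of a 50 × 50 grid. Genotypic values are
  GCA_mother + GCA_father + SCA + within-family segregation with variance
  fractions 0.2/0.2/0.1/0.5 of σ²_G (additive parental effects dominating
  among family components, half of the genotypic variance segregating
  within families). Trait-level splits are σ²_G = 0.32/σ²_E = 0.68 for the
  glucose trait and 0.34/0.66 for xylose. The spatial surface is a random
  low-frequency cosine field (length scale 15 grid units) rescaled to SD
  0.3 on the standardized trait scale.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: pyrolysis matrix effects (nonlinear component
interactions), minor sugars, ash and extractives, instrument drift over
runs, non-Gaussian reference errors, spatially clustered planting of
relatives, and genotype-by-environment interaction. Recovery results on
synthetic data are a check of the estimators under the stated model, not a
validation of py-MBMS chemistry.

## Problem sizes and numerical choices

The shipped analyses and tests use: 93-sample calibrations with validation
on a further ~400 synthetic accessions (mirroring the calibration design
this method uses in production); 200 simulated trials for heritability
recovery and 50 paired trials for the spatial-correction comparison, sizes
at which the Monte Carlo error of a mean H² is ≈ 0.002–0.004 and
comfortably below the effects being measured; a 60-knot GCV spline for a
2,450-tree trial. Key tolerances: unit weight norms at 1e-10, score
orthogonality at 1e-8 relative, PCA/least-squares oracle agreement at
1e-8/1e-6, TIC/mean normalization at 1e-10, grand-mean preservation at
1e-8. Text round-trips write numerics with 17 significant digits and parse
with correctly rounded `strtod`, so write→read is exact. All stochastic
code paths take explicit integer seeds and restore RNG state, so every
pipeline output is bitwise reproducible from (seed, config); dataset
sidecars record seed, configs and a config hash.

## Known limitations

* Single-response PLS only; no PLS2, no sparse/variable-selection PLS.
* The linear mixture model understates real spectral nonlinearity; treat
  synthetic recovery rates as upper bounds.
* Heritability assumes a single site and no G×E; the one-way model on
  factorial pedigrees is slightly conservative, as quantified above.
* No vendor raw-file or mzML ingestion: spectra enter as delimited text
  with unit-mass integer channels (fractional m/z is rejected, not
  rounded).
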