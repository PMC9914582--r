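---
title: "Methods: volatilome-based origin authentication of citrus honey"
author: "honeyvola"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volatilome-based origin authentication of citrus honey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeyvola)
```

## The problem

Unifloral citrus honey commands a price premium, and its geographical
origin is hard to certify: pollen counts in citrus honey are notoriously
under-representative, so chemical profiling of the headspace volatilome
(HS-SPME/GC–MS) is the practical route. This package implements a complete
analysis chain from raw per-run peak tables to an origin-classification
model and a simple authentication ratio:

1. **Semi-quantification** of peak areas against a benzophenone internal
   standard (IS), assuming unit response factor:
   \(C_\mathrm{analyte} = E_\mathrm{analyte} / E_\mathrm{IS} \times C_\mathrm{IS}\),
   with \(C_\mathrm{IS} = 1\) mg/kg. These are *semi*-quantitative values:
   comparable across samples, not calibrated absolute amounts.
2. **Retention indexing** against an n-alkane ladder (C8–C20) using the
   linear van den Dool & Kratz convention appropriate to a
   temperature-programmed run.
3. **Screening**: per-compound one-way ANOVA across origin groups, a
   one-way MANOVA (Wilks' lambda via Rao's F, Pillai's trace via its
   standard F approximation), observed power, and noncentral-F sample-size
   analysis; compounds with p < 0.05 go forward.
4. **Canonical discriminant analysis** with a collinearity tolerance
   screen, eigenvalue / canonical-correlation chain, Bartlett chi-square
   tests, structure-matrix "discrimination power", and original plus
   leave-one-out classification; Kaiser-criterion PCA for unsupervised
   comparison.
5. **The marker-ratio origin index**
   \(R = \sum_{m \in \mathrm{markers}} C_m \;/\; \mathrm{TSQVC}\),
   where TSQVC is the total semi-quantitative volatile content (the sum of
   all compound concentrations) and the markers are the seven compounds
   with the highest discrimination power: lilac aldehyde D, dill ether,
   2-methylbutanal, heptane, benzaldehyde,
   α,4-dimethyl-3-cyclohexene-1-acetaldehyde, and herboxide (isomer II).

The packaged reference table (`load_fixture()`) holds the published group
summary: 41 volatile compounds in 8 chemical classes, group means ± SD in
mg/kg for citrus honey from Egypt (n = 7), Morocco (n = 6), Greece
(n = 17) and Spain (n = 8) and other nectar honeys from Greece (n = 6),
together with retention times/indices and per-compound F significance
stars. "nd" cells are stored as mean 0, sd 0 — the source never
distinguishes below-detection from absent, and this encoding makes the
TSQVC and R sums well defined.

```{r}
tab <- load_fixture()
tab
kn_index(tab)
```

The R row reproduces the published 0.35 (Egypt), 0.29 (Morocco), 0.04
(Greece) and 0.08 (nectar) at two decimals. **Spain is deliberately
flagged, not matched**: summing the seven published Spanish marker means
(0.314 mg/kg) over the Spanish TSQVC (0.874 mg/kg) gives 0.36, while the
published table prints 0.27. The published value is recoverable only if
one marker (herboxide II) is dropped, and rather than guess which subset
produced it, `reproduce_table1_report()` reports the equation's value and
flags the discrepancy.

```{r}
reproduce_table1_report()
```

A related bookkeeping discrepancy in the source — "33 + 9" and "the 42
volatile compounds" alongside a 41-row table — is resolved in favour of
the table: the fixture has exactly 41 rows.

## The synthetic-data generator

The study's per-sample concentration matrix was never published, so the
generator (`simulate_samples()`) draws it from the group summary: compound
c in group g is Normal(mean[c, g], sd[c, g]) with negatives clamped to
zero (*censored* normal, the default). Censoring is the honest choice
here: many tabulated SDs equal or exceed their means (e.g. furfural in
Morocco, 0.14 ± 0.22), so an unbounded normal is infeasible as a
concentration and a truncated normal would shift the mean upward by a
compound-dependent amount. Censoring also shifts the mean (upward, by the
clamped mass); both alternatives are available (`noise_model =
"truncated-normal"`, `"normal"`), and convergence tests use the uncensored
`"normal"` mode, whose sample means are unbiased for the tabulated means.

Other generator choices, fixed once:

* **Defaults are the study design**: group sizes (7, 6, 17, 8, 6), two
  instrument runs per sample with 5% run-to-run CV, IS at 1 mg/kg. The
  duplicate CV has no published value; 5% is a typical HS-SPME
  repeatability figure and the source reports "good yield (over 95%)" for
  the IS across replicates.
* **Compounds are independent** within groups (the source gives no
  covariances); a uniform Gaussian-copula correlation hook exists for
  robustness experiments only.
* **Per-group seed streams** are derived deterministically from the master
  seed, so enlarging one group does not reshuffle another.
* **Duplicates are averaged** arithmetically downstream
  (`average_duplicates()`); the source says samples were run in duplicate
  (88 runs for 44 samples) but not how runs were combined — averaging is
  an assumption, stated here.
* The **alkane ladder** pins octane and nonane at their measured 12.26 and
  14.94 min and extends the spacing linearly. The published indices above
  C9 are *not* all consistent with one linear ladder (undecane prints
  1099), so the ladder is always an explicit input; the packaged one
  reproduces the anchor arithmetic (furfural: RT 13.25 → RI 837).

What passing tests on synthetic data do and do not show: the generator
reproduces the first two moments and the zero pattern of the published
table, so tests demonstrate the *pipeline's* correctness and the
recoverability of table-level quantities, not instrument-level realism —
no peak shapes, co-elution, drift, or between-compound correlation.

## Statistical conventions

* **ANOVA / filter**: fixed-effects one-way ANOVA per compound
  (`stats::lm`); stars at 0.05/0.01/0.001. No multiplicity correction is
  applied to the p < 0.05 filter because the published per-compound F
  table uses none; a Bonferroni-minded user can simply pass a smaller
  `alpha`.
* **MANOVA** is computed from the eigenvalues of \(W^{-1}B\) (within- and
  between-group scatter), giving Wilks \(\Lambda = \prod 1/(1+\lambda_i)\)
  and Pillai \(V = \sum \lambda_i/(1+\lambda_i)\); both match
  `stats::manova`'s determinant/trace route to 1e-10 in the tests.
* **Observed power** uses the plug-in noncentrality \(\hat\lambda = F
  \cdot df_1\) — the convention of the software the published "observed
  power = 1.000" values came from. It is biased upward; it is reported
  because that is what the field's tables show.
* **Sample size** (`required_sample_size()`) takes the root-mean-square
  standardized effect (RMSSE) and grows total n (respecting allocation
  weights, every group ≥ 2) until noncentral-F power reaches the target.
  The published RMSSE of 535.413 is treated as an input example only; its
  derivation is not recoverable, and the published allocation (2+2+3+2
  against "at least n = 10") does not self-consistently sum, so the
  function reports its own computed minimum.
* **Tolerance screen**: tolerance = 1 − R² of a predictor regressed on the
  other kept predictors after within-group centering; iterative removal,
  lowest first, at the conventional 0.001 threshold. This is what keeps
  the pooled scatter invertible with ~30–40 candidate compounds and only
  39 within-group degrees of freedom.
* **Canonical LDA**: coefficients scaled to unit pooled within-group score
  variance; Bartlett chain
  \(\chi^2 = -(N - 1 - (p+g)/2)\ln\Lambda_k\) with
  \(df = (p-k+1)(g-k)\); equal priors by default (proportional by flag);
  classification by Mahalanobis distance in the full discriminant space,
  which is Euclidean there because canonical scores have identity pooled
  within-group covariance. Each function (and each principal component)
  is oriented so its largest-|loading| entry is positive, making output
  signs deterministic.
* **Leave-one-out** refits the model per fold with the *same* variable
  set (the published analysis filtered once, then cross-validated — a
  known optimism source, kept for comparability). Folds whose reduced
  scatter is singular, or that would leave a group with fewer than two
  members, are flagged and the case counted unclassifiable in its own
  confusion-matrix column, so row sums always equal group sizes; such
  cases count against the overall rate.
* **Numerical route**: \(W^{-1}B\) is reduced to a symmetric eigenproblem
  through the spectral inverse square root of W, which is exact for
  positive-definite W and degrades gracefully near singularity; W is
  declared singular when its smallest eigenvalue falls below
  \(p \cdot \varepsilon \cdot \lambda_{max}\). No ridge or pseudo-inverse
  is ever applied silently.
* **Index letters**: the published letter codes come from an
  under-specified "one-sample t-test"; here groups are compared pairwise
  (Welch t) on per-sample R at p < 0.001 and letters assigned greedily in
  descending mean order — the published pattern (five distinct letters)
  is reproduced on clearly separated distributions.
* **Rounding**: half-up, applied to *reported* values only (RI to
  integer, R to two decimals); comparisons use full precision.

## Problem sizes and determinism

The test suite and the acceptance script run the whole pipeline at the
study's own scale (44 samples, 41 compounds, 44 leave-one-out refits) and
use n = 2000 per group for moment-recovery checks — sizes chosen so the
law-of-large-numbers bands (±3 SE) are tight enough to be meaningful while
the full suite stays in the tens of seconds. All randomness flows from
explicit seeds; `run_pipeline()` writes every output file with its MD5
into a manifest, and identical configurations produce byte-identical
outputs.

## Known limitations

* The published per-sample matrix is unavailable, so the published LDA
  eigenvalues (195.319, …), centroids, PCA loadings and the 97.7%/77.3%
  classification rates are *structural* references only (counts of
  functions, orderings); they cannot be and are not reproduced
  numerically.
* The censored-normal generator biases group means upward for compounds
  whose SD is large relative to the mean; convergence claims therefore
  use the uncensored mode.
* The index's letter test and the Spanish R value carry the source's own
  ambiguities, which are surfaced rather than resolved.
* The index is a descriptive authentication aid, not a validated
  diagnostic test.
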