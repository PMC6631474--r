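---
title: "Methods: characterizing bulk phosphatidylcholine measures with side-chain resolving data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing bulk phosphatidylcholine measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccomp)
```

## The measurement model

Two targeted lipidomics platforms report phosphatidylcholine (PC)
concentrations in μmol/L at different structural resolutions. A kit-style
assay quantifies *lipid species level* sums `PC aa Cx:y` / `PC ae Cx:y`:
everything that falls on the same precursor mass as the diacyl species
PC x:y (respectively the acyl-alkyl species PC O-x:y). A side-chain
resolving platform quantifies individual *fatty acid level* species
`PC x1:y1_x2:y2` without sn-position assignment. A bulk sum measure
i therefore decomposes as

conc(PC_i) ≈ Σ_j conc(PC_j) + R,

where j runs over the isobaric fatty-acid-level species and R aggregates
everything isobaric that the resolving platform did not measure. The
package's central quantity is the per-sample ratio

q_ijst = conc(PC_j; fatty acid level)_st / conc(PC_i; lipid species level)_st

for subject s and timepoint t; its mean over samples estimates the
characteristic proportion of constituent j in sum i. This estimator assumes
(i) both platforms report on a common μmol/L scale, (ii) ratios are roughly
stable across samples so a mean is meaningful, and (iii) platform-specific
extraction/ionization efficiencies act multiplicatively — which is why
estimated proportions can exceed 1 and why the sum of proportions over
measured constituents is itself a diagnostic.

## Isobar algebra

Which species fall under one sum is pure arithmetic on sum formulas. With
the monoisotopic weights w(H) = 1.007825, w(C) = 12, w(13C) = 13.003355,
w(O) = 15.994915, w(N) = 14.003074 Da (and w(P) = 30.973762 Da, the standard
monoisotopic value, required to reproduce the printed nominal masses), a
diacyl PC x:y has formula C(x+8) H(2x−2y+16) N O8 P, an ether PC gains 2 H
and loses one O, and an SM x:y is C(x+5) H(2x−2y+13) N2 O6 P. These base
formulas are fixed by glycerophosphocholine/sphingomyelin chemistry and are
validated in the test suite against the printed nominal (floor of
monoisotopic) masses of all 38 reference sums. The isobaric neighbours of a
diacyl anchor PC x:y are PC x+1:y+7 (−0.0939 Da), PC O-x+1:y (+0.036385 Da),
PC O-x+2:y+7 (−0.057515 Da) and the sphingomyelin first-isotope peak
[13C1]SM x+4:y (+0.055724 Da); the ether anchor has the mirror-image series.
The SM peak is included in a sum's catalog only when the corresponding SM is
*not* quantified by the kit, because kit software isotope-corrects the sums
for SMs it quantifies.

The catalog of a sum enumerates, for every member of its isobaric series,
all chain splits {(x1,y1),(x2,y2)} with x1+x2 = x and y1+y2 = y.
Enumeration bounds are configurable (`enumeration_constraints()`); the
defaults are deliberately permissive — chains of 2 to x−2 carbons, per-chain
double bonds up to the structural limit floor((c−1)/2) — because the point
of the qualitative catalog is completeness (odd chains and extreme
desaturation included). Published per-sum counts of theoretically possible
isobars depend on unpublished enumeration bounds, so exact catalog sizes are
not asserted anywhere; with the default bounds typical kit sums yield
catalogs in the low hundreds. Ether splits are enumerated with exactly one
alkyl chain, which participates in the same carbon/double-bond bounds as
acyl chains; assignments differing only in which chain is alkyl-bound are
distinct molecules.

## Nomenclature conventions

Chains are stored as unordered pairs and always emitted in a canonical
order: the alkyl chain first, otherwise ascending by (carbons, double
bonds). This gives every molecule a single textual identity, so analyte
matching is done on canonical labels; `load_reference()` keeps the verbatim
published label in a `constituent_printed` column while matching on the
canonical form. The parser accepts typographic hyphen variants and is
whitespace-tolerant. One deliberate restriction: a bare species label whose
carbon total lies in the single-fatty-acid range (x ≤ 22, e.g. "PC 16:0")
is rejected as an incomplete fatty-acid-level name rather than silently
parsed as a 16-carbon species — in these assays no species-level PC is that
small, and the typo is common.

## Quality control and estimation choices

* **Reference-sample QC** (`qc_filter()`): analytes with a coefficient of
  variation above 25% across reference-plasma replicates are excluded;
  analytes with CV above 20% *and* a significant run-day association are
  also excluded. The run-day test is a two-sided Spearman rank correlation
  at α = 0.05 — the source procedure names only "significant correlation to
  the run day", and a rank test is robust to the shape of the drift.
* **Coverage** (`coverage_filter()`): an analyte must be quantified in at
  least 25% of samples; the threshold is inclusive (≥).
* **Ratios**: samples missing either platform value are dropped pairwise; a
  zero denominator is treated as missing rather than producing an infinite
  ratio. Missing values are never imputed at this stage.
* **Summaries**: the 5%/95% interval is the empirical percentile with
  linear interpolation between order statistics (`quantile(type = 7)`);
  only "lowest/largest 5%" is prescribed, and the interpolating estimator
  is R's default and continuous in the data. Composition categories use
  strict thresholds (II iff mean > 0.8, I iff mean > 0.2). The main
  constituent is the largest mean; exact ties break by canonical label
  order so reports are deterministic. By default all available samples
  enter the estimate; cohort subsets (e.g. "males under 40" for
  replication) are expressed as sample filters, not hard-coded.

## Statistical testing

* **Variation**: `variation_sds()` averages, over (sum, constituent,
  subject), the SD of q across the baseline/intervention timepoints of the
  lipid-related challenges (intra-individual variation), and over
  (sum, constituent, timepoint) the SD across subjects (inter-individual
  variation). Cells with fewer than two observations are skipped and
  counted.
* **Challenge response**: two-sided Wilcoxon signed-rank on subject-paired
  baseline vs intervention ratios. Zero differences are dropped (the common
  convention; the source is silent), and the all-ties case is reported as
  p = 1 — "no evidence of a shift" — rather than undefined.
* **Between subjects**: a Shapiro–Wilk test on within-subject-centred
  residuals at α = 0.05 gates one-way ANOVA (normality not rejected)
  versus Kruskal–Wallis. The gate level is a package choice; the gate
  itself is prescribed.
* **Replication across cohorts**: per sum, agreement of the main
  constituent (reported where both cohorts measure ≥ 2 constituents) and a
  Kruskal–Wallis test on the reference cohort's main-constituent ratios
  between cohorts, at the Bonferroni level α = 0.05 / n_tests with n_tests
  recomputed from the data as the number of sums testable in both cohorts
  (not hard-coded to any published count). Whether to pool all constituents
  per sum or test the main constituent only is genuinely open; the package
  tests the main constituent, which is the replication claim actually made,
  and exposes per-pair tests for the rest.

## Concordance

The through-origin model conc(sum) = b · Σ conc(measured constituents) is
fitted by closed-form least squares. R² is reported, by default, as the
squared Pearson correlation between observed and fitted values (the centred
definition): the uncentred 1 − RSS/Σy² variant of no-intercept fits is
systematically inflated for positive concentration data and cannot produce
the near-zero explained variances that occur when a constituent's
proportion is large but unstable. The uncentred variant remains available
behind a flag. Bland–Altman statistics report per-sample differences
d = conc(sum) − Σ conc(constituents) against per-sample means; the mean
difference is classified against 1× and 2× the SD of the species-level
measure itself (the wording of the source analysis), with the conventional
mean ± 1.96 · SD(d) limits of agreement additionally reported but not used
for classification. Both analyses are complete-case per sum: a sample
missing any mapped constituent is excluded so the cumulated sum is never
partial.

## The packaged reference table

`load_reference()` ships the published composition of 38 PC sums
(25 diacyl-labelled, 13 ether-labelled) by 69 measured fatty-acid-level
constituents, with 4-decimal proportions stored verbatim. Validation on
load checks the schema, the 38/69 counts, percentile ordering, category
consistency, agreement of each printed nominal mass with the mass computed
from the species label, and per-sum consistency of the sum of proportions
with its members. One published row (PC aa C36:3) has a sum of proportions
that differs from the sum of its printed members by 0.001 — slightly more
than 4-decimal rounding can explain — so the consistency tolerance is 2e-3
and the printed values are kept untouched. The ether sum labelled
PC ae C40:1 has a diacyl constituent (PC 18:2_22:6, isobaric via the
x:y+7 rule) which is stored under its diacyl identity, with the sum label
kept as printed. Imputation multiplies each sum concentration by the
reference proportions, propagates missing values, flags its output as
imputed, and is exactly linear — re-estimating proportions on imputed data
returns the table (a test asserts this to machine precision). Compositions
estimated in one cohort need not transfer quantitatively to another
(constituent proportions can differ significantly between populations even
when the main constituent agrees), so `impute_constituents()` accepts any
table with the reference schema; only the published table is shipped.

## What the synthetic generator does and does not emulate

`simulate_paired_cohort()` draws latent per-sample sum concentrations
log-normally with additive subject and timepoint effects on the log scale
(defaults: 4 subjects × 56 timepoints — the few-subjects/many-timepoints
design of multi-challenge studies — with sd_between = 0.3 and
sd_within = 0.2, typical magnitudes for plasma lipid log-concentrations),
splits them by the configured true proportions with a remainder fraction
for unmeasured constituents, applies per-platform efficiency factors, and
observes each value with mean-1 multiplicative log-normal noise at a
configurable CV (default 10% per platform, ordinary targeted-MS precision).
An optional intervention shift exercises the paired tests; missingness is
missing-completely-at-random. The expected estimable ratio is
E[q_ij] = (eff_j / eff_i) · p_ij · exp(σ_i²) with σ_i the species-platform
log-noise SD — the last factor is E[1/noise] of the denominator and is what
a ratio-of-noisy-measurements estimator actually converges to.

What this does *not* model: correlated noise between analytes, run-day
drift and batch structure, censoring at the limit of detection
(missingness here is independent of concentration), challenge-specific
kinetics beyond a step shift, and any structural difference between
diacyl and ether species. Passing tests on these cohorts therefore
demonstrate the estimators' correctness under the stated model, not
robustness to every artifact of real platform data.

## Problem sizes and numerical checks

The validation suite runs at deliberately modest sizes: enumeration is
cross-checked against a brute-force double loop on 100 random
(x, y, bounds) instances; proportion recovery is checked at 200 samples and
10% CV (tolerance ±0.02 on q, several multiples of the standard error);
convergence is probed at 50/200/1000 samples; the null family-wise error of
the Bonferroni replication stage is estimated from 200 simulated cohort
pairs (bounded by the nominal 0.05 plus binomial Monte-Carlo error); and
noiseless cohorts verify the algebraic identities (exact proportion
recovery, R² = 1, b = 1/(1 − remainder), mean Bland–Altman difference =
remainder × mean concentration). `scripts/acceptance.R` recomputes all of
these plus the reference-table statistics from a single command-line seed.

## Known limitations

Only PC and SM chemistry is modelled; lysoPCs and other phospholipid
classes are out of scope, as are sn-positions, double-bond positions and
stereochemistry (a "fatty-acid-level" species is still a class of
molecules). The remainder R is only bounded indirectly through concordance;
no attempt is made to estimate unmeasured constituent abundances or to
deconvolve platform efficiencies from true proportions — with one platform
per resolution those are not separately identifiable.
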