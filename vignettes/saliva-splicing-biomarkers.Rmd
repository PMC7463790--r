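---
title: "Quantifying splicing-factor panels in saliva cell-free RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing-factor panels in saliva cell-free RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaSF)
```

## The measurement model

Cell-free RNA in saliva is scarce (well under a nanogram per sample), so the
panel is read out by real-time PCR, where abundance is encoded in the cycle
threshold Ct: each missing cycle is a two-fold difference in template. All
quantities in this package therefore live on one of two linked scales:

* **ΔCt (cycles):** `Ct(target) − Ct(PPIA)` within the same sample. PPIA is
  the endogenous control — abundant in saliva and stable across samples —
  so ΔCt cancels differences in RNA input.
* **Relative expression (dimensionless):** `2^−ΔCt`, assuming perfect
  doubling per cycle. No efficiency calibration is modelled; if primer
  efficiencies below 2 matter for an assay, ΔCt values can be transformed
  externally before the cohort stages.

Each (sample, target) is measured in triplicate; `aggregate_replicates()`
averages the *detected* wells on the Ct scale (standard comparative-Ct
practice) and records how many wells were detected. Undetected wells are
`NA`, never a sentinel cycle such as 40: sentinels silently bias means,
whereas explicit missingness propagates into the dropout policy below.

The cohort endpoint is the composite score

$$\Sigma\Delta \;=\; \sum_{g \in \text{panel}} 2^{-\Delta Ct_g},$$

the summed relative expression over the seven targets. Summing on the
expression scale (rather than summing ΔCt values) weights abundant targets
more and matches how the per-sample panel levels are plotted and compared;
the ΔCt-sum alternative remains available via
`quantify_profiles(score = "sum_delta_ct")`. By default the score is
**strict**: a sample with any undetected panel target gets `NA` rather than
a silently smaller sum. `score_policy = "rescale"` instead scales the
partial sum by `7 / n_detected`, a reasonable choice when dropout is rare
and random; it is not the default because dropout in qPCR is
abundance-dependent, so rescaling biases low-expression samples upward.

No baseline sample is subtracted anywhere: the score is a sum of
within-sample normalized levels, and no reference-sample convention is
defined for this assay.

## The synthetic-data generator

Real saliva measurements for this panel are not redistributable, so the
package ships a generator whose *structure* matches what the analyses
assume, and all statistical guarantees are demonstrated on it. For subject
$i$ with group $x_i$, day $d$, target $g$, replicate $r$:

$$Ct_{g,i,d,r} - Ct_{\text{PPIA}} = \mu_g + \beta_g \,
  1[x_i = \text{patient}] + u_{g,i} + e_{g,i,d} + \varepsilon_r,$$

with $u \sim N(0, \sigma_b^2)$ per (subject, target), $e \sim N(0,
\sigma_w^2)$ per day, $\varepsilon \sim N(0, \sigma_r^2)$ per well. The
normalizer has its own wells and technical noise but no disease effect and
no subject effect — treating it as the stable control it is chosen to be.

Defaults (all in cycles) and why:

| parameter | default | rationale |
|---|---|---|
| `mu_g` | 2.5–6 by target | targets sit 6- to 64-fold below PPIA, matching their relative read depths in pooled saliva |
| `sigma_between` | 0.8 | subjects differ by roughly ±2-fold (1 cycle ≈ 2×), the "fingerprint" magnitude |
| `sigma_within` | 0.4 | day-to-day spread clearly smaller than between-subject spread |
| `sigma_replicate` | 0.15 | typical well-to-well qPCR noise |
| `beta_g` | +0.3 (HNRNPA2B1), −0.4…−0.8 (others) | encodes the direction pattern: HNRNPA2B1 slightly down in patients, the other six up |
| ages | healthy 40 ± 12, patient 53 ± 13 years | the two cohorts' reported age structure |

The disease effects are a **calibration choice, not an empirical claim**: no
numeric effect sizes exist for this assay, so they were fixed once such that
the composite comparison at the study's sample sizes (36 vs 31) rejects at
α = 0.05 with high power (measured ≈ 0.93, and ≈ 0.77 at α = 0.01) while
individual targets remain only partly significant — the qualitative regime
the analyses are meant to exercise. The generator emulates the hierarchy,
the signs and the noise scales of real data; it does *not* emulate
non-normal heavy tails, abundance-dependent dropout, batch effects or
age-expression correlation. Passing tests therefore certify the statistical
machinery (calibration, recovery, exactness), not field performance on real
saliva.

The count-table generator draws per-gene expected abundance from a Pareto
law (exponent 1.3) with Poisson observation noise — a deliberately simple
long-tail model reproducing the qualitative shape of a pooled cell-free
library: most genes at a handful of reads, a thin abundant tail. Randomness
everywhere flows from a single seed per dataset; callers derive per-stage
seeds by fixed offsets (as `run_pipeline()` does), and every generator
restores the caller's RNG state.

## Statistical procedures and their design choices

**Two-group comparison.** The default test permutes group labels and uses
the absolute difference of group means, because it is assumption-light and
exact by construction; relative-expression values are right-skewed, so
t-distribution tail areas are not relied on (Welch's t is available for
comparison via `method = "welch"`). When the number of label assignments is
at most 10⁴ the test enumerates all of them and returns the exact tail
proportion; otherwise it draws B random shuffles and reports
`(b + 1)/(B + 1)`, which is never zero and makes the test slightly
conservative — visible in the null calibration, which sits at nominal level
within binomial error.

**Sub-group permutation.** The treatment analysis compares a sub-group of
patients to the remainder using the absolute difference of composite-score
means, with the null built from random same-size sub-groups (B = 1000 by
default, matching the study design; exhaustive below 10⁵ combinations). The
statistic is two-sided on the composite score: treatments were not
pre-registered with a direction, and the composite is the endpoint the rest
of the analysis is built on. Treatment predicates are case-insensitive
substring matches because the clinical table records treatments as free
text ("Avastin and Chemotherapy (cisplatin/gemzar)").

**Reproducibility.** CVs are computed on the relative-expression scale
(that is the scale results are reported on; a Ct-scale CV would mix an
arbitrary baseline into the denominator). No hard CV threshold exists for
"reproducible"; a conventional ≤ 0.25 flag is reported without failing
anything. The between- vs within-subject question is answered by a
variance-ratio statistic `var(between-series) / var(within-series)` with a
permutation reference (pool both series, re-split at the original sizes),
one-sided for between > within; an F-test variant exists but is not the
default for the same non-normality reason as above. Both series identically
constant is reported as uninformative with p = 1.

**Variance components.** `estimate_variance_components()` is the one-way
method-of-moments (ANOVA) estimator — within-subject mean square, and
`(MS_between − MS_within)/n₀` for the between component, truncated at zero.
At this design size (hundreds of subjects, a few days) it recovers the
generator's σ_b = 2, σ_w = 0.3 within a few percent; REML machinery would
add dependencies without changing the answer materially.

**Age stratification.** The young/old cut defaults to the pooled median age
at collection — it balances the strata to within one sample and needs no
external convention — and is overridable (`cut = 50` etc.). Samples with
missing age are excluded with a message.

**Multiple testing.** Across the seven per-target tests, Holm-adjusted
p-values are reported next to the raw ones; the composite test is a single
pre-specified endpoint and is not folded into that family.

## Count filtering

The RNA-seq stages consume a ready count table (counting pipelines upstream
are out of scope) and apply, in this order: biotype exclusion →
low-count filter → presence call.

* Biotype exclusion drops the listed non-coding and artifact classes;
  genes *missing* a biotype are kept with a warning, since exclusion is
  defined by listed classes only.
* The low-count filter removes genes with summed counts below 3 across
  samples; the boundary (exactly 3) is kept.
* Presence needs ≥ 49 reads in the pooled column; the boundary read count
  of exactly 49 counts as present (`inclusive = FALSE` gives the strict
  `>` convention). Presence is called last, on the already-filtered table:
  the two earlier filters delete rows a presence call should never see.
* Histograms bin genes into `[0, e1), [e1, e2), …, [e_k, ∞)`, so mass is
  conserved for any edge choice.

All filters are idempotent, and the present set shrinks monotonically in
the threshold; both properties are tested.

## Clinical metadata

The bundled 31-patient characteristics table is parsed with explicit
normalization: check-mark/cross symbols become logical IDC/ILC flags,
plus/minus becomes HER2 status, blank cells become missing values, and a
malformed cell fails with its row number. One record is marked as both
ductal and lobular carcinoma in the source table and is transcribed as-is.
A patient counts as **metastatic** when her site field names at least one
site — non-blank and not "Local disease" (case-insensitive). Blank site
cells cannot be distinguished from "no metastasis" in the source and are
counted non-metastatic; under that reading 22/31 ≈ 71% of the cohort is
metastatic. Treatment sub-group sizes are substring counts over the
free-text field with six canonical labels (avastin, palbocyclib, hormonal,
chemotherapy, HER2, afinitor).

## Numerical conventions and degenerate inputs

* Permutation p-values: exact tail proportion on enumerable spaces (never
  zero, since the observed assignment is included), `(b+1)/(B+1)` for
  Monte-Carlo. Tail comparisons use a 10⁻¹² tolerance so that
  floating-point ties count as ties.
* Zero detected replicates → target undetected; undetected normalizer →
  sample dropped with a warning (nothing on it is quantifiable).
* CV with n < 2 or non-positive mean → flagged undefined, not an error.
* All-equal inputs to any permutation test → p = 1.
* Negative between-subject variance estimates truncate to zero.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run on sizes chosen to make the
statistical assertions sharp at desk scale: 500 null cohorts of 15 + 15
samples (B = 200) for size calibration, 200 subjects × 5 days for
variance-component recovery, 10 + 10 samples for the reproducibility
designs, 36 + 31 for the cohort comparisons, and 20 000-gene count tables.

## Known limitations

* The generator's normality and independence assumptions are idealized;
  real cell-free RNA data show heavier tails and correlated dropout.
* The composite score has no dropout-robust default beyond strict/rescale.
* Single-normalizer design: no geometric-mean multi-control scheme.
* The permutation variance-ratio test has limited power at ten-vs-ten
  sample sizes; it answers "is between > within detectable", not "by how
  much" (use the component estimates for that).
* No classifier is built: the group-level difference does not imply a
  single sample can be classified, and the package deliberately stops at
  group inference.
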