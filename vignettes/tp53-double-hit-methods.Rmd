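---
title: "Calling clonal and sub-clonal TP53 lesions and double-hit status in myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling clonal and sub-clonal TP53 lesions and double-hit status in myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53hits)
library(dplyr)
```

## The problem

TP53 can be inactivated in multiple myeloma by deletion of 17p, by
somatic mutation, or by both. Conventional FISH misses sub-clonal
deletions and ignores mutations entirely, so patients whose TP53 is
fully inactivated — the *double-hit* group: homozygous deletion, or
deletion on one allele plus a pathogenic mutation on the other — are
under-recognized. `tp53hits` implements a complete, testable pipeline
for this assessment from SNP-array segment profiles and targeted
sequencing calls: copy-number and cancer-cell-fraction (CCF) estimation,
multi-caller variant consensus and pathogenicity filtering, per-patient
allelic classification, derivation of the prognostic deletion-call CCF
cutoff by time-dependent ROC, survival modelling, and longitudinal
comparison of diagnosis and relapse.

## Copy number and deletion CCF

The observed mean log2 ratio $L$ of a segment mixes tumor and normal
cells. With tumor purity $\rho$ and tumor copy number $n_T$,

$$2 \cdot 2^{L} = \rho\, n_T + 2 (1 - \rho)
  \quad\Longleftrightarrow\quad
  n_T = \frac{2 \cdot 2^{L} - 2(1-\rho)}{\rho},$$

clamped below at zero. Under a hemizygous single-copy-loss model the
fraction of tumor cells carrying the deletion is

$$\mathrm{CCF} = 100 \cdot \min(\max(2 - n_T,\, 0),\, 1)\ \%.$$

Copy-number classes use fixed thresholds: homozygous loss at or below
0.6, single loss below 1.9, neutral through 2.1, single gain below 3.4,
multi-gain at or above. Values exactly on 1.9/2.1 are neutral, exactly
0.6 homozygous, exactly 3.4 multi-gain; the boundary convention is
arbitrary but fixed and tested. Gene-level calls length-weight the
log2 ratios of all segments overlapping the TP53 locus
(GRCh37 chr17:7,565,097–7,590,856 by default, 1-based inclusive); a
single overlapping segment that classifies as homozygous loss on its own
forces the homozygous call, so a focal biallelic deletion is never
averaged away by its neighbours. A deletion is *called* when the class
is a loss and the CCF reaches the call cutoff (default 10%, see below).

A probe-level fallback segmenter is included: recursive binary
splitting on the two-sample *t* statistic, splitting only below the
significance threshold $10^{-7}$. It is deliberately simple — parental
specific CBS is upstream of this package — and the threshold is the
user-visible parameter.

```{r cn-example}
seg <- tibble(sample_id = "S1", chromosome = "chr17",
              start = 7400000L, end = 7700000L,
              log2_ratio = tumor_cn_to_logratio(1.85, 0.8),
              n_probes = 80L)
call_gene_cn(seg, tibble(sample_id = "S1", purity = 0.8))
```

## Variant consensus and pathogenicity

Per-caller call sets are normalized to a shared key (iterative trimming
of shared leading/trailing bases; multi-allelic records are decomposed
first), then filtered per tool: Mutect2 requires a bare PASS, Shearwater
quality strictly above 30, Sophia DDM a PASS flag. A variant survives
only when at least two of the three callers pass; consensus VAF and
depth are medians across the passing callers (robust to one outlier
caller; the aggregation rule is a package choice). Laboratory
thresholds are strict: depth > 250x and VAF > 5%.

Pathogenicity labelling: a variant is pathogenic when its consequence
implies loss of function (missense, nonsense, frameshift — the missense
convention is deliberately literal, with no damaging-score requirement),
or when a clinical database reports it pathogenic and in-silico support
is strong. Finally, common variants (population frequency above 1%) are
excluded and a confirming database record is required. The
loss-of-function rule needs no database, yet the final filter demands
one; the two stages are applied in their stated order, and
`db_confirm = FALSE` exposes the alternative reading. Annotations are
input fields, never live queries, so results do not drift with database
versions.

## Allelic classification

Homozygous deletion alone is a double hit; deletion plus at least one
retained mutation is a double hit; a lone deletion or lone mutation is a
single hit. Two mutations without deletion remain a single hit: the
double-hit definition used here is strictly homozygous deletion or
deletion-plus-mutation. Cohort percentages round half away from zero,
which reproduces the reference composition of a 143-patient cohort
(34 deletion carriers = 24%, 12 mutation-only = 8%, 7 double hit = 5%);
one published relapse percentage (23/53 printed as 44%) is inconsistent
with any standard rounding of 43.4 and is reported here as 43.

## The prognostic CCF cutoff

The deletion-call cutoff is derived, not assumed. For every value $c$ on
a copy-number grid from 2.0 downward in steps of 0.05, patients are
dichotomized as deleted when $n_T < c$, i.e. CCF $> (2-c)\cdot 100$.
For each grid point, horizon (12–96 months, annual) and endpoint (PFS,
OS), the cumulative/dynamic AUC is estimated with inverse probability of
censoring weights: cases are subjects with events by the horizon,
weighted by $1/\hat G(T_i^-)$; controls are subjects event-free past it,
weighted by $1/\hat G(t)$, with $\hat G$ the Kaplan–Meier estimate of
the censoring distribution. Ties count one half, so with no censoring
the estimator reduces exactly to the Mann–Whitney statistic — the main
unit-test oracle. Significance against AUC = 0.5 uses a seeded
percentile bootstrap (default 1000 resamples); the per-endpoint limit is
the smallest CCF whose dichotomization is significant at any horizon,
and the adopted cutoff rounds each limit to the nearest multiple of 5
and takes the larger. The published limits (9.56% for PFS, 11.32% for
OS) reconcile to 10%.

The scan grid lives in CN units and is reported in both scales because
the two are conflated in common usage ("CCF = 2" meaning the diploid
CN); degenerate grid points (all patients on one side) are recorded as
missing rather than aborting the scan.

A caution established while validating the scan on simulations: the
"smallest significant threshold" is only a consistent estimator of a
generative clonality boundary when essentially no prognostic signal
survives below it. Because clonal carriers stay inside every
carrier-inclusive dichotomization, a cohort with many wild-type patients
retains weak signal at low thresholds, and with growing sample size the
scan's limit drifts downward. The recovery test therefore uses a cohort
where wild type is rare (5%) and the hazard-free sub-clonal mass
(CCF 55–60%) sits within one grid step of the boundary at 60%; all
exploratory seeds recover the boundary exactly under that design. On
real cohorts the limit should be read as "lowest CCF with detectable
signal at this sample size", not as a biological constant.

## Survival analysis

Endpoints are constructed in months from therapy start: PFS to first
progression or death, OS to death, PFS2 to second progression or death,
and 2nd PFS from first progression to second progression or death
(defined only for patients who progressed). Kaplan–Meier medians are
the earliest time the survival estimate reaches 0.5 — on a curve that
sits exactly at 0.5 over an interval this package reports the interval's
left edge — and a curve that never reaches 0.5 yields an explicit
not-reached state, never a sentinel value. Cox models use Efron tie
handling (event times have monthly resolution, so ties are common).
Multivariable models use backward elimination at p < 0.05 with the ISS
stage always retained as adjustment; the elimination order is returned
as a trace so the selection is auditable. Monotone-likelihood fits (a
group without events) are flagged as non-converged rather than silently
reported. Whether published univariable contrasts were ISS-adjusted is
ambiguous; `cox_univariable()` takes an optional `adjust` argument so
both are available.

## Longitudinal evolution

Paired diagnosis/relapse statuses map to a total transition table
(stable wild type, acquired deletion / mutation / double hit, stable
altered, regressed — regression is representable even though rarely
discussed). The cohort-level frequency shift uses the unpaired
continuity-corrected two-proportion test, mirroring the published
comparison of the full diagnosis cohort against the re-assessed subset;
because that comparison is statistically debatable for partially paired
data, McNemar's test on the paired subset is emitted alongside. The
carrier CCF shift uses the unpaired Mann–Whitney test (carrier sets
differ between timepoints), with a paired Wilcoxon companion for
patients deleted at both timepoints.

## The synthetic cohort generator

`simulate_cohort()` draws each patient's TP53 class (default
composition 68/19/8/3.5/1.5% for wild type / deletion-only /
mutation-only / deletion-plus-mutation / homozygous deletion, the
reference diagnosis frequencies), purity uniform on 0.4–1, and deletion
CCF from a 50/50 mixture of sub-clonal U(10, 63) and clonal U(63, 100)
reflecting the 63% clonality boundary. Observables are
forward-simulated: segment log2 ratios through the purity-dilution
model with Gaussian probe noise (SD 0.1, 60 probes over the locus);
mutation VAF as $\rho \cdot \mathrm{CCF}_m / (\rho\, n_T + 2(1-\rho))$
with one mutated copy and binomial read sampling at mean depth 500x;
three caller outputs by thinning true variants at 95% sensitivity and
adding sparse false positives (80% of them sub-threshold, so every
filter branch is exercised); survival as exponential proportional
hazards with wild-type median PFS 41.2 months, OS median 90 months (the
reference wild-type OS median was not reached, so a value beyond the
follow-up horizon is used), hazard ratios 1.63/1.82 (single hit,
PFS/OS) and 3.34/3.47 (double hit), and uniform censoring solved
numerically to hit the target censoring fraction. Relapse pairs
re-assess a uniform subset (53/143 by default), apply acquisition
events, and inflate persisting deletion CCFs by 82.4/62.9.

Because the generator is exponential-PH with independent uniform
censoring and a single locus, passing tests demonstrate correctness of
the estimators under those assumptions — not robustness to real-data
features such as non-proportional hazards, informative censoring,
wavy array noise, or caller error modes beyond thinning and sparse
false positives.

A deterministic assignment mode bypasses the class draw so printed
compositions can be reproduced exactly: `fixture_diagnosis_cohort()`
(97/27/12/5/2 over 143 patients, noise-free probes, full caller
sensitivity, carrier CCFs kept clear of the call cutoff) and
`fixture_relapse_pairs()` (53 pairs, 9 carriers at diagnosis, exactly
8/4/2 acquisitions, hence 23 carriers at relapse).

```{r fixture}
co <- fixture_diagnosis_cohort()
cn <- call_gene_cn(co$segments, co$purity)
v <- filter_variants(co$calls, co$annotations)
st <- classify_allelic_status(cn, filter(v, retained))
summarize_cohort(st)$by_collapsed
```

## Numerical and design choices

* Coordinates are 1-based inclusive in SEG input, as in the common SEG
  dialect; overlap arithmetic is exact integer.
* The probe segmenter treats a two-probe split (no residual degrees of
  freedom) as decisive when the means differ, so the significance
  limits behave sensibly at `alpha = 1` and `alpha = 0`.
* Degenerate inputs error loudly and early: empty cohorts, missing
  locus coverage, unannotated consensus variants, all-censored horizons,
  zero denominators.
* Problem sizes in the test suite are chosen to make each statistical
  property sharp at interactive run times: 500 replicates for CCF
  recovery and null-AUC calibration, 100 replicates for Cox CI
  coverage at 600 patients per arm, one 200-patient scan recovery,
  10,000 patients for composition frequencies.
* Time is always months; day inputs should be divided by 30.4375
  before entry.

## Known limitations

* Purity is an input; no attempt is made to re-estimate it from the
  data (ASCAT-class tools are upstream).
* The CCF model assumes a hemizygous single-copy loss; complex states
  (copy-neutral LOH, subclonal homozygous loss) are outside it.
* Variant normalization trims reported alleles only; full left-alignment
  against the reference genome is not attempted.
* The same 10% CCF cutoff is applied to homozygous-loss calls, whose
  CCF is computed under the hemizygous model.
* Mutation VAF is used as-is for classification; no CCF adjustment of
  VAF for local copy state is applied at the classification step.
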