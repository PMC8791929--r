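# tp53hits

Clonal and sub-clonal **TP53** lesion calling, double-hit classification
and prognostic CCF-cutoff derivation for multiple myeloma cohorts.

TP53 can be lost by 17p deletion, by somatic mutation, or by both.
Conventional FISH misses sub-clonal deletions and ignores mutations, so
patients with fully inactivated TP53 — the *double-hit* group
(homozygous deletion, or deletion plus pathogenic mutation) — are
under-recognized despite carrying the worst prognosis. `tp53hits` is an
end-to-end, tidyverse-style pipeline for this assessment:

* **Copy number & CCF** — segment log2 ratios are purity-corrected via
  the mixture model `2·2^L = ρ·n_T + 2(1−ρ)` and converted, under a
  hemizygous-loss model, to a deletion cancer cell fraction
  `CCF = 100·clamp(2 − n_T, 0, 1)`; CN classes use the 0.6 / 1.9 / 2.1 /
  3.4 thresholds. A recursive binary segmenter (split significance
  1e-7) is included for probe-level input.
* **Variant consensus** — calls from Mutect2, Sophia DDM and Shearwater
  are normalized to shared keys, filtered per tool, kept on a 2-of-3
  consensus (median VAF/depth), passed through strict >250× / >5%
  laboratory thresholds, labelled pathogenic / VUS / benign, and
  retained only when uncommon (≤1% population frequency) and
  database-confirmed.
* **Allelic status** — per patient: `WT`, `SINGLE_DEL`, `SINGLE_MUT`,
  `DOUBLE_HOMDEL`, `DOUBLE_DELMUT`, with cohort summaries.
* **Prognostic cutoff** — a cumulative/dynamic time-dependent ROC
  (IPCW, seeded percentile bootstrap) scanned over a 0.05-step CN grid
  derives the lowest CCF still predicting PFS/OS; per-endpoint limits
  reconcile to a single adopted cutoff (9.56% and 11.32% → 10%).
* **Survival** — PFS / OS / PFS2 / 2nd-PFS construction, Kaplan–Meier
  with explicit not-reached medians, uni- and multivariable Cox (Efron
  ties, backward elimination with forced ISS adjustment).
* **Longitudinal** — paired diagnosis/relapse transition classification
  (acquisitions of deletion / mutation / double hit), frequency-shift
  and CCF-shift tests.
* **Synthetic cohorts** — a seeded generator with full ground truth
  (purity-diluted log ratios, imperfect three-caller outputs,
  proportional-hazards survival, paired relapses) so every stage is
  testable without external data.

## Worked example

```r
library(tp53hits)
library(dplyr)

# deterministic 143-patient cohort: 97 wild type, 27 deletion-only,
# 12 mutation-only, 5 deletion+mutation, 2 homozygous deletions
co <- fixture_diagnosis_cohort()
cn <- call_gene_cn(co$segments, co$purity)            # gene-level CN/CCF
v  <- filter_variants(co$calls, co$annotations)       # consensus + filters
st <- classify_allelic_status(cn, filter(v, retained))
s  <- summarize_cohort(st)
s$by_collapsed
#> # A tibble: 3 × 3
#>   collapsed     n   pct
#>   <fct>     <int> <dbl>
#> 1 wt           97    68
#> 2 single       39    27
#> 3 double        7     5
c(s$n_deletion_carriers, s$pct_deletion_carriers)     # 34 deletion carriers = 24%
#> [1] 34 24
reconcile_cutoffs(c(9.56, 11.32))                     # adopted deletion-call cutoff
#> [1] 10
```

`34/143 = 24%` of patients carry a TP53 deletion, `12/143 = 8%` a lone
mutation, and `7/143 = 5%` are double-hit (2 homozygous deletions, 5
deletion+mutation) — the cohort structure the classifier is checked
against. The relapse companion:

```r
rel  <- fixture_relapse_pairs(co)                     # 53 pairs, 8/4/2 acquisitions
st_r <- classify_allelic_status(
  call_gene_cn(rel$segments, rel$purity),
  filter(filter_variants(rel$calls, rel$annotations), retained)
)
evo <- track_evolution(filter(st, sample_id %in% rel$pair_ids), st_r)
attr(summarize_acquisitions(evo), "total_acquired")
#> [1] 14
```

For a fully random cohort, `run_pipeline(cohort_config(seed = 1))`
executes all eight stages (simulate → copy number → variants → classify
→ ROC scan → survival → longitudinal → report) and returns stage
results plus a digest manifest; reruns with the same seed are
byte-identical.

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (KM curves, scan heatmaps) plus a swimmer-style
`plot_evolution()`.

See the vignette (`vignettes/tp53-double-hit-methods.Rmd`) for the
model, parameter and design discussion.

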