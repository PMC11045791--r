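# agrivar

Case-only gene-environment variant prioritization for pesticide-exposed
Parkinson's disease (PD) cohorts.

## The problem

PD cohorts recruited in intensive-agriculture regions offer a rare
chance to study gene-environment interaction: decades of record-based
ambient pesticide exposure, longitudinal motor examinations, and
targeted sequencing of genes tied to lysosomal function and PD risk.
But such cohorts typically have **no matched sequenced controls**, so
variant-level signal must be extracted case-only: compare panel allele
frequencies with an ancestry-matched public reference (gnomAD-style
AC/AN tables), then ask which enriched variants concentrate in the
patients who were *most exposed* and *progressed fastest*.

`agrivar` implements that workflow end to end, for analysts who want a
tested, reproducible version of it:

1. **Exposure** — long-term (1974 to diagnosis minus 10 years) average
   lbs/acre per pesticide and address type; co-application clusters by
   average-linkage hierarchical clustering on `1 - r` with an `r > 0.45`
   cut; a toxicity-weighted cluster score
   `raw = sum_p,loc beta_p * log(1 + x)/SD`, SD-scaled over the cohort
   and displayed with the cohort mean anchored at 1.
2. **Progression** — REML linear mixed model of UPDRS-III with random
   intercept and visit slope per subject (`lme4`); empirical-Bayes
   slopes, residualized on covariates; display score
   `1 + residual/SD`.
3. **Variant QC** — PASS filter, Phred >= 30, depth >= 10 in >= 90% of
   each subpopulation; exonic/splice-site canonical restriction;
   gene-specific artifact rules; PLINK-style method-of-moments IBD
   (`pi_hat = P(IBD=2) + P(IBD=1)/2`) with greedy exclusion above 0.05.
4. **Enrichment** — pooled two-proportion z-test (continuity-corrected)
   of cohort AC/AN against the matched reference population, two-sided
   with a directional enrichment rule, no frequency floor, no
   multiple-testing correction (a documented property of the emulated
   workflow, not a recommendation).
5. **Prioritization** — carrier-averaged display scores; keep entries
   with both averages >= 1; rank by the composite
   `(avg_prog/max) * (avg_exp/max)`; gene rollup, CADD bins
   (`<10`, `10-20`, `>20`), replication interface, and a Welch test
   comparing multi- vs single-variant carriers.
6. **Synthetic cohort** — a first-class generator for every input
   (subjects, visits, application records with correlated co-application
   clusters, panel VCF with planted enriched variants whose carriers are
   exponentially tilted toward high exposure and fast progression,
   relatedness SNPs with planted duplicate and parent-offspring pairs)
   plus ground truth for parameter-recovery testing.

## Worked example

```r
library(agrivar)
cfg <- run_config(sim = sim_config(n_subjects = 400,
                                   n_background_variants = 100,
                                   n_planted_variants = 10,
                                   n_ibd_sites = 12000,
                                   n_related_pairs = 4, seed = 1))
res <- run_all(cfg, out_dir = "agrivar_out")
res$report
```

```
# Prioritized variant report

- Prioritized variants: 14 (19 entries) in 12 genes
- Genes with multiple variants: 2/12 (17%)
- Genes with a multi-carrier variant: 10/12 (83%)
- Composite score range: 0.349 (LFG058) to 0.856 (LFG046)
- CADD bins (of 14 variants): <10 14%, 10-20 43%, >20 43%, unscored 0%
```

Of the 14 prioritized variants, all 10 planted variants are recovered
(the other 4 are background false positives, consistent with the
per-variant alpha of 0.05 and no multiplicity correction). The top of
the ranked table:

```
    gene      variant_id   subpop carriers avg_exposure avg_progression composite
  LFG046   13:139759:A:C European       13         1.72            2.05     0.856
  LFG037 12:43528450:C:A European       33         1.62            2.14     0.839
  LFG066 13:24603377:A:C European       17         1.61            2.14     0.833
```

Carrier averages are display scores: 1 is the cohort reference level,
so these carriers sit 0.6-0.7 SD above the cohort in exposure and ~1 SD
above in progression rate — exactly the planted structure. The run also
removed 5 subjects for relatedness (one member of each planted pair plus
its greedy resolution) and reports the multi- vs single-variant carrier
comparison (`res$additivity`, Welch p = 0.0029 here: multi-variant
carriers of strongly tilted variants do score higher in this synthetic
cohort).

`example_prioritized_table()` ships a transcription of a published
prioritized ranking (36 variants, 26 genes); `report()` on it reproduces
the published counts and composite extrema (0.497 down to 0.036) from
the table alone.

A thin CLI over the same functions lives at `inst/cli/agrivar-run.R`
(`simulate` and `run-all` subcommands, YAML config).

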