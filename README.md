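# pathgwas

Gene-set (pathway) association testing on individual-level GWAS
genotypes, built as a reusable R package plus a numbered analysis
workflow. It re-implements the full analytic chain used in large
case-control pathway studies of neuropsychiatric disorders — the design
follows the Tourette-syndrome GWAS gene-set analyses of ~3600 cases /
~7700 controls on ~236k SNPs, where gene sets for neural and immune
function were tested with both a self-contained and a competitive method:

1. **IO** — PLINK BED/BIM/FAM (2-bit SNP-major codec), GMT gene sets,
   gene coordinate tables.
2. **QC** — sample call rate ≥ 0.98, |F| inbreeding ≤ 0.2, marker call
   rate ≥ 0.98, case-control differential missingness ≤ 0.02,
   Hardy-Weinberg exact tests (p ≥ 1e-6 in controls, ≥ 1e-10 in cases),
   pairwise batch-effect scans (flag at p ≤ 1e-6), 6-SD ancestry-PCA
   outlier removal, identity-by-descent pruning at PI_HAT > 0.1875.
3. **Structure** — Patterson-normalized PCA, Tracy-Widom selection of
   significant axes (optionally after LD regression), iterative outlier
   removal; the top 5 PCs feed the association model as covariates.
4. **Association** — per-SNP additive logistic regression (Wald), plus a
   vectorized Rao score-test path for permutation work; minor-allele
   frequencies by status and the allelic odds ratio
   OR = (F_A/(1−F_A)) / (F_U/(1−F_U)).
5. **SBA** — the self-contained set-based association test: SNPs map to
   genes within ±10 kb and genes to sets; each set keeps its top
   LD-independent SNPs (p < 0.05, pairwise r² < 0.5, at most 5) and is
   scored by the mean of their p-values; case/control labels are permuted
   (covariates stay attached, association refit) to give the empirical
   p-value EMP1 = (1 + #{perm ≤ obs})/(R + 1), a max(T) family-wise EMP2,
   Bonferroni reporting at 0.05/45 ≈ 1.1e-3, and leave-one-gene-out
   sensitivity re-tests.
6. **Competitive** — gene statistics as LD-aware mean chi-squares
   (Brown-style moment matching), probit z-scores, one-sided regression of
   z on set membership with gene-level covariates, and an adaptive
   gene-label permutation correction with a family-wise threshold.
7. **Simulator** — Balding-Nichols population structure, founder-mosaic LD
   blocks with AR(1) ancestral LD, case-control ascertainment by rejection
   sampling, planted causal gene sets and plantable QC pathologies, so
   every stage is testable against known truth.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated cohort with
one planted enriched set (5 causal SNPs, per-allele OR 1.5, all in one
gene) and planted QC artifacts:

```sh
Rscript analysis/01_simulate_cohort.R       # 801 samples x 5000 SNPs, 45 sets
Rscript analysis/02_quality_control.R
Rscript analysis/03_ancestry_pca.R
Rscript analysis/04_association_scan.R
Rscript analysis/05_set_based_association.R 2000
Rscript analysis/06_competitive.R
```

Stage 2 recovers the planted artifacts:

```
removed samples by reason:
low_call_rate   pca_outlier
            1             2
removed markers by reason:
batch_effect
          10
planted batch-shift markers recovered: 10 / 10 (reason batch_effect)
```

(the near-duplicate pair surfaces in the PCA-outlier stage here: at this
cohort size a twin pair dominates a principal component before the IBD
stage sees it). Stage 5 finds the planted set and the sensitivity re-test
behaves like the published FLT3 check — dropping the causal gene destroys
the signal:

```
Bonferroni threshold for 45 sets: 0.001111
   SET NSNPS NSIG ISIG      STAT      EMP1      EMP2
 set01   135   18    5 1.801e-09 0.0004998 0.0004998
 set32   128    8    5 1.188e-05 0.0004998 0.0004998
 ...
set01 EMP1 = 0.0004998; after dropping gene 57: EMP1 = 0.4593
```

`set01` is the planted set; `set32` holds a gene from the same LD block
and tags the causal SNPs — self-contained tests inherit the LD of the
cohort. Per-SNP rows mirror the conventional association-table layout
(CHR SNP BP A1 F_A F_U A2 P OR), e.g. the top SNP
`rs000570: F_A 0.526, F_U 0.276, OR 2.88`, where the allelic OR
reconstructed from the frequencies (2.91) tracks the model OR.

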