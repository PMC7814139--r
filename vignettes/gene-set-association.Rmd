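---
title: "Gene-set association from individual-level genotypes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set association from individual-level genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathgwas)
```

`pathgwas` implements the analytic chain of a case-control pathway GWAS
on raw genotypes: quality control, ancestry principal components,
covariate-adjusted single-marker association, a *self-contained*
phenotype-permutation set test (SBA), and a *competitive* gene-set test.
The two set tests answer different questions. The self-contained null is
"no gene in this set is associated with the trait"; the competitive null
is "genes in this set are no more associated than genes outside it". A
cohort-wide inflation (polygenicity, residual stratification) moves
self-contained p-values but not, to first order, competitive ones; a set
can therefore be strongly self-contained-significant and competitively
unremarkable.

This vignette records the models, the parameters that matter, and the
design decisions taken where the design was genuinely open. Everything
quantitative stated here is computed by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`.

## The association model

Single-marker association is additive logistic regression,

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_g\, g +
  \Gamma' \mathrm{PC}_{1..5},$$

with $g \in \{0,1,2\}$ copies of the A1 (minor) allele and the leading
ancestry PCs as covariates. The reporting path (`gwas_scan()`) uses the
Wald test from the full fit; SNPs that separate or fail to converge are
flagged and carried with $p = 1$ rather than dropped silently. Sample
sizes are complete-case per SNP, which keeps the reported case/control
minor-allele frequencies `F_A`/`F_U` interpretable: the allelic odds
ratio $(F_A/(1-F_A))/(F_U/(1-F_U))$ reconstructs the published top-SNP
odds ratios of the motivating study within 0.5% relative error (asserted
in the acceptance suite over all fifteen printed rows).

The permutation path (`score_scan()`, used inside `sba_test()`) uses the
Rao score test from the null model instead: the null logistic fit depends
only on the covariates and the (permuted) phenotype, after which every
SNP costs a handful of BLAS operations. When no covariates are supplied
the label permutation preserves the case count, the null fit collapses to
the intercept, and an entire permutation block reduces to one matrix
product. Both the observed pass and the permuted passes of the SBA test
use this same statistic, so observed and permuted set scores are
exchangeable under the null — mixing a Wald observed pass with score-test
permutations would bias EMP1. Missing genotypes are mean-imputed on this
path (complete-case fitting per SNP per permutation would be
prohibitively slow and changes p-values negligibly at the missingness
rates QC admits).

## The self-contained SBA test

For each set: SNPs are assigned to genes by position within a ±10 kb
window (`window_kb`, boundary-inclusive), gene SNPs are pooled and
deduplicated, and the set keeps its top LD-independent SNPs — greedy
descent through the sorted p-values, accepting a SNP only if its $r^2$
with every previously accepted SNP is below `set_r2` (0.5), the p-value
is below `set_p` (0.05), and at most `set_max` (5) SNPs are taken. The
set statistic is the **mean of the selected p-values**; an empty
selection is a sentinel that behaves as the weakest possible statistic.
Ties in the greedy sort are broken by position then identifier, so
results are order-deterministic. A `statistic = "mean_chisq"` variant
(mean of the selected 1-df chi-squares) is available; the mean-p form is
the default because it is the form the motivating analysis describes.

Case/control labels are then permuted `n_perm` times — covariates stay
attached to their samples, the association is refit, the selection is
redone — and

$$\mathrm{EMP1} = \frac{1 + \#\{b : T_b \le T_{\mathrm{obs}}\}}{R + 1},$$

which can never be zero. `EMP2` is the max(T) analogue: the best
(smallest) statistic across all sets per permutation replaces $T_b$,
giving family-wise control. With 45 sets at $\alpha = 0.05$ the
Bonferroni threshold is $0.05/45 \approx 1.1\times10^{-3}$, so at least
~900 permutations are needed before EMP1 can cross it; `sba_test()`
warns below that floor. The default `n_perm` of 10,000 resolves
$10^{-4}$; production analyses of the motivating kind use $10^6$.

Correctness anchor: on an 8-sample cohort the permutation space (all 70
case/control assignments) is enumerated exhaustively and EMP1 must equal,
exactly, an independent re-computation through `stats::glm` score tests —
this is asserted in the acceptance suite, as are null calibration (type-I
error at 5% within its binomial interval and KS-uniform EMP1 over 200
null cohorts) and power (a planted set with five OR-1.5 SNPs at
$n = 2000$ detected below $0.05/45$ in ≥ 80% of replicates).

`leave_out_retest()` re-runs a single modified set under the same
permutation seed, mirroring the published robustness checks in which a
driver gene (or single top SNPs) is removed from a significant set. Note
that in dense LD a removed gene's signal can survive through proxy SNPs
of neighbouring member genes; the simulator therefore isolates its
planted causal gene within its LD block so the re-test is interpretable.

## The competitive test

Gene-level statistics follow the mean-chi-square construction: per-SNP
1-df score chi-squares $q_i$ are averaged within the gene, and the null
of $T = \bar q$ is approximated by a scaled chi-square with matched
moments, $E[T] = 1$ and

$$\operatorname{Var}[T] = \frac{2k + 4\sum_{i<j} \hat r^2_{ij}}{k^2},$$

where $\hat r$ is the Pearson genotype correlation (Brown-style moment
matching). A single-SNP gene reduces *exactly* to the SNP p-value; $k$
fully redundant SNPs reduce to the single-SNP p within a few percent.
Gene p-values become probit z-scores, and each set is tested by
least-squares regression

$$z_g = \alpha + \beta\, s_g + \Gamma' C_g + \varepsilon,$$

one-sided for $\beta > 0$, with $C_g$ = (log SNP count, log gene length,
mean pairwise $r^2$) — the standard size/length/LD confounders of
competitive tests. This module is an explicit reconstruction of the
three-step competitive method the motivating study employed (annotation,
gene statistics, set regression); the fidelity target is the statistical
contract, not bit-compatibility with the external tool.

Family-wise correction permutes *gene labels* — the competitive null is
exchangeability of genes — recomputing all sets' nominal p per
permutation; each set's corrected p counts permutations whose minimum
nominal p beats the set's observed one, with early stopping once every
set has accumulated `stop_exceedances` exceedances (adaptive
permutation). The 5th percentile of the permutation min-p distribution is
reported as the family-wise nominal-p threshold.

**Known limitation.** The nominal one-sided t p-value is anticonservative
in its far tail under the permutation null, because the z population is
finite, skewed and slightly heavy-tailed; at desk scale (hundreds of
genes, sets of 10–50) the measured marginal tail is roughly
$P(p \le 1.1\times10^{-3}) \approx 2\times10^{-3}$, which places the
family-wise threshold *below* the Bonferroni bound $0.05/45$. The
motivating study's own adaptive-permutation threshold (0.00100496) also
lies below its Bonferroni bound, so this is a property of the method, not
only of the scale; the permutation-corrected p, not the nominal p, is the
quantity to report. A second desk-scale caveat: when the tested sets tile
the entire gene universe, the strongest genes land inside *some* tested
set in every permutation and the family-wise correction becomes extremely
conservative; real pathway collections cover a minority of genes.

## Quality control

The cascade runs in the published order with the published thresholds:
sample call rate ≥ 0.98 and method-of-moments inbreeding $|F| \le 0.2$
(the threshold is applied two-sided: both excess homozygosity and excess
heterozygosity indicate artifacts); marker call rate ≥ 0.98; case-control
differential missingness, read as a *rate difference* ≤ 0.02 (the
alternative p-value reading is computed and reported but not
thresholded); Hardy-Weinberg exact tests at $10^{-6}$ in controls and
$10^{-10}$ in cases, computed per class; pairwise batch scans (allelic
association and missingness between batches, within cases only and
controls only, flag at $p \le 10^{-6}$); 6-SD iterative PCA outlier
removal over the top 10 PCs; and IBD pruning at PI_HAT > 0.1875, removing
the lower-call-rate member of each flagged pair (exact ties go against
the lexicographically larger sample id, for determinism).

The HWE test is the exact conditional test (total probability of all
heterozygote counts no more probable than the observed one); it is
asserted equal to brute-force enumeration for *every* genotype table with
$n \le 50$. PI_HAT is Purcell-style method-of-moments from IBS sharing;
two implementation details matter at desk scale: the allele-frequency
functionals ($p^2q^2$ etc.) are estimated by unbiased factorial moments
rather than plug-in $\hat p$ (the plug-in version visibly inflates PI_HAT
when markers are few), and only the final PI_HAT is clamped to $[0,1]$ —
clamping the intermediate IBD-state estimates at zero biases unrelated
pairs upward by ~0.03. Even so the estimator needs a few thousand pruned
markers before the 0.1875 threshold separates cleanly from sampling
noise; QC-focused analyses here use ≥ 5000-marker cohorts.

Two desk-scale stage interactions are worth knowing. A duplicated pair
dominates a principal component of an unstructured cohort (its rank-one
unit block beats the Marchenko-Pastur edge), so the PCA-outlier stage can
claim duplicates before the IBD stage sees them. And far-ancestry
samples read as inbred against pooled allele frequencies (the Wahlund
effect), so with very divergent planted outliers the $|F|$ stage can fire
first. Neither is wrong — the samples should go — but tests that assert
*which* stage removes them isolate the stage under study.

## Ancestry PCA and Tracy-Widom selection

Markers are mean-imputed, exactly column-centered, and scaled by
$\sqrt{2\hat p(1-\hat p)}$ with the posterior frequency estimate
$\hat p = (\text{count} + 0.5)/(2n + 1)$; exact centering keeps the
spectrum at rank $n-1$, on which the Tracy-Widom calibration relies.
Significance of the leading eigenvalues follows Patterson's procedure:
the effective marker count is estimated from eigenvalue moments,
$m_{\mathrm{eff}} = (L+1)S_1^2 / (L S_2 - S_1^2)$ (re-estimated after
each tested eigenvalue is dropped), each leading eigenvalue is
standardized with the white-Wishart centering constants, and components
are counted significant against the TW1 critical value (0.9793 at
$\alpha = 0.05$; 2.0234 and 3.2724 at 0.01 and 0.001) until the first
failure. On pure-noise genotype matrices this yields a TW1 statistic with
mean −1.29 and SD 1.26 (theory: −1.21 / 1.27) and a 3–5% exceedance rate.

Linkage disequilibrium destroys that calibration: the noise eigenvalue
bulk of an LD-structured cohort extends far beyond the white-noise edge
and the moment correction does not absorb it. `ld_regress = 5`
residualizes each standardized marker on its five predecessors on the
chromosome before the eigenanalysis, restoring the null (0 significant
axes on LD-structured single-population cohorts, ancestry axes retained).
The regression makes results depend on marker order, so it is off by
default for ancestry *scores* and on wherever the *count* of significant
axes is the quantity of interest. The motivating analysis found five
significant axes on its cohort and used the first five PCs as covariates
while scanning ten PCs for 6-SD outliers; both knobs are separate here
(`n_pcs_covariates`, `pca_n_pcs`).

## The simulator

`simulate_cohort()` is the package's study-conditions generator, not a
fixture: population structure is Balding-Nichols (ancestral frequencies
$p_0 \sim U(0.05, 0.5)$, subpopulation frequencies
$\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$); LD comes from a pool of
founder haplotypes per block carrying ancestral LD (AR(1) Gaussian copula
with exact Bernoulli($p$) marginals, latent coefficient 0.9), from which
individual haplotypes are built as mosaics with a geometric switch
process (switch probability 0.05 per SNP) emulating recombination.
Defaults: 40 blocks × 50 SNPs at 10 kb spacing (array-like density — the
motivating cohort has roughly one SNP per 13 kb — and chosen so the
±10 kb gene window reaches one SNP past a gene, keeping SNP-to-gene
attribution nearly unique), 5 genes tiling each block, gene sets
partitioning the genes, 200 founder haplotypes (baseline pairwise kinship
≈ 2/200 in PI_HAT units, far below the 0.1875 relatedness threshold —
smaller pools make every cohort member cryptically related), baseline
prevalence 0.2 with case/control quotas filled by rejection sampling
(case-control ascertainment), two genotyping batches, one seed for all
randomness. Causal SNPs get log-odds $\log(\mathrm{OR})$ and live inside
genes of the designated sets; with `one_gene = TRUE` they concentrate in
a single gene that is additionally isolated from same-set neighbours in
its LD block, so leave-one-gene-out re-tests are not confounded by LD
proxies. `implant_artifacts()` plants QC pathologies (duplicates,
parent-child pairs, stratified missingness, Hardy-Weinberg violations)
with the planted truth returned alongside.

What the simulator does *not* emulate — and hence what green tests do not
certify about real data: realistic human LD maps and recombination
hotspots, allele-frequency spectra with rare variants, X-chromosome
inheritance, genotyping-intensity artifacts, and confounders beyond
ancestry (e.g. phenotype-correlated batch assignment). The permutation
machinery itself refits covariates per label permutation, which is
documented to be potentially anticonservative under strong confounding;
the motivating analysis also ran an unadjusted variant as a robustness
check, which `sba_test(covariates = NULL)` reproduces.

## Numerical and engineering choices

Problem sizes in the validation studies are desk-scale by design: null
calibration uses 200 cohorts of $n = 400$, $m = 2000$ with 45 null sets
and 2000 permutations each; power uses 50 cohorts of $n = 2000$; QC
recovery uses $m = 5000$ cohorts. The permutation engine vectorizes the
score test across permutation blocks (one BLAS product per block in the
unadjusted case) and pushes the per-set greedy selection into a small
C++ kernel that indexes shared union-level matrices; chi-squares are
converted to p-values only for the at-most-five selected SNPs per set and
permutation. Empirical p-values use the $(b+1)/(R+1)$ correction
throughout. Degenerate inputs are handled explicitly: monomorphic and
collinear SNPs are flagged rather than fatal, empty selections and empty
sets carry sentinels, boundary allele frequencies give flagged
infinite/zero odds ratios, and PI_HAT on fewer than 50 overlapping
markers is marked unreliable.
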