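---
title: "PRS-stratified GWAS: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRS-stratified GWAS: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical content of `PRSstrat`: the models
each stage fits, every tunable parameter with its default and rationale,
what the synthetic cohort generator does and does not emulate, and the
numerical conventions that make results reproducible to the digit.

## The stratification idea

A case-control phenotype that is secretly a mixture — a majority subtype
with strong, well-known common-variant drivers and a minority subtype with
its own (typically rarer) drivers — defeats the pooled GWAS: the minority
signal is diluted by a factor of roughly the minority fraction. The
package's flow turns the majority signal into a *filter*: a polygenic risk
score trained on half the study captures the majority-subtype liability,
cases with low PRS are depleted of the majority subtype, and a GWAS of
low-PRS cases against low-PRS controls re-concentrates the minority
signal. The cohort switch (train on B, test on A) is the built-in
replication.

Two readouts summarise whether the mechanism worked:

* minority-subtype variants gain significance in the low-PRS analysis
  relative to the overall analysis, and
* majority-subtype variants *lose* effect size there — quantified per lead
  SNP by the odds-ratio heterogeneity z-test.

## Stage-by-stage models

**Cohort split.** A randomized half-partition stratified by phenotype,
with the odd-stratum remainder assigned to cohort A, deterministic given a
seed. Stratification is our choice: the near-equal per-phenotype counts
published for this design are only achievable when case and control counts
are balanced by construction. A half-split cannot reproduce arbitrary
published cohort sizes whose halves differ by more than one; we guarantee
`|A − B| ≤ 1` per stratum instead.

**Association engine.** For each variant, additive-dosage logistic
regression `logit Pr(case) = b0 + b·G + sex + PC1..PC10` fit by IRLS
(tolerance 1e-8 on the step, at most 25 iterations), Wald test from the
observed information. Implemented in C++ (RcppArmadillo) and verified
against `stats::glm` in the unit tests. On non-convergence or any fitted
probability within 1e-8 of 0 or 1 — quasi-separation is routine for rare
variants at a few thousand samples — the variant is refit with the Firth
bias-reduced penalty (hat-diagonal-corrected score, step-halving, up to
100 iterations) and flagged `test = "firth"`. Missing dosages are
mean-imputed per variant; constant variants are skipped with a recorded
reason. Sex is coded 0/1 with unknown mean-imputed so sex-undetermined
samples are retained. Confidence intervals use the conventional 1.96
(not a higher-precision normal quantile): the published tables this
package's heterogeneity test reproduces were evidently built with it, and
the CI-to-SE inversion `se = ln(U95/L95)/(2·1.96)` must match.

**PCA.** PCs are eigenvectors of the sample covariance of standardized
dosages (mean-centred, scaled by `sqrt(2p(1−p))`), computed on variants
with MAF ≥ 0.05 after sliding-window LD pruning (window 50 variants,
step 5, r² 0.2). The smaller of the two covariance dimensions is
eigendecomposed. Sign convention: the largest-magnitude variant loading of
each PC is positive. For the low-PRS stratum GWAS the PCs are recomputed
on the stratum by default (`recompute_pcs_low = TRUE`): stratifying on a
genetic score can induce its own confounding, and recomputation guards
against it; reusing the full-cohort PCs is one switch away.

**Heterogeneity test.** Two-sample z on log odds ratios assuming
independence, `z = (β₂ − β₁)/√(se₁² + se₂²)`, two-sided normal P. The
low-PRS stratum is nested inside the overall cohort, so independence is
technically violated and the test is, if anything, conservative about
claiming heterogeneity when the shared samples pull the estimates
together; we keep it because it exactly reproduces the published
lead-SNP heterogeneity P-values from the published ORs/CIs (verified in
`tests/testthat/test-acceptance.R`).

**PRS.** Greedy clumping: smallest-P unclaimed variant becomes an index,
claiming all unclaimed variants within 250 kb with dosage r² > 0.1 in the
training cohort's own genotypes (the LD reference); ties broken by P then
position. The 14-cutoff threshold grid spans 1e-10 … 1 and includes 0.5
(the published grid table has 14 rows even though the accompanying text
lists 13 cutoffs; we follow the table). Scores average beta per
non-missing allele, `S_j = Σ β_i G_ij / (2 M_j)` — the published cutoff
magnitudes (~1e-3) are only plausible under this convention, not for raw
sums of hundreds of ln-OR terms. Model variants missing from the scored
genotypes drop out of numerator and denominator and are counted.

**Cutoff selection.** AUC is the Mann–Whitney pair statistic (ties at
one half), exact under ties and invariant to monotone transforms. The MCC
is maximized over candidate cutoffs at midpoints between consecutive
distinct scores plus sentinels — midpoints keep the inclusive low-risk
rule (`low ⇔ score ≤ cutoff`) unambiguous under floating-point equality.
A degenerate MCC denominator yields 0 by the standard convention. Ties in
the MCC go to the smallest cutoff.

**Locus calling.** Genome-wide significance is `P ≤ 5e-8`, inclusive.
Hits merge by single linkage within 500 kb — the grouping rule is not
fixed by any convention we could adopt, so 500 kb is a deliberate,
configurable default of this package. The lead is the smallest P (ties to
the smaller position); novelty is judged within 300 kb flanks of the
user-supplied known-locus intervals; quality class is high iff the lead's
imputation r² exceeds 0.9 (strict), rare iff lead MAF < 0.05 (strict).

## The synthetic cohort generator

`simulateCohort` is the package's stand-in for a real two-subtype study.
Per subtype *s*, disease follows a logistic liability
`logit Pr(case) = a_s + Σ_{i∈panel(s)} ln(OR_i)·G_i` with the intercept
`a_s` solved by bisection (tolerance 1e-8 on the marginal prevalence) so
each subtype's marginal case probability equals `baseline_prevalence`.
Cases are accumulated by rejection sampling per subtype — rather than a
Gaussian liability-threshold model — because the downstream analysis is
logistic regression, which keeps the simulation's ORs directly
interpretable as the estimands. Controls are sampled non-cases from the
subtype mixture. Genotypes are per-variant binomial(2, MAF)
(Hardy–Weinberg), within subpopulations when structure is enabled:
two subpopulations with Balding–Nichols allele-frequency divergence around
the base MAF, and separately configurable case/control subpopulation
fractions to induce confounding for the PC-correction tests.

Defaults, fixed once as the package's study conditions:

* `common_panel`: OR 6.0 at MAF 0.25 (HLA-like), OR 2.2 at MAF 0.10
  (PTPN22-like), OR 0.44 at MAF 0.25 (INS-like protective);
* `rare_panel`: MAF 0.002–0.035 with OR 9, 8, 6, 5, 3, 2 — spanning the
  rare-variant ranges the motivating design targets;
* `subtype_fraction = 0.08`, inside the 5–10 % quoted for
  antibody-negative presentations;
* `baseline_prevalence = 0.005`, a pediatric-T1D-like prevalence that
  also keeps rejection sampling affordable;
* rare-panel variants carry imputation quality 0.95/Imputed so the locus
  quality classification is exercised; everything else is Genotyped.

The analytic oracle `expectedCaseFrequency` (the exact three-term sum over
genotype classes of `HW(g)·Pr(case|g)`) calibrates the generator: the
simulated minority-case allele frequencies are required to match it within
Monte-Carlo error, and case-frequency monotonicity in the OR is checked
through it.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: linkage disequilibrium beyond the
correlated fixtures used for clumping tests (no recombination maps, no
haplotype structure), imputation dosage error (quality scores are carried
as labels, dosages are exact), genotyping batch effects, relatedness and
family structure, and a realistically polygenic majority subtype. The last
point matters for interpretation: with only three common drivers the PRS
reaches AUC ≈ 0.80 and the MCC cutoff labels roughly half the cases
low-risk, a much blunter stratification than a deeply polygenic score
achieves; consequently rare-variant hits that cross 5e-8 in a real
low-PRS analysis may only show as strong *enrichment* (not genome-wide
hits) at the simulation scales used here.

One approximation under structure: subtype intercepts are calibrated at
the base MAFs, so with strong divergence the realized marginal prevalence
per subpopulation deviates slightly from `baseline_prevalence`; the
structure mode is used for confounding tests, where this is immaterial.
For panels larger than ~7 variants the liability distribution used by the
intercept solver is binned at 1e-3 resolution, bounding the induced
prevalence error well below sampling noise.

## Problem sizes and frozen bounds

The test suite and acceptance script run simulations sized to finish
comfortably on one CPU, and the stochastic checks are frozen, seeded
regression bounds chosen from pilot runs at those sizes:

* end-to-end enrichment: 4,000 cases + 8,000 controls (split into halves),
  1,500 null variants — asserting the mean −log10 P of rare
  minority-panel variants is larger in the low-PRS analysis than overall,
  the minimum rare-panel P is smaller there, and the common-panel
  heterogeneity z is positive;
* inflation: 3,000 null variants at Fst 0.1 with 70/30 case-control
  subpopulation imbalance — naive λ > 1.05, PC-corrected λ within
  [0.93, 1.07], a band reflecting the Monte-Carlo noise of a median over
  3,000 χ² deviates;
* CI coverage: 60 common causal variants at 6,000 samples, coverage in
  [0.85, 1.00];
* switch symmetry: thresholds agree in at least 2 of 3 seeded replicates
  at 1,600 + 3,200 samples per cohort.

## Known limitations

* The heterogeneity test ignores the nesting of the stratum in the
  cohort (documented above), exactly as required to reproduce the
  published values.
* X-chromosome handling, mixed-model association, meta-analysis,
  conditional analysis, imputation and liftover are out of scope; the
  quality-score filter (`R² ≥ 0.3`, inclusive) treats imputation quality
  purely as input metadata.
* `filterVariants`, clumping and scoring all key on variant ids; variants
  must be harmonized to one id space upstream. Strand-ambiguous (A/T,
  C/G) variants are kept but flagged in the variant metadata, since all
  data flow through one harmonized dosage matrix.
* The split's determinism is tied to R's RNG stream; the same seed on the
  same R version reproduces partitions byte-for-byte.
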