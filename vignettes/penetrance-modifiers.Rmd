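---
title: "Methods: cis-regulatory modification of rare-variant penetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-regulatory modification of rare-variant penetrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cispen)
```

## The model under test

A rare heterozygous coding variant with a loss-of-function (LoF)
consequence removes (roughly) one gene copy. Whether the carrier manifests
a neurodevelopmental phenotype may then depend on how much product the
remaining **wild-type haplotype** makes. `cispen` tests this with
*genetically predicted* expression: each gene carries a sparse linear model
of common cis-eQTLs, and the prediction for a haplotype (or an individual)
is the weighted sum of its alleles (or dosages). Predicted values are used
raw — they are interpretable as inverse quantile-normalised expression, and
every downstream test is difference- or rank-based, so any monotone
rescaling is irrelevant.

Two complementary tests address the hypothesis:

1. **Within-family paired test.** For trios in which an undiagnosed,
   affected child inherited a putatively damaging variant from an
   unaffected parent, compare the predicted expression of the wild-type
   haplotype between the transmitting parent and the child
   (`family_paired_test()`, one-sided: parent higher). The design controls
   population stratification and conditions on the shared
   variant-carrying haplotype; under the modifier hypothesis the parent
   was protected by a high-expressing wild-type homolog.
2. **Carrier-vs-control rank test.** Per gene, percentile-rank the
   predicted expression of variant-carrying probands together with
   population controls, pool ranks across genes, and test one-sided
   whether carriers rank lower (`build_rank_input()`,
   `rank_wilcoxon()`). Each control contributes one rank per gene, so the
   pooled size is `n_carriers + n_genes x n_controls`; no within-control
   dependence correction is applied, a deliberate simplification shared
   with the study design this mirrors, and a known limitation.

Around these sit a TWAS logistic scan for average-expression effects on
case status, an outlier-expression (±3 control SD) Fisher test per gene for
extreme-regulation mechanisms, rare-variant classification, and genotype
QC.

## The synthetic-data generator

No public generative model exists for this design, so the package defines
one explicitly and treats it as the study condition for every calibration
and recovery claim.

* **Weight models.** Each of `n_genes` genes gets `snps_per_gene`
  independent cis-SNPs, MAF ~ U(0.05, 0.5), weight ~ N(0, `weight_sd`²)
  with `weight_sd = 0.2`. With the default 10 SNPs per gene this puts the
  SD of one haplotype's predicted expression near 0.2 expression units,
  comparable to the spread the tests operate on in practice. Synthetic
  cross-validation p values are drawn Beta(0.5, 10) — right-skewed so most
  but not all genes pass the conventional `cv_p < 0.05` filter, which keeps
  `filter_models()` exercised.
* **Haplotypes and transmission.** Parental haplotypes are independent
  Bernoulli(MAF) strings (no LD, no recombination); the child receives one
  uniformly chosen haplotype from each parent, independently per gene.
  Independence keeps the haplotype-expression contrast interpretable and
  lets the ascertainment sampler work gene-locally (the accept/reject
  decision depends only on the variant gene's four parental haplotypes;
  remaining genes are filled in afterwards — exact under independence).
  An LD hook is deliberately absent from the configuration.
* **Penetrance mechanism.** One rare damaging variant is placed on one
  haplotype of one parent, in a uniformly chosen gene. Affection is
  Bernoulli with logit α + β·(μ_g − (E_wt + ε)), ε ~ N(0, `noise_sd`),
  where E_wt is the predicted expression of the individual's *non-carrier*
  haplotype and μ_g the population mean haplotype expression. The carrier
  haplotype's expression is ignored, matching the LoF reading of the
  hypothesis. β = 0 recovers the null exactly. `noise_sd` (default 0.1) is
  environmental noise on the expression scale; it enters the liability
  only through the expression term.
* **Ascertainment.** Candidate trios are drawn until `n_trios_target`
  satisfy: child affected, child inherited the variant, transmitting
  parent unaffected. The non-transmitting parent does not enter the
  condition and is emitted unaffected. A bounded attempt budget
  (`max_attempts`) turns pathological configurations (e.g. α so low nothing
  is affected) into an explicit error naming the bound.
* **Baseline risk.** `baseline_logit = -2` (≈ 12% risk) is a risk scale
  for families already segregating a damaging variant, not a population
  prevalence; it makes proband ascertainment tractable while leaving both
  affected and unaffected outcomes common enough that the conditioning is
  meaningful.
* **Case/control cohorts.** Unrelated genotypes are drawn under
  Hardy–Weinberg from the same MAFs; a configured subset of genes
  (default one) carries a liability effect γ per unit predicted
  expression. The emitted covariates are standard-normal nuisance columns
  with no liability effect — they exist to exercise covariate handling,
  not to confound.
* **Seeds.** One master seed; the three generators derive streams at
  fixed offsets (+101 models, +202 trios, +303 case/control), so identical
  configurations give byte-identical emitted VCF/PED/TSV files.

What the generator does **not** emulate: LD panels, recombination,
population structure, imputation noise, genotyping error, pleiotropy
across genes, or realistic disease prevalence. Passing calibration and
recovery tests therefore demonstrates internal statistical correctness of
the pipeline under a clean mechanism — not performance on real cohorts.

## Numerical and design choices

* **Expression prediction.** Model variants absent from the dosage data
  are dropped, not mean-imputed; a per-gene coverage fraction is reported
  and genes with no matched variant are omitted with a message. Ref/alt
  swaps relative to the weight table are a hard error unless
  `allow_flip = TRUE` (dosage becomes 2 − dosage, logged). Palindromic
  variants are expected to be removed upstream by QC, so no strand
  heuristics are attempted.
* **HWE exact test.** Standard exact formulation (sum of configurations no
  more probable than observed, conditional on allele counts; not mid-p),
  computed with a ratio recurrence for stability and compared in tests
  against a closed-form log-factorial enumeration. In trio data the test
  uses founders only, the usual convention to avoid counting transmitted
  alleles twice.
* **"Call rate < 5%"-style thresholds.** The SNP missingness filter is
  expressed as `snp_missing_max = 0.05` (markers with ≥ 95% calls kept);
  heterozygosity bounds are applied as an open interval (strictly below
  0.158 or strictly above 0.17 removed). Batch differential missingness is
  a per-variant 2×2 Fisher exact test (p < 10⁻⁵⁰), and the batch
  allele-frequency check is an absolute-difference threshold (0.05),
  since no specific statistic is conventional. Removal order is fixed
  (palindromic, duplicated, multiallelic, indel, missingness, MAF, HWE,
  Mendelian, batch) and every removed marker carries exactly one primary
  reason, which makes the filters idempotent and the report reconcile
  (input = kept + removed).
* **Imputation r² filter.** Kept at r² ≥ 0.8 (inclusive). Source
  descriptions of this step are contradictory about direction in one
  place; the implementation keeps high-quality variants, the only reading
  consistent with the variant counts involved.
* **Variant classification.** gnomAD gate strict (< 10⁻⁵), cohort gate
  inclusive (≤ 10⁻⁴); MPC ≥ 2 is required for missense only in the
  constrained-gene category (a switch extends it to all categories);
  missing MPC fails the gate conservatively, with a warning when it
  excludes an otherwise-qualifying candidate. A lenient preset (MAF
  < 0.1%) mirrors the usual sensitivity analysis.
* **Unique pair selection.** Within each category analysis, one
  (parent, gene) candidate per proband, uniform, seeded; a proband can
  appear in several category analyses, which matches per-analysis
  sampling.
* **Paired test.** Closed form on the differences; one-sided p for
  "parent higher", with the two-sided p and a two-sided 95% t-interval
  always emitted. Zero-variance differences and n < 2 are errors, not
  NaNs.
* **Percentile ranks.** `100·(rank − 0.5)/N` with mean ranks for ties:
  a complete untied control set has mean percentile exactly 50 (the
  convention that reproduces a control mean of 50.00 in pooled-rank
  reports), and the transform is invariant to strictly monotone
  transformations of expression.
* **Wilcoxon.** Exact enumeration when the pooled size is ≤ 20 without
  ties, otherwise normal approximation with tie and continuity
  correction; the path taken is recorded in the output. The two paths
  agree within 0.01 by n = 15, which the suite checks.
* **TWAS.** Wald test on the expression coefficient by default
  (likelihood-ratio behind a flag); the information matrix is evaluated at
  the converged estimate. Constant expression, non-convergence and
  separation are flagged rather than reported as spurious p values.
* **Power.** Noncentral t: power = P(T' > t₁₋α,ₙ₋₁) with noncentrality
  d√n; the sample-size solver does a bracketed integer search for the
  minimal n, so `power(n(d)) ≥ target > power(n(d) − 1)` by construction.

## Problem sizes used by the test suite

Calibration and recovery claims are computed at sizes chosen to make
binomial error bands tight while keeping the default suite fast: the
family-test null uses 1,000 replicates of 120 ascertained pairs over a
4-gene, 6-SNP panel; the rank-test null 1,000 replicates of 8 carriers vs
100 controls; the TWAS null one 200-gene scan at 500 + 500 samples;
parameter recovery 400 replicates at each of β ∈ {0, 1, 3} with 100 pairs
(the grid was fixed after a 10,000-trio pilot run of the generator
confirmed the direction and spacing of the ascertainment asymmetry); and
the noncentral-t power check a 10⁵-replicate Monte-Carlo oracle at
(d = 0.5, n = 30, α = 0.05). Acceptance bands are ±3 binomial SEs for
calibration rates, 0.05 absolute for power agreement, and 10⁻⁸–10⁻¹² for
oracle equivalences.

## Known limitations

* Independent cis-SNPs and gene-local transmission mean the generator
  cannot probe LD-induced artefacts in weight-based prediction.
* The pooled rank test reuses each control across genes without a
  dependence correction; its null calibration holds under the simulated
  independence but would be optimistic under strong cross-gene
  correlation of predicted expression.
* The rare variant is an annotation bound to a named haplotype, not a row
  in the genotype matrix — weight models never include it, so this loses
  nothing for the implemented analyses, but the emitted VCFs do not show
  the damaging allele itself.
* Clinical inputs (ratings, DDG2P annotations, HPO terms) are consumed as
  given tables; no ontology traversal or transcript-level annotation is
  performed.
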