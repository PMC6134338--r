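---
title: "Methods: SNP-set association with a latent neurodevelopmental factor in trisomy and twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-set association with a latent neurodevelopmental factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctassoc)
```

# The scientific question

Children with a sex chromosome trisomy (47,XXX; 47,XXY; 47,XYY) show a wide
range of language and neurodevelopmental outcomes. One explanation is a
*double hit*: the extra sex chromosome amplifies the phenotypic effect of
otherwise mild autosomal variants, here common variants in two synaptic
genes, *CNTNAP2* (exon 13–14 region, chr7:147,514,390–147,612,852, hg19) and
*NRXN1* (exons 1–4 plus 20 kb upstream, chr2:51,141,501–51,280,121, hg19).
The package implements the complete analysis pipeline for testing this
hypothesis — genotype QC, phenotype construction, a component-based
structural model with permutation inference, exploratory per-SNP and
gene-based tests, and the power analysis for the ascertainment-biased
design — together with a synthetic cohort generator, because individual
genotype data of this kind cannot be distributed.

# The structural model (GSCA)

The inferential core is Generalized Structured Component Analysis: each
gene's SNP block $Z_g$ (standardized minor-allele dosages) forms a
*component* $c_g = Z_g w_g$, the three outcome measures form a latent
Neurodev factor $f = P v$, and the structural model is

$$ f = \sum_g a_g\, c_g + e, $$

with every component constrained to unit variance. Unlike covariance-based
SEM, the latent variables are exact weighted sums of their indicators, so
the model remains estimable with ~50 SNPs and a few hundred samples.

Estimation is by alternating least squares. Each pass solves three exact
subproblems, so the residual criterion
$\lVert f - \sum_g a_g c_g \rVert^2/(n-1)$ is monotone non-increasing (this
is asserted on every fit in the test suite):

1. **Paths** $a$: ordinary least squares given the current components.
2. **Gene weights** $w_g$: the partial residual is regressed on $Z_g$
   without constraint, and the solution is split into a unit-variance weight
   vector and a scalar path — jointly optimal for the constrained problem.
3. **Phenotype weights** $v$: the norm-constrained projection of the
   structural prediction onto the column space of $P$ (scaled projection,
   which is the exact constrained minimizer).

Numerical choices: weights initialize at equal values, fitting is entirely
deterministic, components are sign-fixed so each correlates non-negatively
with its first indicator, convergence is declared when the criterion
changes by less than `1e-5` (configurable), and singular block Gram
matrices (possible when SNPs are perfectly correlated or a subgroup is
smaller than the block) fall back to a pseudoinverse solve. With one SNP
and one measure the model collapses to the Pearson correlation, which the
suite checks to `1e-10`.

## Permutation inference

Significance of each path comes from permuting the phenotype block's rows
as a unit relative to the genotype blocks — preserving both LD and the
phenotype intercorrelations, and matching the exchangeability of unrelated
individuals (twin subsamples contain one twin per pair) — then refitting.
We use the add-one estimator $p = (1 + \#\{|a^{perm}| \ge |a^{obs}|\})/(B+1)$,
two-sided by default (directional one-tailed options exist). The two paths
are tested against pre-declared sequential alphas, 0.05 for *CNTNAP2* and
0.025 for *NRXN1*, mirroring the registered multiplicity control. Because
only crossproducts change under permutation, refits cost $O(m^2)$ per
iteration and 5000 permutations take seconds.

The analysis is repeated for the SCT group and the two twin subsamples,
and — exploratorily — for karyotype subgroups restricted to cases *not*
ascertained through developmental problems; subgroups below a configurable
floor (default 20) are skipped with a warning, and subgroup fits where
parameters exceed samples are flagged.

# Genotype quality control

The cascade applies, in order: sample call rate ≥ 95% (inclusive),
per-sample heterozygosity within ±2 SD of the input-set mean (exclusive
band, not iterated), exact Hardy–Weinberg p ≥ 1e-6, MAF ≥ 1% (inclusive —
"below 95%" and "less than 1%" fail), and a per-SNP Mendelian error rate
≤ 1% over informative trios with remaining inconsistent child calls set
missing. The HWE test is the exact conditional test (stable recurrence
over heterozygote counts, log-space), which the suite verifies against a
direct enumeration oracle for every genotype triple with total ≤ 50; the
chi-square approximation would be unreliable at the extreme 1e-6 threshold.
HWE counts are computed on unrelated individuals (one twin per pair) when
the caller supplies them, since trisomic samples genotype atypically and
co-twins are not independent. Missing dosages are excluded pairwise from
MAF and LD denominators. Pairwise LD is reported as squared Pearson
correlation of dosages; SNPs are deliberately not pruned for LD, matching
the registered analysis. X-chromosome handling is out of scope.

# Phenotype construction

Three measures: (A) nonword repetition, consumed as supplied (scaled-score
metric); (B) a general language factor from Verbal Comprehension, Oromotor
Sequences, Sentence Repetition and Vocabulary — a one-factor maximum
likelihood model fitted on complete cases, scored by regression (Thomson)
scores with available-item reweighting for children with at least two
subtests, falling back to the first principal component if ML fails (the
fallback is recorded); (C) a global neurodevelopmental burden index,
consumed as supplied because its construction from parental report was
ad hoc in the source study — the generator emits it directly. All three are
oriented so a low score means impairment (the burden index is sign-flipped
when supplied in the raw orientation), and the language factor is
z-standardized against the pooled twin subsamples, the natural norming
population; both the reference choice and the orientation steps are logged.

# Exploratory per-SNP and gene-based tests

Per-SNP association uses OLS of each phenotype on minor-allele count with
both variables z-standardized, so slopes are in SD units per SD of dosage
(a slope of 0.25 corresponds to d = 0.5 per allele copy); per-dosage group
means support allele-count plots, and the collection of p-values is
screened against Uniform(0,1) with a KS statistic and decile counts (a
descriptive check — inter-SNP LD makes the p-values dependent, and the
output says so).

The burden test aggregates rare variants (MAF strictly < 0.01) into a
per-sample carrier proportion — the fraction of rare sites at which the
sample carries at least one minor allele, robust to per-gene variant count;
an allele-count coding is available — and regresses the phenotype on it.
The variance-component test is the standard linear-model score test
$Q = r^\top G_W G_W^\top r$ with Beta(1, 25) MAF weights (flat optional)
and an intercept-only null, with the p-value from the mixture of 1-df
chi-squares via a moment-matching noncentral-chi-square approximation;
Imhof's exact characteristic-function inversion is available as an option,
and a rank-one kernel is evaluated in closed form (exactly the
single-variant score test). Multiplicity is summarized by the Bonferroni
threshold $\alpha/(\text{SNPs} \times \text{phenotypes})$ — 0.05/(47×3) =
0.00035 at two significant figures.

# Power analysis and ascertainment bias

The registered design anticipated a standardized per-allele slope of 0.25.
The simulator draws a biallelic dosage (default frequency 0.5 — power
depends on the standardized slope, not the frequency), sets the phenotype
to $0.25 \times$ standardized dosage plus noise scaled to unit total
variance, and tests the slope one-tailed at $\alpha = 0.05$. At n = 150
this yields ~93–94% power (Fisher-z analytic cross-check: 92.7%).

Ascertainment is modelled by truncation sampling: ascertained individuals
are re-drawn until their phenotype falls below the threshold $c$ solving
$\varphi(c)/\Phi(c) = 0.9$, so their expected mean sits 0.9 SD below the
remainder. With n = 130 and half the sample ascertained, pooled-regression
power drops to ~86%, consistent with the registered figure of 87%. An
open design question was whether to condition on ascertainment status; we
implement both modes and default to the pooled regression (the simplest
reading of a slope test on the combined sample). The covariate-adjusted
mode loses considerably more power (~76%) because conditioning on the
truncation indicator removes the informative phenotype-tail variation
rather than restoring it.

# The synthetic cohort generator

The generator is the package's stand-in for the study data and defines the
conditions every downstream test runs under:

* **Genotypes.** A Gaussian copula at the *haplotype* level: each haplotype
  thresholds a latent multivariate normal at the allele-frequency quantile;
  a genotype is the sum of two independent haplotypes. HWE therefore holds
  exactly at generation, and the dosage correlation between SNPs equals the
  allele-indicator correlation, which is calibrated numerically (uniroot
  over the bivariate-normal orthant probability) so realized r² matches the
  target without thresholding attenuation. Infeasible (non-PSD) targets are
  rejected with a diagnostic. The default 47-SNP panel (24 *CNTNAP2* — the
  array SNPs plus rs2710102 and rs7794745 — and 23 *NRXN1*) engineers six
  and eight SNP pairs with r² > 0.8 respectively, mirroring the reported LD
  summaries; it makes no attempt to copy the real (unavailable) allele
  frequencies.
* **Twins.** Four parental haplotypes per pair; each twin draws one
  maternal and one paternal transmission. MZ co-twins copy the same
  transmissions (identical genotypes); DZ co-twins draw independently
  (expected IBD 0.5, within-pair dosage correlation 0.5). One-per-pair
  splitting assigns each complete pair's members to opposite subsamples;
  singleton pairs (missing co-twin DNA) go to a random subsample, which can
  make the subsamples unequal.
* **Phenotypes.** One latent factor; the three measures load on it with
  loadings solved in closed form from the observed correlations
  (0.76/0.60/0.69), giving loadings (0.813, 0.935, 0.738). Four language
  subtests are generated from the language measure (loadings ~0.75–0.85,
  a realistic subtest reliability). The gene effect enters the latent
  factor through the standardized equal-weight sum of the causal block's
  dosages; `sct_multiplier` amplifies it in the SCT group only, which is
  how a double hit is injected and how parameter-recovery power ordering is
  tested.
* **Ascertainment.** The SCT group is selected from a candidate pool:
  the representative ("prenatal") subgroup is drawn first, then the
  ascertained subgroup by truncation on the language factor (the measure
  the study quantified the bias on); drawing the representative subgroup
  first keeps both subgroup means on target. Defaults: 130 cases, 59
  postnatally ascertained, shift 0.9 SD, karyotypes 42/43/45, 185 twin
  pairs with one third MZ.

What the generator does *not* emulate: real allele-frequency spectra and
fine-scale LD, shared twin environment (MZ phenotype correlation beyond
genetics), age/sex structure, instrument-specific measurement error, and
informative missingness (missing-data injection is available but MCAR and
off by default, since the study reports no rates). Passing tests therefore
demonstrate the *methods* behave correctly under the study's statistical
structure, not that the original cohort's numbers are reproduced — the
original genotypes are not available, and the headline permutation
p-values are anchored only by calibration properties (null uniformity,
type-I error, power ordering), not by value.

# Problem sizes and reproducibility

Simulation-based checks use deliberately chosen desk scales: null
calibration of the permutation test uses 200 replicate cohorts of n = 500
with B = 500 permutations; gene-based test calibration uses 500 replicates
of n = 1000 with 20 variants; power results use 10,000–20,000 Monte-Carlo
replicates (binomial SE ~0.2–0.3 percentage points). Every generator and
test derives its randomness from an explicit seed; the pipeline driver
(`run_pipeline()`) derives all stage seeds from one master seed and writes
an MD5 manifest, and re-running a configuration reproduces every output
file byte for byte.

# Known limitations

* The ALS criterion is guaranteed non-increasing but, like all alternating
  schemes, converges to a stationary point; with strongly collinear blocks
  different initializations could reach different weights. The fixed
  equal-weight initialization keeps results deterministic.
* The moment-matching SKAT p-value is an approximation; it is exact for
  rank-one kernels and accurate in the tails, but can deviate by a few
  hundredths mid-distribution (the Imhof option is exact to quadrature
  tolerance).
* Heterozygosity filtering recomputes its band only on the input set; on
  pathological inputs the cascade need not be idempotent, though it is on
  realistic data and on the constructed fixtures.
* The per-gene component model estimates one path per gene; it does not
  localize signal to individual SNPs (that is what the exploratory per-SNP
  scan is for).
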