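---
title: "Partitioning feed-efficiency variance between host genetics and the gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning feed-efficiency variance between host genetics and the gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfe)
```

## The problem

Feed conversion ratio (FCR = cumulative feed intake / body-weight gain) is
the standard feed-efficiency metric in meat poultry; lower is better. FCR is
shaped both by the bird's genome and by the microbial communities of its
intestinal tract, and the two are entangled: host variants influence which
taxa colonize each gut segment, and those taxa in turn influence energy
harvest. `microfe` implements the full quantitative-genetics workflow for
dissecting this entanglement in a cohort genotyped genome-wide and profiled
by 16S sequencing in four gut segments (duodenum, jejunum, ileum, cecum):

1. **Kernels.** A genomic relationship matrix (GRM) from reference-allele
   dosages, and one microbial relationship matrix (MRM) per segment from
   standardized taxon abundances.
2. **Variance components.** Average-information REML for the single-kernel
   animal model (SNP heritability of FCR, and of every taxon's abundance)
   and for the five-kernel model that partitions FCR variance into genetic,
   four segment-microbial, and residual fractions ("omics-explainability").
3. **Association.** Mixed-linear-model GWAS of FCR and mGWAS of heritable
   taxa, with Bonferroni thresholds, per-SNP variance explained, and
   LD-block delineation.
4. **Two-part microbiome-wide association** of taxa with FCR
   (presence/absence and log-abundance parts, BH-controlled).
5. **Integration.** The intersection of two-part hits, mGWAS-mapped taxa
   and genotype-differential taxa at trait-associated SNPs, which defines
   the host-genetics-influenced, FCR-associated taxa.

A seeded synthetic-data generator reproduces the assumed data-generating
process with retained ground truth, so every stage is exercised by
parameter-recovery experiments rather than fixtures.

## Models

### Relationship kernels

For dosages $x_{iz} \in \{0,1,2\}$ counting **reference** alleles (note:
most GWAS stacks count the alternate allele; the orientation flips effect
signs, never magnitudes or p-values) and sample reference-allele frequency
$\bar p_z$,

$$g_{ij} = \frac{1}{n}\sum_{z=1}^{n}
  \frac{(x_{iz} - 2\bar p_z)(x_{jz} - 2\bar p_z)}{2\bar p_z(1-\bar p_z)}.$$

$\bar p_z$ is estimated from the analyzed sample — the only estimator
available. Missing dosages are mean-imputed inside kernel and association
computations only; storage keeps the explicit missing marker. Monomorphic
variants (zero denominator) are an error by design: `filter_variants()`
(missing rate, MAF, exact Hardy-Weinberg) runs first.

The per-segment MRM is the analogous standardized cross-product over taxa,
$m_{sij} = \frac{1}{t_s}\sum_a z_{ia} z_{ja}$ with $z$ the per-taxon
z-scores. Two conventions are pinned down here because they change the
numbers:

* **Unbiased (n−1) variance** in the z-scores, matching common GRM/MRM
  software. Consequently the MRM's mean diagonal is exactly $(n-1)/n$, and
  its trace $n-1$.
* **CLR before standardization.** The taxa entering the MRM are centered
  log-ratio transformed first (`clr(x) = ln x - mean(ln x)` per sample),
  because the heritability and mGWAS stages operate on CLR abundances and
  the MRM should measure similarity on the same scale. A flag-free way to
  skip CLR is to pass a `zscore`- or `clr`-tagged table directly.

### Zero replacement before CLR

Zeros in 16S genus tables are censored low abundances, not structural
absences. The default replacement is therefore **half of each taxon's
smallest non-zero relative abundance** — its empirical detection limit —
applied multiplicatively so rows still close to 1. A global scalar
`pseudocount` override is exposed. We deliberately do not use the global
table minimum: it places absent samples many log-units below every taxon's
observed range, so the absent/present contrast dominates the CLR variance
of any zero-inflated taxon; in recovery experiments that artifact roughly
halves taxon-level heritability estimates and the within-present two-part
signal.

### REML

The mixed model is $y = Xa + \sum_k u_k + e$ with
$u_k \sim N(0, \sigma^2_k K_k)$. The optimizer is average-information REML
with step-halving and an expectation-maximization fallback whenever an AI
step fails to improve the restricted log-likelihood, so accepted iterations
are monotone. Convergence is declared at successive log-likelihood change
$< 10^{-8}$ (default `max_iter = 200`; non-convergence is flagged, never
silent). Components whose update turns negative are pinned at a floor of
$10^{-6}\,\sigma^2_p$. Standard errors come from the inverse AI matrix,
ratio SEs by the delta method. For repeated single-kernel fits (the
heritable-taxon screen, the association null model) an equivalent spectral
path is used: one eigendecomposition of the GRM, then a one-dimensional
profiled optimization over $\lambda = \sigma^2_g/\sigma^2_e$ per trait.
Both paths maximize the same objective; the test suite checks they agree,
and that the AI-REML optimum matches a brute-force likelihood grid to
within $10^{-4}$.

Variance-component LRTs use the boundary null $\tfrac12\chi^2_0 +
\tfrac12\chi^2_1$ (so $p = \tfrac12 P(\chi^2_1 \ge \mathrm{LRT})$, and
$p = 0.5$ at LRT = 0); `mixture = FALSE` restores the plain $\chi^2_1$ used
by some tools. A taxon is flagged heritable when $h^2 > 0.2$ **and**
$p_{LRT} < 0.05$ jointly.

### Association

The scan fits the no-SNP null model once by REML, rotates everything into
the GRM eigenbasis, and tests each variant by weighted least squares with
weights $1/(\hat\lambda d_i + 1)$ — one $O(n)$ pass per variant after a
single eigendecomposition. The per-variant statistic is the Wald t with the
residual scale re-estimated per variant, so constraining $\lambda = 0$
reproduces ordinary least squares exactly (the suite checks agreement to
$10^{-10}$). An `exact` mode re-optimizes $\lambda$ per variant; it is
quadratic-cost and intended for small panels. The two modes agree to a
fraction of a percent for the vast majority of variants; the exceptions are
variants that genuinely realign the variance ratio when fitted jointly,
which is the reason the exact mode exists.

Per-SNP variance explained is reported as
$\mathrm{PVE} = \frac{2f(1-f)\beta^2}{2f(1-f)\beta^2 + 2f(1-f)\,
\mathrm{se}^2 n}$ — a convention computable from scan output alone, not a
model-derived quantity. Significance uses fixed Bonferroni thresholds
($0.05/n_{\text{tests}}$ genome-wide, $1/n_{\text{tests}}$ suggestive); no
FDR is applied to GWAS. LD blocks are maximal runs of map-consecutive
variants whose every **adjacent** pair has $r^2 > 0.8$ (composite LD:
squared Pearson correlation of unphased dosages); an all-pairs rule is
available by flag since the verbal definition admits both readings.

### Two-part MWAS and integration

Each taxon is tested twice against FCR: a presence/absence regression
(equivalent to the equal-variance two-sample t-test) where prevalence is
strictly between 0 and 1, and a log10-relative-abundance regression over
present samples only, requiring at least 10 present samples (guards against
near-degenerate regressions; the threshold is a package choice). Both parts
are written as intercept + slope regressions with residual error — a
regression without a residual term is not estimable. BH adjustment is
applied within part × segment, matching per-segment reporting; a taxon is a
key taxon at FDR < 0.05 in either part.

Genotype-stratified tests at trait-associated SNPs use one-way ANOVA plus
pairwise exact Wilcoxon rank-sum tests (exact enumeration when the combined
pair size is ≤ 20 without ties, normal approximation with tie correction
otherwise); genotype classes with fewer than 2 birds are dropped rather
than failing the scan. A taxon counts as genotype-differential when ANY
tested SNP gives ANOVA $p < 0.05$ (the aggregation rule is unstated in the
field; "any SNP" is the permissive reading and is configurable through the
differential table). The final integration retains membership in all four
evidence sets and defines the included set as genotype-differential AND
(binary hit OR abundance hit); included taxa are annotated with their
Pearson (default; Spearman available) correlation with FCR on the CLR
scale.

## The synthetic-data generator

`sim_config()` defaults encode the cohort the package is designed around:
313 individuals in two lines split 151:162, line allele frequencies
drifting around ancestral values with variance 0.05 (strong enough that the
leading genetic PC separates the lines completely), four segment tables
with genus counts 230/231/167/103 and 6/12/4/10 genetically driven taxa,
and the phenotype built bottom-up as

$$y = \text{intercept} + g + m_d + m_j + m_i + m_c + e$$

with variance fractions (0.3696, 0.0796, 0.0763, 0.0000, 0.1390) and the
residual filling the remainder. Components are centered and rescaled to
their exact sample-variance targets, so the reconstruction identity holds
elementwise and the realized fractions match the configuration to ±0.02 at
n ≥ 500 (without the planted taxon; see below). Building bottom-up from 30
causal SNPs — the largest carrying 25% of the genetic variance, so its
marginal PVE sits near 0.09–0.12 — lets one dataset exercise GWAS power and
variance-partition recovery simultaneously. Genetic effects are drawn per
standardized dosage, the architecture the GRM model assumes, so GREML
estimates the configured fraction without systematic distortion. Microbial
effects are weighted combinations of each segment's standardized CLR taxa,
i.e. exactly the construction whose covariance is the MRM, so the
configured fraction is exactly what MRM-REML estimates. The FCR column is
an affine recalibration of $y$ to mean 2.3, sd 0.25 (a plausible duck FCR
scale); every analysis in the package is invariant to that calibration, and
FI is backed out from a simulated body-weight gain so FCR = FI/BWG holds.

**Zeros are detection-limit censoring.** A taxon is recorded absent when
its latent log-abundance falls below the quantile of its zero-inflation
probability, so the marginal absence rate equals the configured probability
while a heritable taxon's absences still carry genetic signal. We chose
censoring over independent Bernoulli thinning deliberately: under
independent thinning the random absent/present contrast dominates the CLR
variance and caps a taxon's observed-scale heritability near 0.1 regardless
of its latent genetic fraction, which would make taxon-level recovery
experiments impossible and does not match how 16S zeros arise.

**Genetically driven taxa** have liabilities spread over 50 driver SNPs
(default). Single-locus liabilities were rejected after measurement: the
GREML screen estimate of a one-SNP taxon is unstable (conditional on the
SNP, the rank-one phenotypic covariance is nearly orthogonal to the GRM),
whereas 30–100 drivers give stable estimates — and heritable gut genera
are empirically polygenic with a handful of mappable loci.

**The planted key taxon** is the generator's end-to-end probe: one cecal
genus that is simultaneously heritable, FCR-associated and
genotype-differential. Its latent genetic fraction is 0.75 with 35% of the
liability on the phenotype's major causal SNP (negatively loaded: the
FCR-raising allele depletes the beneficial genus, matching its negative
weight on FCR), its zero-inflation is 0.12, and it carries 65% of the cecal
effect on the phenotype, residualized against the remaining taxa so the
share is exact. These latent values are calibrated to land the
**observed**-scale quantities near the real-data anchors — a screen
estimate around 0.45–0.5 and a taxon–FCR correlation around −0.25 to
−0.4 — after the attenuation that censoring, compositional closure and
PC-absorbed line structure impose (roughly a 35–50% loss from latent to
observed scale). Because the plant deliberately correlates the genetic and
cecal components (a mediated channel), the realized-fraction orthogonality
check applies to the unplanted generator.

## What the simulations do and do not show

The generator emulates: two diverged lines, Hardy-Weinberg genotypes within
line, zero-inflated compositional segment microbiomes with partially
host-genetic taxa, and a trait with additive genetic plus
microbial-compositional architecture. It does **not** emulate linkage
disequilibrium beyond line structure (variants are independent given line
frequencies), phylogenetic correlation among taxa, sequencing-depth noise,
ASV-level resolution, or genotype-by-environment effects. Passing recovery
tests therefore demonstrates the estimators are correct under their own
assumptions — unbiased variance partitioning, calibrated scans, working
integration logic — not that real 16S data meet those assumptions.

## Numerical choices and problem sizes

* Kernel symmetry enforced to 1e-10; eigenvalues ≥ −1e-8·λ_max clipped to
  zero with a warning ("bending"), anything lower is an error.
* REML tolerance 1e-8 on the restricted log-likelihood; component floor
  1e-6·σ²_p; SEs from the inverse AI matrix at the optimum.
* The spectral association path clips tiny negative GRM eigenvalues to 0.
* Exact Hardy-Weinberg p-values sum configuration probabilities ≤ the
  observed one, with a 1+1e-12 tie guard.
* Ties in BH adjustment resolve by the step-up definition (cumulative
  minimum on the sorted scale).
* Recovery experiments in the test and acceptance suites run at n = 500
  with 1,000 SNPs and 40-taxon segments (100 replicates single-kernel, 50
  five-kernel), scan calibration at n = 400 with 5,000 tested variants, and
  the end-to-end planted-signal experiment at the cohort's n = 313 with
  1,200 SNPs and 40/40/35/25 taxa over 20 seeds. These sizes keep each
  suite a few minutes long while leaving Monte-Carlo error well inside the
  asserted tolerances; they are stated here so the experiments are
  reproducible as specified.
* Recovery experiments use a single panmictic line: with two diverged
  lines, the top-PC covariates absorb the between-line share of the
  simulated genetic variance, so the configured fraction is no longer the
  estimand. The two-line structure is kept where it matters — population
  stratification control and the planted-signal run.

## Known limitations

* GREML estimates carry a small upward finite-sample bias (~0.02–0.03 at
  n = 500, p = 1,000) when causal variants are a subset of the kernel's
  variants and component variances are rescaled in-sample; the recovery
  tolerances account for it.
* The two-part abundance model tests log10 relative abundance, while
  effects are generated on standardized CLR scale; the scales differ by the
  per-sample row-mean log, which costs the abundance part power on heavily
  zero-inflated taxa. This mirrors the analysis choice of the original
  workflow rather than a statistical optimum.
* The `exact` association mode re-estimates the variance ratio per variant
  and can disagree with the fast mode by more than 10% in p for the ~1% of
  variants that realign the ratio; see the methods note above.
* No LD pruning before kernel PCA, no weighted GRMs, no conditional/joint
  association, no mediation analysis.
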