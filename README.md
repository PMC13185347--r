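# microfe

Integrated host-genetics × gut-microbiota analysis of feed efficiency.

`microfe` is for quantitative geneticists and microbiome researchers who
have a cohort genotyped genome-wide, profiled by 16S sequencing in several
intestinal segments, and phenotyped for feed conversion ratio
(FCR = feed intake / body-weight gain), and who want to answer, in one
tested workflow: how heritable is FCR; which variants drive it; which taxa
are under host-genetic control; which taxa associate with FCR; and how much
trait variance each layer explains.

## What it computes

**Relationship kernels.** The genomic relationship matrix from
reference-allele dosages,

    g_ij = (1/n) Σ_z (x_iz − 2p̄_z)(x_jz − 2p̄_z) / (2 p̄_z (1 − p̄_z)),

and a microbial relationship matrix per gut segment,
`M = Z Z' / t` for the z-scored (CLR-transformed) taxon matrix `Z`.

**Variance components.** Average-information REML (EM fallback,
monotone iterations) for the animal model `y = Xa + g + e` — SNP
heritability `h² = σ²_g / σ²_p` with a boundary-mixture likelihood-ratio
test — and for the five-kernel model
`y = Xa + g + m_d + m_j + m_i + m_c + e`, whose ratios are the
omics-explainabilities of FCR. A per-taxon screen flags heritable genera
(`h² > 0.2` and `P_LRT < 0.05`).

**Association.** Mixed-linear-model GWAS/mGWAS
(`y = Xa + xb + g + e`) via one GRM eigendecomposition and O(n) per
variant, Bonferroni thresholds (`0.05/n_tests`, `1/n_tests`), per-SNP
variance explained, LD `r²` and adjacent-`r² > 0.8` haplotype blocks.

**Two-part MWAS and integration.** Presence/absence and
log10-abundance regressions of each taxon against FCR with
Benjamini–Hochberg control, genotype-stratified ANOVA/Wilcoxon tests at
trait-associated SNPs, and the four-set evidence intersection that
nominates host-genetics-influenced, FCR-associated taxa.

**Synthetic data.** A seeded generator
(`sim_config()` → `generate_dataset()`) emulating the target study: 313
ducks from two diverged lines, four zero-inflated compositional segment
microbiomes with partially host-genetic genera, and an FCR assembled as
`fixed + polygenic + four microbial effects + residual` with retained
ground truth for recovery experiments.

## Worked example

```r
library(microfe)

cfg <- sim_config(n_individuals = 313, n_variants = 1200,
                  taxa_per_segment = c(duodenum = 40, jejunum = 40,
                                       ileum = 35, cecum = 25),
                  heritable_taxa_per_segment = c(duodenum = 2, jejunum = 3,
                                                 ileum = 1, cecum = 3),
                  seed = 1)
g   <- simulate_genotypes(cfg)
mic <- simulate_microbiota(cfg, g)
ph  <- simulate_phenotype(cfg, g, mic)

res <- run_pipeline(g, mic$tables, ph$phenotypes)

h <- res$heritability
sprintf("FCR h2 = %.3f (SE %.3f), LRT p = %.3g", h$h2$ratio, h$h2$se, h$p)
#> "FCR h2 = 0.505 (SE 0.142), LRT p = 0.000455"

res$gwas$thresholds
#> <significance_thresholds> 982 tests: genome-wide 5.09e-05, suggestive 0.00102

nrow(res$gwas$significant); mean(res$gwas$significant$pve)
#> 4 significant SNPs, mean PVE 9.0%

res$varpart$fit
#> <variance_decomposition> n=313, logLik=19.4116, converged in 107 iter
#>  component  variance       se     ratio
#>    genetic 9.819e-03 0.008051 1.641e-01
#>   duodenum 7.627e-03 0.003076 1.275e-01
#>    jejunum 1.797e-03 0.001694 3.003e-02
#>      ileum 5.991e-08 0.001279 1.001e-06
#>      cecum 1.125e-02 0.004355 1.881e-01
#>   residual 2.934e-02 0.007421 4.904e-01

subset(res$integration, included,
       c(segment, taxon, binary_hit, abundance_hit, mgwas_hit, r))
#>      segment    taxon binary_hit abundance_hit mgwas_hit          r
#> 3   duodenum duo_g003       TRUE         FALSE     FALSE  0.2229660
#> 120    cecum cec_g006       TRUE          TRUE      TRUE -0.4410421
```

Reading the output: the single-kernel fit estimates the SNP heritability of
FCR with its delta-method SE and boundary-mixture LRT p. The thresholds
object rescales the Bonferroni cut-offs to the 982 variants surviving QC in
this small panel. The five-kernel decomposition splits FCR variance across
host genetics, the four segment microbiotas and noise — here the genetic,
duodenal and cecal kernels carry most of the explained variance, and the
ileum is estimated at its zero boundary. The integration table nominates
taxa that are genotype-differential at FCR-associated SNPs *and* FCR-
associated in the two-part model; `cec_g006` is the generator's planted key
taxon, recovered in all four evidence sets with the expected negative FCR
correlation.

Each analysis stage is also callable on its own (`build_grm`, `reml_fit`,
`mlm_assoc`, `two_part_mwas`, ...), and a thin command-line driver with
`simulate | kernels | reml | gwas | mgwas | mwas | integrate | varpart`
subcommands over YAML configs ships at `inst/cli/microfe.R`.

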