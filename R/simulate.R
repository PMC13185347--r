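#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a cohort of diploid
#' individuals from one or two diverged lines, biallelic autosomal SNPs,
#' four segment-specific zero-inflated compositional microbiomes with
#' partially host-genetic taxon abundances, and a phenotype assembled as
#' `y = fixed + polygenic + four microbial random effects + residual`.
#'
#' Defaults mirror the duck feed-efficiency cohort the package is designed
#' around: n = 313 individuals in two lines (151:162), variance fractions
#' (genetic 0.3696; duodenum 0.0796; jejunum 0.0763; ileum 0; cecum 0.1390),
#' per-segment genus counts 230/231/167/103 with 6/12/4/10 genetically
#' driven taxa, 30 phenotype-causal SNPs of which the largest carries 25% of
#' the genetic variance, and an FCR scale of mean 2.3, sd 0.25. A "key"
#' taxon (default: a cecal genus whose latent log-abundance is 75%
#' genetic — calibrated so its OBSERVED CLR-scale heritability lands near
#' 0.45-0.5 after detection censoring and compositional closure — with
#' zero-inflation 0.12 and 65% of the cecal effect on the phenotype,
#' negatively directed) is planted as a jointly heritable,
#' trait-associated, genotype-differential genus for end-to-end recovery
#' experiments.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of biallelic SNPs.
#' @param n_chromosomes autosomes the SNPs are spread over.
#' @param n_lines 1 (panmictic) or 2 (diverged lines).
#' @param line_proportions relative line sizes (2 lines only).
#' @param drift_var variance of line-specific allele-frequency drift around
#'   the ancestral frequency.
#' @param maf_range ancestral minor-allele-frequency range, within (0, 0.5].
#' @param taxa_per_segment named integer vector (duodenum, jejunum, ileum,
#'   cecum).
#' @param heritable_taxa_per_segment genetically driven taxa per segment.
#' @param taxon_h2 genetic variance fraction of a driven taxon's latent
#'   log-abundance.
#' @param taxon_drivers causal SNPs per driven taxon.
#' @param zero_inflation_range per-taxon absence-probability range.
#' @param var_fractions named phenotype variance fractions (genetic,
#'   duodenum, jejunum, ileum, cecum); residual is `1 - sum`.
#' @param n_causal_snps causal SNPs for the phenotype's polygenic part.
#' @param major_snp_share share of the genetic variance carried by the
#'   top causal SNP (0 disables the major-SNP design).
#' @param key_taxon plant the key taxon (default `TRUE`).
#' @param key_segment,key_taxon_h2,key_taxon_zero_inflation,key_taxon_weight_share
#'   key-taxon settings: its segment, genetic fraction, absence probability,
#'   and share of that segment's effect on the phenotype.
#' @param key_major_share share of the key taxon's genetic liability carried
#'   by the phenotype's major causal SNP; the remainder is a polygenic tail
#'   over `taxon_drivers` SNPs (a genome-wide-heritable genus with one
#'   mappable locus, the architecture the mGWAS stage is designed to
#'   detect).
#' @param fcr_mean,fcr_sd affine calibration of the FCR column (cosmetic:
#'   all variance ratios are scale-invariant).
#' @param bwg_mean,bwg_sd body-weight-gain scale (g) used to back out feed
#'   intake as `FI = FCR * BWG`.
#' @param fixed_intercept intercept of the latent phenotype.
#' @param seed integer governing all randomness of the generator.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 313,
                       n_variants = 10000,
                       n_chromosomes = 39,
                       n_lines = 2,
                       line_proportions = c(ZF = 151, CF = 162) / 313,
                       drift_var = 0.05,
                       maf_range = c(0.05, 0.5),
                       taxa_per_segment = c(duodenum = 230, jejunum = 231,
                                            ileum = 167, cecum = 103),
                       heritable_taxa_per_segment = c(duodenum = 6,
                                                      jejunum = 12,
                                                      ileum = 4, cecum = 10),
                       taxon_h2 = 0.35,
                       taxon_drivers = 50,
                       zero_inflation_range = c(0.05, 0.5),
                       var_fractions = c(genetic = 0.3696,
                                         duodenum = 0.0796,
                                         jejunum = 0.0763,
                                         ileum = 0.0000,
                                         cecum = 0.1390),
                       n_causal_snps = 30,
                       major_snp_share = 0.25,
                       key_taxon = TRUE,
                       key_segment = "cecum",
                       key_taxon_h2 = 0.75,
                       key_taxon_zero_inflation = 0.12,
                       key_taxon_weight_share = 0.65,
                       key_major_share = 0.35,
                       fcr_mean = 2.3, fcr_sd = 0.25,
                       bwg_mean = 1750, bwg_sd = 150,
                       fixed_intercept = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  # tolerate list-valued vector arguments (e.g. from YAML configs)
  for (nm in c("line_proportions", "maf_range", "taxa_per_segment",
               "heritable_taxa_per_segment", "zero_inflation_range",
               "var_fractions")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (cfg$n_variants < 1) stop("n_variants must be >= 1")
  if (cfg$n_individuals < 2) stop("n_individuals must be >= 2")
  if (!cfg$n_lines %in% c(1, 2)) stop("n_lines must be 1 or 2")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (length(cfg$taxa_per_segment) != 4 ||
      !setequal(names(cfg$taxa_per_segment), SEGMENTS)) {
    stop("taxa_per_segment must name exactly the four gut segments")
  }
  cfg$taxa_per_segment <- cfg$taxa_per_segment[SEGMENTS]
  cfg$heritable_taxa_per_segment <- cfg$heritable_taxa_per_segment[SEGMENTS]
  if (any(cfg$heritable_taxa_per_segment > cfg$taxa_per_segment)) {
    stop("more genetically driven taxa than taxa in a segment")
  }
  vf <- cfg$var_fractions
  if (length(vf) != 5 ||
      !setequal(names(vf), c("genetic", SEGMENTS))) {
    stop("var_fractions must name genetic plus the four gut segments")
  }
  cfg$var_fractions <- vf[c("genetic", SEGMENTS)]
  if (any(vf < 0) || sum(vf) > 1) {
    stop("variance fractions must be >= 0 and sum to <= 1")
  }
  if (any(cfg$zero_inflation_range < 0) || any(cfg$zero_inflation_range >= 1)) {
    stop("zero-inflation probabilities must lie in [0, 1)")
  }
  cfg$key_segment <- match.arg(cfg$key_segment, SEGMENTS)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic (config-seeded) choice of the phenotype's causal SNPs among
# reasonably common variants; the first index is the major-effect SNP shared
# with the planted key taxon.
causal_snps <- function(cfg, g) {
  set.seed(cfg$seed + 101L)
  freq <- colMeans(impute_dosages(g)) / 2
  maf <- pmin(freq, 1 - freq)
  pool <- which(maf >= 0.1)
  if (length(pool) < cfg$n_causal_snps) pool <- which(maf > 0)
  if (length(pool) < cfg$n_causal_snps) {
    stop("not enough polymorphic variants for n_causal_snps")
  }
  idx <- sample(pool, cfg$n_causal_snps)
  list(idx = idx, major = idx[1])
}

#' Simulate genotypes for one or two diverged lines
#'
#' Each variant gets an ancestral reference-allele frequency drawn from the
#' configured MAF range (randomly oriented); with two lines, line-specific
#' frequencies are drawn around the ancestral value with the configured
#' drift variance and truncated to (0.01, 0.99). Genotypes are
#' `Binomial(2, line frequency)`. Output is sorted by chromosome and
#' position; line membership is attached as `attr(, "line")`.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; p <- cfg$n_variants
  samples <- sprintf("D%04d", seq_len(n))
  if (cfg$n_lines == 2) {
    n1 <- round(n * cfg$line_proportions[1] / sum(cfg$line_proportions))
    sizes <- c(n1, n - n1)
    line_names <- names(cfg$line_proportions) %||% c("L1", "L2")
    lines <- rep(line_names, sizes)
  } else {
    sizes <- n
    lines <- rep("L1", n)
  }
  maf <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  flip <- runif(p) < 0.5
  p0 <- ifelse(flip, 1 - maf, maf)      # reference-allele frequency
  dos <- matrix(NA_real_, n, p)
  offset <- 0
  for (l in seq_along(sizes)) {
    pl <- if (cfg$n_lines == 2) {
      pmin(pmax(p0 + rnorm(p, 0, sqrt(cfg$drift_var)), 0.01), 0.99)
    } else p0
    nl <- sizes[l]
    dos[offset + seq_len(nl), ] <-
      matrix(rbinom(nl * p, 2, rep(pl, each = nl)), nrow = nl)
    offset <- offset + nl
  }
  per_chrom <- diff(round(seq(0, p, length.out = cfg$n_chromosomes + 1)))
  chrom <- rep(sprintf("%d", seq_len(cfg$n_chromosomes)), per_chrom)
  pos <- unlist(lapply(per_chrom[per_chrom > 0], function(k) {
    sort(sample.int(1e8, k))
  }), use.names = FALSE)
  alleles <- vapply(seq_len(p), function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2))
  variants <- data.frame(chrom = chrom, pos = pos, ref = alleles[1, ],
                         alt = alleles[2, ], stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)   # match constructor ordering
  rownames(dos) <- samples
  g <- genotype_matrix(dos, variants)
  attr(g, "line") <- setNames(lines, samples)
  g
}

#' Simulate four segment-specific zero-inflated microbiomes
#'
#' Each taxon's latent log-abundance is a genetic liability (a standardized
#' weighted sum of its driver-SNP dosages, scaled to the configured genetic
#' fraction) plus Gaussian noise, on top of a taxon-specific base abundance.
#' A taxon is observed as absent when its latent value falls below the
#' quantile of its per-taxon zero-inflation probability (detection-limit
#' censoring, so each taxon's marginal absence rate equals its configured
#' probability while a heritable taxon's absences still carry genetic
#' signal); the observed value is `presence * exp(latent)` and rows are
#' closed to relative abundances. The planted key taxon is driven by the
#' phenotype's major causal SNP plus a polygenic tail.
#'
#' @param cfg a [sim_config()].
#' @param g genotypes from [simulate_genotypes()].
#' @return list with `tables` (named list of relative-scale
#'   [abundance_table()]s) and `truth` (per-segment driver/heritability
#'   bookkeeping, incl. latent genetic liabilities of the driven taxa).
#' @export
simulate_microbiota <- function(cfg, g) {
  stopifnot(inherits(cfg, "sim_config"), inherits(g, "genotype_matrix"))
  set.seed(cfg$seed + 1L)
  cs <- causal_snps(cfg, g)
  dos <- impute_dosages(g)
  n <- nrow(dos)
  tables <- list(); truth <- list()
  for (s in SEGMENTS) {
    t_s <- cfg$taxa_per_segment[[s]]
    h_s <- cfg$heritable_taxa_per_segment[[s]]
    taxa <- sprintf("%s_g%03d", substr(s, 1, 3), seq_len(t_s))
    driven <- if (h_s > 0) sort(sample(t_s, h_s)) else integer(0)
    is_key <- rep(FALSE, t_s)
    if (cfg$key_taxon && s == cfg$key_segment) {
      if (!length(driven)) driven <- 1L
      is_key[driven[1]] <- TRUE
    }
    mu <- rnorm(t_s, 0, 1.5)
    zi <- runif(t_s, cfg$zero_inflation_range[1], cfg$zero_inflation_range[2])
    h2 <- ifelse(seq_len(t_s) %in% driven, cfg$taxon_h2, 0)
    zi[is_key] <- cfg$key_taxon_zero_inflation
    h2[is_key] <- cfg$key_taxon_h2
    drivers <- vector("list", t_s)
    liab <- matrix(NA_real_, n, t_s)
    raw <- matrix(0, n, t_s, dimnames = list(rownames(dos), taxa))
    for (a in seq_len(t_s)) {
      if (h2[a] > 0) {
        std1 <- function(x) (x - mean(x)) / max(sd(x), .Machine$double.eps)
        if (is_key[a]) {
          # major mappable locus plus a polygenic tail; the loading is
          # negative so the trait-raising allele depletes the taxon, in
          # line with the taxon's negative weight on the trait
          drv <- c(cs$major, sample(setdiff(seq_len(ncol(dos)), cs$major),
                                    cfg$taxon_drivers))
          tail_gl <- std1(as.numeric(dos[, drv[-1], drop = FALSE] %*%
                                       rnorm(length(drv) - 1)))
          gl <- -sqrt(cfg$key_major_share) * std1(dos[, cs$major]) +
            sqrt(1 - cfg$key_major_share) * tail_gl
        } else {
          drv <- sample(ncol(dos), cfg$taxon_drivers)
          gl <- as.numeric(dos[, drv, drop = FALSE] %*% rnorm(length(drv)))
        }
        gl <- std1(gl)
        latent <- sqrt(h2[a]) * gl + sqrt(1 - h2[a]) * rnorm(n)
        drivers[[a]] <- drv
        liab[, a] <- gl
      } else {
        latent <- rnorm(n)
      }
      # zeros are detection-limit censoring: the taxon is unobserved when its
      # latent log-abundance falls below the zero-inflation quantile, so a
      # heritable taxon's absences carry genetic signal too
      presence <- as.numeric(latent > qnorm(zi[a]))
      raw[, a] <- presence * exp(mu[a] + latent)
    }
    zero_rows <- rowSums(raw) == 0
    if (any(zero_rows)) {   # pathological: give the sample its commonest taxon
      top <- which.max(mu)
      raw[zero_rows, top] <- exp(mu[top])
    }
    rel <- raw / rowSums(raw)
    tables[[s]] <- abundance_table(rel, s, scale = "relative")
    truth[[s]] <- list(taxa = taxa, driven = taxa[driven],
                       key_taxon = if (any(is_key)) taxa[is_key] else NULL,
                       h2 = setNames(h2, taxa),
                       zero_inflation = setNames(zi, taxa),
                       drivers = setNames(drivers[driven], taxa[driven]),
                       liabilities = liab[, driven, drop = FALSE])
  }
  list(tables = tables, truth = truth)
}

#' Simulate the phenotype from genotypes and microbiomes
#'
#' The polygenic value is a weighted sum of standardized causal-SNP dosages
#' (Gaussian weights; the major SNP's share fixed by the config), rescaled
#' so its sample variance equals the configured genetic fraction. Each
#' segment's microbial effect is a weighted combination of that segment's
#' standardized CLR taxa (so the configured fraction is exactly the
#' quantity an MRM-REML fit estimates), with the key taxon carrying its
#' configured share, negatively directed. The residual fills the remainder;
#' all components are centered and scaled to their exact target variances,
#' so the reconstruction `y = fixed + g + sum(m_k) + e` holds elementwise.
#' The FCR column is an affine recalibration of `y`; FI is backed out from
#' a plausible BWG so that `FCR = FI / BWG`.
#'
#' @param cfg a [sim_config()].
#' @param g genotypes from [simulate_genotypes()].
#' @param micro microbiomes from [simulate_microbiota()].
#' @return list with `phenotypes` (data.frame: sample, line, FI, BWG, FCR)
#'   and `truth` (components, causal effects, realized variance fractions).
#' @export
simulate_phenotype <- function(cfg, g, micro) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  cs <- causal_snps(cfg, g)
  dos <- impute_dosages(g)
  n <- nrow(dos)
  vf <- cfg$var_fractions
  v_res <- 1 - sum(vf)
  rescale <- function(x, target) {
    if (target <= 0) return(rep(0, n))
    x <- x - mean(x)
    x * sqrt(target / var(x))
  }
  # polygenic part
  beta_std <- rep(0, length(cs$idx))
  g_poly <- rep(0, n)
  if (vf[["genetic"]] > 0) {
    Z <- scale(dos[, cs$idx, drop = FALSE])
    share <- if (length(cs$idx) >= 2) cfg$major_snp_share else 1
    b_minor <- rnorm(length(cs$idx) - 1)
    part_major <- rescale(Z[, 1], vf[["genetic"]] * share)
    part_minor <- if (length(cs$idx) >= 2) {
      rescale(as.numeric(Z[, -1, drop = FALSE] %*% b_minor),
              vf[["genetic"]] * (1 - share))
    } else rep(0, n)
    g_raw <- part_major + part_minor
    g_poly <- rescale(g_raw, vf[["genetic"]])
    beta_std <- c(sqrt(vf[["genetic"]] * share / max(var(Z[, 1]), 1e-12)),
                  if (length(cs$idx) >= 2) {
                    b_minor * sqrt(vf[["genetic"]] * (1 - share) /
                                     max(var(as.numeric(
                                       Z[, -1, drop = FALSE] %*% b_minor)), 1e-12))
                  }) * sqrt(vf[["genetic"]] / max(var(g_raw), 1e-12))
  }
  # microbial parts
  m <- list()
  for (s in SEGMENTS) {
    target <- vf[[s]]
    if (target <= 0) { m[[s]] <- rep(0, n); next }
    z <- standardize_taxa(clr_transform(micro$tables[[s]]))$values
    key <- micro$truth[[s]]$key_taxon
    w <- rnorm(ncol(z))
    if (!is.null(key) && cfg$key_taxon_weight_share > 0) {
      k <- match(key, colnames(z))
      zk <- (z[, k] - mean(z[, k])) / sd(z[, k])
      others <- as.numeric(z[, -k, drop = FALSE] %*% w[-k])
      # residualize against the key taxon (compositional closure correlates
      # taxa) so the configured share is realized exactly
      others <- others - zk * (cov(zk, others) / var(zk))
      others <- rescale(others, 1 - cfg$key_taxon_weight_share)
      m_raw <- -sqrt(cfg$key_taxon_weight_share) * zk + others
    } else {
      m_raw <- as.numeric(z %*% w)
    }
    m[[s]] <- rescale(m_raw, target)
  }
  e <- rescale(rnorm(n), v_res)
  y <- cfg$fixed_intercept + g_poly + Reduce(`+`, m) + e
  fcr <- cfg$fcr_mean + cfg$fcr_sd * (y - mean(y)) / sd(y)
  bwg <- rnorm(n, cfg$bwg_mean, cfg$bwg_sd)
  line <- attr(g, "line") %||% setNames(rep("L1", n), rownames(dos))
  phen <- data.frame(sample = rownames(dos), line = unname(line[rownames(dos)]),
                     FI = fcr * bwg, BWG = bwg, FCR = fcr,
                     stringsAsFactors = FALSE)
  comps <- c(list(genetic = g_poly), m, list(residual = e))
  truth <- list(
    causal = data.frame(id = g$variants$id[cs$idx], index = cs$idx,
                        beta_std = beta_std, major = cs$idx == cs$major,
                        stringsAsFactors = FALSE),
    fixed = cfg$fixed_intercept,
    g = g_poly, m = m, e = e, y = y,
    realized_fractions = vapply(comps, var, numeric(1)) / var(y),
    fcr_calibration = c(mean = cfg$fcr_mean, sd = cfg$fcr_sd))
  list(phenotypes = phen, truth = truth)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs the three simulation stages under the config seed and writes: a VCF
#' of genotypes, one relative-abundance TSV per gut segment, a phenotype
#' TSV, a ground-truth JSON, and a manifest JSON of all realized
#' parameters. Repeated calls with the same config are byte-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, list with the simulated objects and file paths.
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  g <- simulate_genotypes(cfg)
  micro <- simulate_microbiota(cfg, g)
  phen <- simulate_phenotype(cfg, g, micro)
  paths <- list(genotypes = file.path(dir, "genotypes.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "manifest.json"))
  write_genotypes(g, paths$genotypes, format = "vcf")
  for (s in SEGMENTS) {
    paths[[paste0("abundance_", s)]] <- file.path(dir,
                                                  paste0("abundance_", s, ".tsv"))
    write_abundance(micro$tables[[s]], paths[[paste0("abundance_", s)]])
  }
  write_phenotypes(phen$phenotypes, paths$phenotypes)
  truth <- list(phenotype = phen$truth,
                microbiota = lapply(micro$truth, function(tr) {
                  tr$liabilities <- NULL; tr
                }),
                line = as.list(table(attr(g, "line"))))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config = unclass(cfg),
    n_individuals = nrow(g$dosages),
    n_variants = ncol(g$dosages),
    taxa_per_segment = vapply(micro$tables, function(t) ncol(t$values),
                              numeric(1)),
    realized_fractions = phen$truth$realized_fractions,
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genotypes = g, microbiota = micro, phenotypes = phen,
                 paths = paths))
}
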