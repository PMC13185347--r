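#' Run the integrated host-genetics x microbiota analysis end to end
#'
#' Chains every stage of the analysis on a dataset (simulated via
#' [generate_dataset()]-style objects, or loaded from files): variant QC and
#' GRM/PC construction; per-segment core-taxon filtering, CLR transform and
#' MRM construction; REML heritability of the trait with its LRT;
#' mixed-model GWAS with Bonferroni thresholds; the heritable-taxon screen;
#' mGWAS of heritable taxa; two-part microbiome-wide association;
#' genotype-stratified differential tests at the trait-associated SNPs; the
#' four-set evidence intersection; and five-kernel variance partitioning
#' (omics-explainability) with per-component LRTs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param tables named list of per-segment [abundance_table()]s (counts or
#'   relative scale).
#' @param phenotypes data.frame with `sample` and `FCR` columns, ordered as
#'   the genotypes.
#' @param n_pcs genetic principal components used as fixed covariates
#'   (default 5).
#' @param max_missing,min_maf,hwe_alpha variant QC thresholds, see
#'   [filter_variants()].
#' @param min_total_rel_abund,min_prevalence core-taxon thresholds, see
#'   [filter_core_taxa()].
#' @param max_diff_snps trait-associated SNPs (strongest first) carried into
#'   the genotype-differential stage (default 10; a runtime cap on the
#'   study design of testing every significant locus).
#' @param alpha significance level for differential tests and LRTs.
#' @param stages character vector of stages to run after the kernels
#'   (default all): any of `"reml"`, `"gwas"`, `"screen"`, `"mgwas"`,
#'   `"mwas"`, `"integrate"`, `"varpart"`. Stage dependencies are resolved
#'   automatically.
#' @return list with elements `kernels` (grm, mrms, pcs), `filtered`
#'   (genotypes, tables, clr tables), `heritability`, `gwas` (results,
#'   thresholds, significant hits, LD blocks), `screen`, `mgwas`, `mwas`,
#'   `differential`, `integration`, `varpart`.
#' @export
run_pipeline <- function(genotypes, tables, phenotypes, n_pcs = 5,
                         max_missing = 0.1, min_maf = 0.05, hwe_alpha = 1e-6,
                         min_total_rel_abund = 5e-4, min_prevalence = 0.30,
                         max_diff_snps = 10, alpha = 0.05,
                         stages = c("reml", "gwas", "screen", "mgwas",
                                    "mwas", "integrate", "varpart")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("integrate" %in% stages) {
    stages <- union(stages, c("gwas", "screen", "mgwas", "mwas"))
  }
  if ("mgwas" %in% stages) stages <- union(stages, "screen")
  stopifnot(inherits(genotypes, "genotype_matrix"),
            is.data.frame(phenotypes), "FCR" %in% names(phenotypes))
  if (!identical(as.character(phenotypes$sample),
                 rownames(genotypes$dosages))) {
    stop("phenotype samples must match the genotype sample order")
  }
  y <- phenotypes$FCR
  out <- list()

  g <- filter_variants(genotypes, max_missing, min_maf, hwe_alpha)
  grm <- build_grm(g)
  pcs <- kernel_pca(grm, n_pcs)
  rel <- lapply(tables, filter_core_taxa,
                min_total_rel_abund = min_total_rel_abund,
                min_prevalence = min_prevalence)
  clr <- lapply(rel, clr_transform)
  mrms <- lapply(clr, build_mrm)
  out$kernels <- list(grm = grm, mrms = mrms, pcs = pcs)
  out$filtered <- list(genotypes = g, relative = rel, clr = clr)
  X <- pcs$scores

  if ("reml" %in% stages) {
    fit <- reml_fit(y, X, list(genetic = grm))
    # residual-only restricted likelihood has a closed form; use it directly
    ll0 <- reml_null_loglik(y, cbind(Intercept = 1, X))
    lrt <- max(0, 2 * (fit$loglik - ll0))
    out$heritability <- list(fit = fit,
                             h2 = heritability(fit, "genetic"),
                             lrt = lrt,
                             p = 0.5 * pchisq(lrt, 1, lower.tail = FALSE))
  }
  if ("gwas" %in% stages) {
    res <- mlm_assoc(y, g, grm, X, feature = "FCR")
    thr <- significance_thresholds(sum(res$testable))
    sig <- res[res$testable & res$p < thr$suggestive, , drop = FALSE]
    blocks <- NULL
    if (nrow(sig) >= 2) {
      top_chrom <- names(sort(table(sig$chrom), decreasing = TRUE))[1]
      blocks <- tryCatch(
        ld_blocks(g, chrom = top_chrom,
                  start = min(sig$pos[sig$chrom == top_chrom]),
                  end = max(sig$pos[sig$chrom == top_chrom])),
        error = function(e) NULL)
    }
    out$gwas <- list(results = res, thresholds = thr, significant = sig,
                     blocks = blocks)
  }
  if ("screen" %in% stages) {
    out$screen <- screen_heritable_taxa(clr, grm, X)
  }
  if ("mgwas" %in% stages) {
    her <- out$screen[!is.na(out$screen$heritable) & out$screen$heritable, ]
    thr <- significance_thresholds(ncol(g$dosages))
    eig <- eigen(grm$values, symmetric = TRUE)
    hits <- list(); scans <- list()
    for (i in seq_len(nrow(her))) {
      seg <- her$segment[i]; taxon <- her$taxon[i]
      scan <- mlm_assoc(clr[[seg]]$values[, taxon], g, grm, X,
                        feature = paste(seg, taxon, sep = ":"), eig = eig)
      sig <- scan[scan$testable & scan$p < thr$suggestive, , drop = FALSE]
      scans[[paste(seg, taxon, sep = ":")]] <- scan
      if (nrow(sig)) {
        hits[[length(hits) + 1]] <-
          data.frame(segment = seg, taxon = taxon, snp = sig$id, p = sig$p,
                     stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(segment = character(), taxon = character(),
                 snp = character(), p = numeric())
    out$mgwas <- list(hits = hits, thresholds = thr, scans = scans)
  }
  if ("mwas" %in% stages) {
    out$mwas <- do.call(rbind, lapply(rel, function(t) two_part_mwas(y, t)))
    rownames(out$mwas) <- NULL
  }
  if ("integrate" %in% stages) {
    sig <- out$gwas$significant
    sig <- sig[order(sig$p), , drop = FALSE]
    sig <- head(sig, max_diff_snps)
    diff_rows <- list()
    fcr_diff <- list()
    for (i in seq_len(nrow(sig))) {
      snp <- sig$id[i]
      geno <- genotype_classes(g, snp)
      fcr_diff[[snp]] <- tryCatch(genotype_differential(y, geno, alpha),
                                  error = function(e) NULL)
      for (seg in names(clr)) {
        for (taxon in colnames(clr[[seg]]$values)) {
          gd <- tryCatch(
            genotype_differential(clr[[seg]]$values[, taxon], geno, alpha),
            error = function(e) NULL)
          if (!is.null(gd)) {
            diff_rows[[length(diff_rows) + 1]] <-
              data.frame(segment = seg, taxon = taxon, snp = snp,
                         F = gd$F, p_anova = gd$p_anova,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
    differential <- if (length(diff_rows)) do.call(rbind, diff_rows) else
      data.frame(segment = character(), taxon = character(),
                 snp = character(), F = numeric(), p_anova = numeric())
    mg_taxa <- unique(out$mgwas$hits[, c("segment", "taxon"), drop = FALSE])
    out$differential <- list(taxa = differential, fcr = fcr_diff,
                             snps = sig$id)
    out$integration <- integrate_taxa(out$mwas, mg_taxa, differential, y,
                                      clr, alpha = alpha)
  }
  if ("varpart" %in% stages) {
    kernels <- c(list(genetic = grm), mrms)
    full <- reml_fit(y, X, kernels)
    lrts <- lapply(names(kernels), function(comp) {
      red <- reml_fit(y, X, kernels[setdiff(names(kernels), comp)])
      lrt_component(full, red)
    })
    names(lrts) <- names(kernels)
    out$varpart <- list(fit = full, lrt = lrts,
                        ratios = setNames(full$components$ratio,
                                          full$components$component))
  }
  out
}

# Genotype class labels (e.g. "TT", "TG", "GG") at one variant id.
genotype_classes <- function(g, snp) {
  j <- match(snp, g$variants$id)
  if (is.na(j)) stop("unknown variant id: ", snp)
  v <- g$variants[j, ]
  codes <- c(`2` = paste0(v$ref, v$ref), `1` = paste0(v$ref, v$alt),
             `0` = paste0(v$alt, v$alt))
  unname(codes[as.character(g$dosages[, j])])
}
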