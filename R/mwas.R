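#' Two-part microbiome-wide association with a trait
#'
#' For each taxon of one segment, associates the feed conversion ratio (or
#' any trait) with (part 1) the taxon's presence/absence indicator and
#' (part 2) its log10 relative abundance over present samples only. Both
#' parts are intercept + slope regressions with a t-test on the slope; the
#' binary part is equivalent to the equal-variance two-sample t-test on the
#' present/absent split. P-values are Benjamini-Hochberg adjusted within
#' each part across the taxa of the segment, and a taxon is flagged as key
#' when either adjusted q-value is below `fdr`.
#'
#' The binary part is inapplicable (NA, not an error) when prevalence is 0
#' or 1; the quantitative part is inapplicable with fewer than
#' `min_present` present samples.
#'
#' @param y trait vector aligned with the table's samples.
#' @param t an [abundance_table()] on counts or relative scale.
#' @param min_present minimum present samples for the quantitative part
#'   (default 10).
#' @param fdr key-taxon FDR threshold (default 0.05).
#' @return data.frame with one row per taxon: `segment`, `taxon`,
#'   `prevalence`, `beta_bin`, `p_bin`, `q_bin`, `beta_ab`, `p_ab`, `q_ab`,
#'   `key`.
#' @export
two_part_mwas <- function(y, t, min_present = 10, fdr = 0.05) {
  rel <- to_relative(t)
  y <- as.numeric(y)
  if (length(y) != nrow(rel$values)) stop("y and table sample counts differ")
  v <- rel$values
  slope_test <- function(x, yy) {
    fit <- summary(lm(yy ~ x))$coefficients
    if (nrow(fit) < 2) return(c(NA_real_, NA_real_))
    c(fit[2, 1], fit[2, 4])
  }
  res <- lapply(colnames(v), function(a) {
    x <- v[, a]
    present <- x > 0
    prev <- mean(present)
    bin <- c(NA_real_, NA_real_)
    if (prev > 0 && prev < 1) bin <- slope_test(as.numeric(present), y)
    ab <- c(NA_real_, NA_real_)
    if (sum(present) >= min_present && sd(x[present]) > 0) {
      ab <- slope_test(log10(x[present]), y[present])
    }
    data.frame(segment = rel$segment, taxon = a, prevalence = prev,
               beta_bin = bin[1], p_bin = bin[2],
               beta_ab = ab[1], p_ab = ab[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_bin <- res$q_ab <- NA_real_
  ok_bin <- !is.na(res$p_bin)
  if (any(ok_bin)) res$q_bin[ok_bin] <- bh_adjust(res$p_bin[ok_bin])
  ok_ab <- !is.na(res$p_ab)
  if (any(ok_ab)) res$q_ab[ok_ab] <- bh_adjust(res$p_ab[ok_ab])
  res$key <- (!is.na(res$q_bin) & res$q_bin < fdr) |
    (!is.na(res$q_ab) & res$q_ab < fdr)
  res[, c("segment", "taxon", "prevalence", "beta_bin", "p_bin", "q_bin",
          "beta_ab", "p_ab", "q_ab", "key")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of p_(j) * m / j` on the sorted p-values, capped
#' at 1; order-preserving.
#'
#' @param p vector of p-values in `[0, 1]` (no NAs).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Genotype-stratified differential test
#'
#' Compares a numeric feature (taxon CLR abundance, or the trait itself)
#' across the genotype classes at one SNP: one-way ANOVA across all classes
#' plus exact Wilcoxon rank-sum tests for every class pair (exact
#' enumeration when the combined pair size is at most 20 and there are no
#' ties, normal approximation with tie correction otherwise). Classes with
#' fewer than 2 observations are dropped with a warning.
#'
#' @param values numeric vector.
#' @param genotypes per-sample genotype class labels (e.g. `"TT"`, `"TG"`,
#'   `"GG"`).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @return list with `group_sizes`, `F`, `p_anova`, `pairwise` (data.frame
#'   `g1`, `g2`, `p`), `significant`.
#' @export
genotype_differential <- function(values, genotypes, alpha = 0.05) {
  values <- as.numeric(values)
  genotypes <- as.character(genotypes)
  stopifnot(length(values) == length(genotypes))
  ok <- !is.na(values) & !is.na(genotypes)
  values <- values[ok]; genotypes <- genotypes[ok]
  sizes <- table(genotypes)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropped genotype class(es) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(genotypes %in% small)
    values <- values[keep]; genotypes <- genotypes[keep]
    sizes <- table(genotypes)
  }
  if (length(sizes) < 2) stop("need at least 2 genotype classes with >= 2 observations")
  fit <- anova(lm(values ~ factor(genotypes)))
  pairs_ <- combn(names(sizes), 2)
  pw <- apply(pairs_, 2, function(gg) {
    a <- values[genotypes == gg[1]]; b <- values[genotypes == gg[2]]
    exact <- (length(a) + length(b) <= 20) &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
  })
  list(group_sizes = as.integer(sizes) |> setNames(names(sizes)),
       F = fit$`F value`[1], p_anova = fit$`Pr(>F)`[1],
       pairwise = data.frame(g1 = pairs_[1, ], g2 = pairs_[2, ], p = pw,
                             stringsAsFactors = FALSE),
       significant = fit$`Pr(>F)`[1] < alpha)
}

#' Taxon-trait correlation
#'
#' Pearson (default) or Spearman correlation between a taxon's CLR
#' abundance and the trait, with the two-sided test p-value.
#'
#' @param abundance numeric vector (typically CLR scale).
#' @param y trait vector.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` and `p`.
#' @export
taxon_trait_correlation <- function(abundance, y,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(abundance) == length(y))
  if (length(y) < 3) stop("need at least 3 observations")
  if (sd(abundance) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- suppressWarnings(cor.test(abundance, y, method = method))
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}

#' Intersect the evidence for host-genetics-influenced, trait-associated taxa
#'
#' Combines (i) two-part association hits (binary and abundance parts),
#' (ii) taxa with mGWAS-identified SNPs, and (iii) taxa differing
#' significantly across genotypes at trait-associated SNPs. A taxon is
#' `included` when it is genotype-differential AND a hit in either two-part
#' part; membership in all four sets is retained for every taxon, and
#' included taxa are annotated with their trait correlation and its sign.
#'
#' @param two_part row-bound output of [two_part_mwas()] across segments.
#' @param mgwas_taxa data.frame with columns `segment`, `taxon`: taxa with
#'   at least one mGWAS-significant SNP (may have zero rows).
#' @param differential data.frame with columns `segment`, `taxon`, `snp`,
#'   `p_anova`: genotype-differential tests at trait-associated SNPs. A
#'   taxon counts as differential when ANY of its SNP tests has
#'   `p_anova < alpha`.
#' @param y trait vector.
#' @param tables named list of CLR [abundance_table()]s keyed by segment,
#'   used for the correlation annotation.
#' @param alpha genotype-differential significance level (default 0.05).
#' @param method correlation method, see [taxon_trait_correlation()].
#' @return data.frame with one row per taxon: `segment`, `taxon`,
#'   `binary_hit`, `abundance_hit`, `mgwas_hit`, `differential_hit`,
#'   `included`, `r`, `p_r`, `direction`.
#' @export
integrate_taxa <- function(two_part, mgwas_taxa, differential, y, tables,
                           alpha = 0.05, method = "pearson") {
  key <- function(df) paste(df$segment, df$taxon, sep = "\r")
  base_keys <- key(two_part)
  for (nm in c("mgwas_taxa", "differential")) {
    df <- get(nm)
    if (nrow(df)) {
      unmatched <- setdiff(key(df), base_keys)
      if (length(unmatched)) {
        stop("taxa in ", nm, " absent from the two-part results: ",
             paste(gsub("\r", ":", unmatched), collapse = ", "))
      }
    }
  }
  fdr_hit <- function(q) !is.na(q) & q < 0.05
  diff_keys <- if (nrow(differential)) {
    unique(key(differential[differential$p_anova < alpha, , drop = FALSE]))
  } else character(0)
  out <- data.frame(segment = two_part$segment, taxon = two_part$taxon,
                    binary_hit = fdr_hit(two_part$q_bin),
                    abundance_hit = fdr_hit(two_part$q_ab),
                    mgwas_hit = base_keys %in% key(mgwas_taxa),
                    differential_hit = base_keys %in% diff_keys,
                    stringsAsFactors = FALSE)
  out$included <- out$differential_hit & (out$binary_hit | out$abundance_hit)
  out$r <- out$p_r <- NA_real_
  out$direction <- NA_character_
  for (i in which(out$included)) {
    tab <- tables[[out$segment[i]]]
    if (is.null(tab) || !out$taxon[i] %in% colnames(tab$values)) next
    ct <- tryCatch(
      taxon_trait_correlation(tab$values[, out$taxon[i]], y, method = method),
      error = function(e) NULL)
    if (!is.null(ct)) {
      out$r[i] <- ct$r; out$p_r[i] <- ct$p
      out$direction[i] <- if (ct$r >= 0) "positive" else "negative"
    }
  }
  out
}
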