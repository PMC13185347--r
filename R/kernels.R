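#' Relationship-kernel container
#'
#' Symmetric positive-semidefinite n-by-n relationship matrix: a genomic
#' relationship matrix (GRM) built from genotype dosages, or a microbial
#' relationship matrix (MRM) built from standardized taxon abundances of one
#' gut segment. Symmetry is enforced to 1e-10. Eigenvalues slightly below
#' zero (>= -1e-8 times the largest) are clipped to zero with a warning
#' ("bending"); anything more negative is an error, since REML requires a
#' valid covariance kernel.
#'
#' @param values numeric n-by-n matrix.
#' @param kind `"GRM"` or `"MRM"`.
#' @param samples sample identifiers (default from rownames).
#' @param segment gut-segment label, required for MRMs.
#' @param check_psd verify positive semidefiniteness via an
#'   eigendecomposition (default `TRUE`; builders that are PSD by
#'   construction skip it).
#' @return An object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind = c("GRM", "MRM"),
                          samples = rownames(values), segment = NULL,
                          check_psd = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("kernel must be square")
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n) stop("sample labels do not match kernel dimension")
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (max(abs(values - t(values))) > 1e-10) {
    stop("kernel is not symmetric (max asymmetry ",
         format(max(abs(values - t(values)))), ")")
  }
  values <- (values + t(values)) / 2
  if (!is.null(segment)) segment <- match.arg(segment, SEGMENTS)
  if (kind == "MRM" && is.null(segment)) stop("an MRM needs a segment label")
  if (check_psd) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(ev, 0)
    if (min(ev) < -1e-8 * max(lmax, 1)) {
      stop("kernel is not positive semidefinite (min eigenvalue ",
           format(min(ev)), ")")
    }
    if (min(ev) < 0) {
      warning("clipped ", sum(ev < 0),
              " marginally negative eigenvalue(s) to zero (bending)")
      ed <- eigen(values, symmetric = TRUE)
      values <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
      values <- (values + t(values)) / 2
    }
  }
  dimnames(values) <- list(samples, samples)
  structure(list(values = values, kind = kind, segment = segment),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %s%s: %d x %d (mean diagonal %.3f)\n",
              x$kind, if (is.null(x$segment)) "" else paste0("/", x$segment),
              nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided test by full enumeration of heterozygote configurations
#' conditional on the allele counts: the p-value is the summed probability
#' of all configurations whose conditional probability does not exceed that
#' of the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts at one biallelic variant.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotyped individuals")
  n_a <- 2 * n_hom_ref + n_het           # reference-allele count
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible heterozygote counts
  # log-probability of each configuration, conditional on allele counts
  logp <- vapply(hets, function(h) {
    hom1 <- (rare - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) - (lchoose(2 * n, rare))
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count infeasible")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filter
#'
#' Drops variants failing any of: missing rate above `max_missing`,
#' minor-allele frequency below `min_maf`, or exact Hardy-Weinberg p-value
#' below `hwe_alpha`. Counts removed per criterion are reported via
#' `message()`.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated fraction of missing genotypes.
#' @param min_maf minimum minor-allele frequency.
#' @param hwe_alpha Hardy-Weinberg exact-test significance cut-off.
#' @return filtered [genotype_matrix()].
#' @export
filter_variants <- function(g, max_missing = 0.1, min_maf = 0.05,
                            hwe_alpha = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5,
            hwe_alpha >= 0, hwe_alpha <= 1)
  dos <- g$dosages
  miss <- colMeans(is.na(dos))
  fail_miss <- miss > max_missing
  p_ref <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_ref, 1 - p_ref)
  fail_maf <- is.na(maf) | maf < min_maf
  hwe_p <- rep(1, ncol(dos))
  todo <- which(!fail_miss & !fail_maf)
  for (j in todo) {
    x <- dos[, j]
    hwe_p[j] <- hwe_exact_test(sum(x == 2, na.rm = TRUE),
                               sum(x == 1, na.rm = TRUE),
                               sum(x == 0, na.rm = TRUE))
  }
  fail_hwe <- hwe_p < hwe_alpha
  keep <- !(fail_miss | fail_maf | fail_hwe)
  message(sprintf(
    "filter_variants: %d/%d retained (missing-rate removed %d, MAF removed %d, HWE removed %d)",
    sum(keep), ncol(dos), sum(fail_miss), sum(fail_maf & !fail_miss),
    sum(fail_hwe & !fail_miss & !fail_maf)))
  if (!any(keep)) {
    stop("all variants removed; review max_missing/min_maf/hwe_alpha thresholds")
  }
  genotype_matrix(dos[, keep, drop = FALSE], g$variants[keep, , drop = FALSE],
                  rownames(dos))
}

#' Core-microbiome taxon filter
#'
#' Keeps taxa whose mean relative abundance across samples is at least
#' `min_total_rel_abund` AND that are detected (abundance > 0) in at least
#' `min_prevalence` of samples (both thresholds inclusive). Remaining rows
#' are re-closed to sum to 1.
#'
#' @param t an [abundance_table()] on counts or relative scale.
#' @param min_total_rel_abund mean relative-abundance threshold
#'   (default 0.05%).
#' @param min_prevalence detection-prevalence threshold (default 30%).
#' @return filtered relative-scale [abundance_table()].
#' @export
filter_core_taxa <- function(t, min_total_rel_abund = 5e-4,
                             min_prevalence = 0.30) {
  t <- to_relative(t)
  rel <- t$values
  mean_ab <- colMeans(rel)
  prevalence <- colMeans(rel > 0)
  keep <- mean_ab >= min_total_rel_abund & prevalence >= min_prevalence
  message(sprintf(
    "filter_core_taxa [%s]: %d/%d taxa retained (abundance removed %d, prevalence removed %d)",
    t$segment, sum(keep), ncol(rel), sum(mean_ab < min_total_rel_abund),
    sum(prevalence < min_prevalence & mean_ab >= min_total_rel_abund)))
  if (!any(keep)) stop("all taxa removed by the core-microbiome filter")
  rel <- rel[, keep, drop = FALSE]
  rs <- rowSums(rel)
  if (any(rs <= 0)) {
    stop("sample(s) left with zero total abundance after filtering: ",
         paste(rownames(rel)[rs <= 0], collapse = ", "))
  }
  abundance_table(rel / rs, t$segment, scale = "relative", rank = t$rank)
}

#' Centered log-ratio transform
#'
#' Maps each sample's composition to unconstrained space:
#' `clr(x) = ln(x) - mean(ln(x))`. Zeros are first replaced by multiplicative
#' simple replacement: each zero becomes half that taxon's smallest non-zero
#' relative abundance (its empirical detection limit — zeros in 16S tables
#' are censored low abundances, so the replacement sits just below the
#' taxon's observed range) and the non-zero parts are shrunk proportionally
#' so each row still sums to 1. A scalar `pseudocount` overrides the
#' per-taxon rule. Every output row sums to 0 by construction.
#'
#' @param t an [abundance_table()] on counts or relative scale.
#' @param pseudocount zero-replacement value on the relative scale;
#'   `NULL` (default) uses half of each taxon's smallest non-zero relative
#'   abundance.
#' @return [abundance_table()] with `scale = "clr"`.
#' @export
clr_transform <- function(t, pseudocount = NULL) {
  t <- to_relative(t)
  rel <- t$values
  if (any(rowSums(rel > 0) == 0)) {
    stop("sample(s) with all-zero composition: ",
         paste(rownames(rel)[rowSums(rel > 0) == 0], collapse = ", "))
  }
  if (any(rel == 0)) {
    delta <- if (is.null(pseudocount)) {
      # per-taxon detection limit; table minimum for never-observed taxa
      apply(rel, 2, function(x) {
        if (any(x > 0)) 0.5 * min(x[x > 0]) else 0.5 * min(rel[rel > 0])
      })
    } else {
      stopifnot(pseudocount > 0)
      rep(pseudocount, ncol(rel))
    }
    repl <- matrix(delta, nrow(rel), ncol(rel), byrow = TRUE)
    n0w <- (rel == 0) %*% delta             # replaced mass per sample
    scaled <- rel * as.numeric(1 - n0w)     # multiplicative replacement
    scaled[rel == 0] <- repl[rel == 0]
    rel <- scaled / rowSums(scaled)
  }
  lx <- log(rel)
  clr <- lx - rowMeans(lx)
  abundance_table(clr, t$segment, scale = "clr", rank = t$rank)
}

#' Per-taxon z-score standardization
#'
#' Centers each taxon column to mean 0 and scales to unbiased (n-1) sample
#' variance 1. This is the normalization entering the microbial relationship
#' matrix.
#'
#' @param t an [abundance_table()].
#' @return [abundance_table()] with `scale = "zscore"`.
#' @export
standardize_taxa <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  v <- t$values
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance taxa cannot be standardized: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  z <- scale(v, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  abundance_table(z, t$segment, scale = "zscore", rank = t$rank)
}

#' Genomic relationship matrix
#'
#' For dosages `x` counting reference alleles and sample reference-allele
#' frequency `p_z` per variant,
#' `G[i,j] = (1/n) * sum_z (x_iz - 2 p_z)(x_jz - 2 p_z) / (2 p_z (1 - p_z))`
#' over the `n` variants. Missing dosages are mean-imputed per variant
#' before centering. Monomorphic variants make the denominator zero and are
#' an error; run [filter_variants()] first.
#'
#' @param g a [genotype_matrix()].
#' @return [kernel_matrix()] of kind `"GRM"`.
#' @export
build_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- impute_dosages(g)
  if (ncol(dos) < 1) stop("need at least one variant")
  p <- colMeans(dos) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic variant(s) present (zero denominator): ",
         paste(colnames(dos)[p <= 0 | p >= 1][1:min(3, sum(p <= 0 | p >= 1))],
               collapse = ", "), "; run filter_variants() first")
  }
  w <- sweep(sweep(dos, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  grm <- tcrossprod(w) / ncol(dos)
  kernel_matrix(grm, kind = "GRM", samples = rownames(dos), check_psd = FALSE)
}

#' Microbial relationship matrix
#'
#' Standardized cross-product of taxon abundances for one gut segment:
#' `M[i,j] = (1/t) * sum_a (x_ia - xbar_a)(x_ja - xbar_a) / s2_a`
#' with `t` taxa and unbiased per-taxon variance `s2_a`; equivalently
#' `M = Z Z' / t` for the z-scored matrix `Z`. With the (n-1) variance the
#' mean diagonal equals `(n-1)/n`.
#'
#' @param t a filtered [abundance_table()] (any scale; typically CLR);
#'   taxa must be non-constant.
#' @return [kernel_matrix()] of kind `"MRM"` tagged with the segment.
#' @export
build_mrm <- function(t) {
  z <- standardize_taxa(t)$values
  mrm <- tcrossprod(z) / ncol(z)
  kernel_matrix(mrm, kind = "MRM", samples = rownames(z),
                segment = t$segment, check_psd = FALSE)
}

#' Principal components of a relationship kernel
#'
#' Eigendecomposition of the double-centered kernel; component scores are
#' eigenvectors scaled by the square root of their eigenvalues, and
#' variance-explained fractions are eigenvalues over the centered trace.
#'
#' @param k a [kernel_matrix()].
#' @param n_components number of leading components (`<= n`).
#' @return list with `scores` (n x n_components matrix),
#'   `variance_explained` (fractions), and `values` (eigenvalues).
#' @export
kernel_pca <- function(k, n_components = 5) {
  stopifnot(inherits(k, "kernel_matrix"))
  n <- nrow(k$values)
  if (n_components > n) stop("n_components exceeds the number of samples")
  v <- k$values
  rm_ <- rowMeans(v)
  b <- v - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(v)
  ed <- eigen(b, symmetric = TRUE)
  lambda <- pmax(ed$values, 0)
  idx <- seq_len(n_components)
  scores <- ed$vectors[, idx, drop = FALSE] %*% diag(sqrt(lambda[idx]),
                                                     n_components)
  dimnames(scores) <- list(rownames(v), paste0("PC", idx))
  list(scores = scores,
       variance_explained = lambda[idx] / sum(lambda),
       values = lambda[idx])
}

#' Write a kernel matrix to text
#'
#' `format = "tsv"` writes a plain square table with sample ids as row and
#' column names. `format = "gcta"` writes the GCTA-compatible lower-triangle
#' text (columns: index i, index j, number of markers, value) plus a
#' companion `<path>.id` file with family/within-family ids.
#'
#' @param k a [kernel_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"gcta"`.
#' @param n_markers marker count recorded in the GCTA triangle (default `NA`).
#' @return `path`, invisibly.
#' @export
write_kernel <- function(k, path, format = c("tsv", "gcta"), n_markers = NA) {
  format <- match.arg(format)
  stopifnot(inherits(k, "kernel_matrix"))
  if (format == "tsv") {
    tab <- data.frame(sample = rownames(k$values), k$values,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- nrow(k$values)
    ij <- which(lower.tri(k$values, diag = TRUE), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    tri <- data.frame(i = ij[, 1], j = ij[, 2], n_markers = n_markers,
                      value = k$values[ij])
    write.table(tri, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(fid = rownames(k$values),
                           iid = rownames(k$values)),
                paste0(path, ".id"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a square-TSV kernel matrix
#'
#' @param path path written by [write_kernel()] with `format = "tsv"`.
#' @param kind `"GRM"` or `"MRM"`.
#' @param segment segment label for MRMs.
#' @return a [kernel_matrix()].
#' @export
read_kernel <- function(path, kind = c("GRM", "MRM"), segment = NULL) {
  kind <- match.arg(kind)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- as.character(tab[[1]])
  kernel_matrix(v, kind = kind, segment = segment, check_psd = FALSE)
}
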