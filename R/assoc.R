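#' Mixed-linear-model association scan
#'
#' Per-variant association of a feature (the trait for GWAS, or a taxon's
#' CLR abundance for mGWAS) under the polygenic model
#' `y = X a + x b + g + e`, `g ~ N(0, sigma2_g G)`. The default (`"fast"`)
#' mode fits the no-SNP null model once by REML, then tests every variant by
#' generalized least squares under the null-model covariance using the
#' spectral decomposition of the GRM: one eigendecomposition up front, then
#' O(n) work per variant. The `"exact"` mode re-optimizes the variance ratio
#' per variant (slow; intended for small panels and for validating the fast
#' mode). Effects are per copy of the reference allele; missing dosages are
#' mean-imputed; monomorphic variants are flagged untestable rather than
#' dropped.
#'
#' @param y numeric feature vector.
#' @param g a [genotype_matrix()] with the variants to test.
#' @param grm a [kernel_matrix()] of kind `"GRM"` sharing the sample order
#'   of `y`.
#' @param covariates fixed covariates (e.g. top genetic PCs), or `NULL`.
#' @param method `"fast"` (null-model variance components reused across
#'   variants) or `"exact"` (per-variant REML).
#' @param lambda optional fixed variance ratio `sigma2_g / sigma2_e`
#'   overriding the REML estimate; `lambda = 0` reduces every test to
#'   ordinary least squares.
#' @param feature label recorded in the output (default `"trait"`).
#' @param eig optional precomputed `eigen(grm$values, symmetric = TRUE)`,
#'   reusable across scans that share the GRM (e.g. mGWAS over many taxa).
#' @return data.frame ordered by chromosome/position with columns `chrom`,
#'   `pos`, `ref`, `alt`, `id`, `freq` (reference-allele frequency), `beta`,
#'   `se`, `stat` (Wald t), `p`, `pve`, `testable`, `feature`. The fitted
#'   `lambda` and the per-test residual df are attached as attributes.
#' @export
mlm_assoc <- function(y, g, grm, covariates = NULL,
                      method = c("fast", "exact"), lambda = NULL,
                      feature = "trait", eig = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(g, "genotype_matrix"), inherits(grm, "kernel_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(g$dosages) != n || nrow(grm$values) != n) {
    stop("y, genotypes and kernel must share the sample ordering")
  }
  dos <- impute_dosages(g)
  freq <- colMeans(dos) / 2
  testable <- freq > 0 & freq < 1
  if (is.null(eig)) eig <- eigen(grm$values, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  X <- cbind(Intercept = rep(1, n), covariates)
  q <- ncol(X)
  ystar <- as.numeric(crossprod(U, y))
  Xstar <- crossprod(U, X)
  if (is.null(lambda)) {
    null_fit <- reml_single_spectral(y, X, eig)
    lambda <- null_fit$lambda
  }
  Gstar <- crossprod(U, dos)
  p_var <- ncol(dos)
  beta <- se <- stat <- pval <- rep(NA_real_, p_var)
  df <- n - q - 1
  run_gls <- function(lam, cols) {
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xstar, Xstar * w)
    XtWXinv_Xw <- solve(XtWX, t(Xstar * w))
    # Frisch-Waugh: residualize y and each dosage column on the covariates
    ytil <- ystar - Xstar %*% (XtWXinv_Xw %*% ystar)
    Gt <- Gstar[, cols, drop = FALSE]
    Gtil <- Gt - Xstar %*% (XtWXinv_Xw %*% Gt)
    sxx <- colSums(w * Gtil^2)
    sxy <- colSums(w * Gtil * as.numeric(ytil))
    syy <- sum(w * ytil^2)
    b <- sxy / sxx
    rss <- pmax(syy - b * sxy, 0)
    s2 <- rss / df
    se_ <- sqrt(s2 / sxx)
    list(beta = b, se = se_)
  }
  if (method == "fast") {
    cols <- which(testable)
    if (length(cols)) {
      fit <- run_gls(lambda, cols)
      beta[cols] <- fit$beta
      se[cols] <- fit$se
    }
  } else {
    for (j in which(testable)) {
      Xj <- cbind(X, dos[, j])
      fitj <- reml_single_spectral(y, Xj, eig)
      lamj <- fitj$lambda
      w <- 1 / (lamj * d + 1)
      Xjs <- cbind(Xstar, Gstar[, j])
      XtWX <- crossprod(Xjs, Xjs * w)
      bhat <- solve(XtWX, crossprod(Xjs, ystar * w))
      r <- ystar - Xjs %*% bhat
      s2 <- sum(w * r^2) / df
      covb <- solve(XtWX) * s2
      beta[j] <- bhat[q + 1]
      se[j] <- sqrt(covb[q + 1, q + 1])
    }
  }
  stat <- beta / se
  pval <- 2 * pt(-abs(stat), df = df)
  pve <- rep(NA_real_, p_var)
  pve[testable] <- snp_pve(beta[testable], se[testable], freq[testable], n)
  out <- data.frame(g$variants[, c("chrom", "pos", "ref", "alt", "id")],
                    freq = freq, beta = beta, se = se, stat = stat,
                    p = pval, pve = pve, testable = testable,
                    feature = feature, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  attr(out, "df") <- df
  out
}

#' Per-variant proportion of phenotypic variance explained
#'
#' `PVE = 2f(1-f) beta^2 / (2f(1-f) beta^2 + 2f(1-f) se^2 n)`, a function of
#' the estimated effect, its standard error, the allele frequency and the
#' sample size. This estimator is a reporting convention for
#' association output (it requires nothing beyond the scan results), not a
#' model quantity.
#'
#' @param beta estimated allelic effect.
#' @param se its standard error (`> 0`).
#' @param freq allele frequency in (0, 1).
#' @param n sample size (`> 1`).
#' @return PVE fraction in `[0, 1)`. Vectorized; NA in, NA out.
#' @export
snp_pve <- function(beta, se, freq, n) {
  ok <- !is.na(beta) & !is.na(se) & !is.na(freq)
  if (any(freq[ok] <= 0 | freq[ok] >= 1)) {
    stop("allele frequency must lie strictly in (0, 1)")
  }
  if (any(se[ok] <= 0) || any(n <= 1)) stop("need se > 0 and n > 1")
  v <- 2 * freq * (1 - freq)
  (v * beta^2) / (v * beta^2 + v * se^2 * n)
}

#' Bonferroni significance thresholds
#'
#' Genome-wide threshold `0.05 / n_tests` and suggestive threshold
#' `1 / n_tests`; kept at full precision internally and rounded to 3
#' significant digits only for display.
#'
#' @param n_tests number of variants tested (`>= 1`).
#' @return object of class `significance_thresholds` with fields `n_tests`,
#'   `genome_wide`, `suggestive`.
#' @export
significance_thresholds <- function(n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a single value >= 1")
  }
  structure(list(n_tests = n_tests, genome_wide = 0.05 / n_tests,
                 suggestive = 1 / n_tests),
            class = "significance_thresholds")
}

#' @export
print.significance_thresholds <- function(x, ...) {
  cat(sprintf("<significance_thresholds> %s tests: genome-wide %s, suggestive %s\n",
              format(x$n_tests, big.mark = ","),
              format(signif(x$genome_wide, 3)),
              format(signif(x$suggestive, 3))))
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors (composite LD on
#' unphased genotypes); individuals missing either genotype are dropped.
#'
#' @param g a [genotype_matrix()].
#' @param i,j variant column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$dosages[, i]; yv <- g$dosages[, j]
  ok <- !is.na(x) & !is.na(yv)
  x <- x[ok]; yv <- yv[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(yv) == 0) {
    stop("LD undefined for monomorphic/zero-variance dosage vectors")
  }
  cor(x, yv)^2
}

#' Haplotype-block delineation from adjacent LD
#'
#' Default rule: maximal runs of map-consecutive variants in which every
#' ADJACENT pair has `r2 > r2_threshold`; singletons are not blocks. The
#' `"allpairs"` rule additionally requires every pair within the run to
#' exceed the threshold (greedy left-to-right extension). Block spans are
#' closed intervals from the first to the last member position.
#'
#' @param g a [genotype_matrix()].
#' @param chrom chromosome to scan (default: the only chromosome present).
#' @param start,end optional closed base-pair interval bounds.
#' @param r2_threshold LD threshold (default 0.8, exclusive).
#' @param rule `"adjacent"` (default) or `"allpairs"`.
#' @return data.frame with one row per block: `chrom`, `start`, `end`,
#'   `n_snps`, `min_r2` (minimum adjacent r2 inside the block), and a list
#'   column `members` of variant indices into `g`.
#' @export
ld_blocks <- function(g, chrom = NULL, start = NULL, end = NULL,
                      r2_threshold = 0.8, rule = c("adjacent", "allpairs")) {
  rule <- match.arg(rule)
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  if (is.null(chrom)) {
    if (length(unique(v$chrom)) > 1) stop("specify chrom: several present")
    chrom <- v$chrom[1]
  }
  sel <- which(v$chrom == chrom &
                 (is.null(start) | v$pos >= (start %||% -Inf)) &
                 (is.null(end) | v$pos <= (end %||% Inf)))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      min_r2 = numeric())
  empty$members <- list()
  if (length(sel) < 2) return(empty)
  sel <- sel[order(v$pos[sel])]
  r2_pair <- function(i, j) {
    tryCatch(ld_r2(g, i, j), error = function(e) NA_real_)
  }
  adj <- vapply(seq_len(length(sel) - 1),
                function(k) r2_pair(sel[k], sel[k + 1]), numeric(1))
  linked <- !is.na(adj) & adj > r2_threshold
  blocks <- list()
  k <- 1
  while (k <= length(sel)) {
    if (k < length(sel) && linked[k]) {
      end_k <- k + 1
      while (end_k < length(sel) && linked[end_k]) {
        if (rule == "allpairs") {
          cand <- sel[end_k + 1]
          all_ok <- all(vapply(sel[k:end_k], function(i) {
            r2 <- r2_pair(i, cand); !is.na(r2) && r2 > r2_threshold
          }, logical(1)))
          if (!all_ok) break
        }
        end_k <- end_k + 1
      }
      members <- sel[k:end_k]
      blocks[[length(blocks) + 1]] <-
        list(members = members, min_r2 = min(adj[k:(end_k - 1)]))
      k <- end_k + 1
    } else {
      k <- k + 1
    }
  }
  if (!length(blocks)) return(empty)
  out <- data.frame(
    chrom = chrom,
    start = vapply(blocks, function(b) min(v$pos[b$members]), numeric(1)),
    end = vapply(blocks, function(b) max(v$pos[b$members]), numeric(1)),
    n_snps = vapply(blocks, function(b) length(b$members), integer(1)),
    min_r2 = vapply(blocks, function(b) b$min_r2, numeric(1)),
    stringsAsFactors = FALSE)
  out$members <- lapply(blocks, `[[`, "members")
  out
}
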