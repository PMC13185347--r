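test_that("exact HWE test matches full enumeration on the 2-individual toy", {
  # counts (hom-ref=1, het=0, hom-alt=1): configurations het in {0,2} with
  # conditional probabilities 1/3 and 2/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  # equal-probability edge: all configurations counted
  expect_equal(hwe_exact_test(0, 2, 0), 1)
})

test_that("variant filter applies missingness, MAF and HWE rules", {
  dos <- cbind(rep(0, 20),                        # monomorphic, MAF 0
               c(rep(NA, 3), rep(1, 17)),         # missing rate 0.15
               rep(c(0, 1, 2, 1), 5),             # clean variant
               c(rep(0, 10), rep(2, 10)))         # extreme HWE violation
  g <- toy_genotypes(dos)
  f <- quiet(filter_variants(g, max_missing = 0.1, min_maf = 0.05,
                             hwe_alpha = 1e-4))
  expect_equal(ncol(f$dosages), 1L)
  expect_equal(unname(f$dosages[, 1]), rep(c(0, 1, 2, 1), 5))
  # the 2-individual toy is retained at the 1e-6 threshold (p = 1/3)
  g2 <- toy_genotypes(cbind(c(2, 0), c(1, 1)))
  f2 <- quiet(filter_variants(g2, min_maf = 0.05, hwe_alpha = 1e-6))
  expect_equal(ncol(f2$dosages), 2L)
  expect_error(quiet(filter_variants(toy_genotypes(cbind(rep(0, 4))))),
               "all variants removed")
})

test_that("core-taxon filter applies abundance and prevalence thresholds", {
  # taxon A: 10% everywhere; B: 0.01% everywhere; C: 5% in 1 of 4 samples
  v <- cbind(A = rep(0.10, 4), B = rep(1e-4, 4), C = c(0.05, 0, 0, 0))
  v <- cbind(v, filler = 1 - rowSums(v))
  t <- abundance_table(v, "cecum", scale = "relative")
  f <- quiet(filter_core_taxa(t))
  expect_setequal(colnames(f$values), c("A", "filler"))
  expect_equal(unname(rowSums(f$values)), rep(1, 4))
  # thresholds (0, 0) keep everything
  f0 <- quiet(filter_core_taxa(t, 0, 0))
  expect_equal(ncol(f0$values), 4L)
  # exactly 30% prevalence is retained (inclusive)
  v2 <- cbind(A = c(0.5, 0.5, 0.5, rep(0.5, 7)),
              B = c(rep(0.5, 3), rep(0, 7)))
  v2 <- v2 / rowSums(v2)
  t2 <- abundance_table(v2, "ileum", scale = "relative")
  f2 <- quiet(filter_core_taxa(t2, min_prevalence = 0.30))
  expect_true("B" %in% colnames(f2$values))
})

test_that("CLR transform matches direct evaluation and sums to zero", {
  u <- abundance_table(matrix(0.25, 1, 4), "cecum", scale = "relative")
  expect_equal(unname(clr_transform(u)$values[1, ]), rep(0, 4))
  w <- abundance_table(matrix(c(1/6, 1/6, 4/6), 1), "cecum",
                       scale = "relative")
  expect_equal(unname(clr_transform(w)$values[1, ]),
               c(-log(4) / 3, -log(4) / 3, 2 * log(4) / 3))
  set.seed(4)
  r <- toy_abundance(matrix(rexp(60) * rbinom(60, 1, 0.8), 6))
  expect_true(all(abs(rowSums(clr_transform(r)$values)) < 1e-9))
  allzero <- abundance_table(matrix(c(1, 0, 1, 0), 2), "cecum",
                             scale = "counts")
  expect_error(clr_transform(allzero), "zero total|all-zero")
})

test_that("taxon standardization uses the unbiased variance", {
  t <- abundance_table(cbind(a = c(1, 3), b = c(2, 4)), "jejunum",
                       scale = "clr")
  z <- standardize_taxa(t)
  expect_equal(unname(z$values[, "a"]), c(-1, 1) / sqrt(2))
  expect_equal(standardize_taxa(z)$values, z$values, tolerance = 1e-12)
  t2 <- abundance_table(cbind(a = c(1, 3), b = c(2, 2)), "jejunum",
                        scale = "clr")
  expect_error(standardize_taxa(t2), "b")
})

test_that("GRM matches the hand example and is near 1 on the diagonal", {
  g <- toy_genotypes(cbind(c(0, 1, 2)))
  grm <- build_grm(g)
  expect_equal(unname(grm$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3), tolerance = 1e-12)
  expect_error(build_grm(toy_genotypes(cbind(c(0, 0, 0)))), "monomorphic")
  # expectation of the diagonal under Hardy-Weinberg is 1
  set.seed(11)
  p <- runif(10000, 0.05, 0.5)
  dos <- matrix(rbinom(50 * 10000, 2, rep(p, each = 50)), nrow = 50)
  dos <- dos[, apply(dos, 2, sd) > 0, drop = FALSE]  # rare monomorphic draws
  big <- build_grm(toy_genotypes(dos))
  expect_gt(mean(diag(big$values)), 0.95)
  expect_lt(mean(diag(big$values)), 1.05)
})

test_that("MRM matches the hand example and the z-score cross-product", {
  t <- abundance_table(cbind(a = c(1, 3)), "cecum", scale = "clr")
  mrm <- build_mrm(t)
  expect_equal(unname(mrm$values), matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  set.seed(5)
  r <- toy_abundance(matrix(rexp(200), 10), segment = "duodenum")
  m <- build_mrm(clr_transform(r))
  z <- standardize_taxa(clr_transform(r))$values
  expect_equal(m$values, tcrossprod(z) / ncol(z), tolerance = 1e-10,
               ignore_attr = TRUE)
  # with the unbiased variance the mean diagonal is (n-1)/n
  expect_equal(mean(diag(m$values)), (10 - 1) / 10, tolerance = 1e-9)
  # permutation equivariance
  perm <- sample(10)
  m2 <- build_mrm(abundance_table(z[perm, ], "duodenum", scale = "zscore"))
  expect_equal(m2$values, m$values[perm, perm], ignore_attr = TRUE)
})

test_that("kernel builders yield symmetric PSD kernels on random fixtures", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    dos <- matrix(rbinom(n * 30, 2, runif(30, 0.1, 0.9)), n, byrow = FALSE)
    dos[, apply(dos, 2, sd) == 0] <- NA
    keep <- colSums(is.na(dos)) == 0
    grm <- build_grm(toy_genotypes(dos[, keep, drop = FALSE]))
    ev <- eigen(grm$values, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(grm$values - t(grm$values))), 1e-10)
    expect_gte(min(ev), -1e-8 * max(ev))
    r <- toy_abundance(matrix(rexp(n * 6) + 1e-3, n))
    mrm <- build_mrm(clr_transform(r))
    ev2 <- eigen(mrm$values, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev2), -1e-8 * max(ev2))
  }
})

test_that("kernel PCA explains rank-1 kernels and separates two lines", {
  v <- rnorm(8)
  k <- kernel_matrix(tcrossprod(v), kind = "GRM", check_psd = FALSE)
  pca <- kernel_pca(k, 3)
  expect_gt(pca$variance_explained[1], 0.999)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  expect_lte(sum(pca$variance_explained), 1 + 1e-9)
  expect_error(kernel_pca(k, 9), "n_components")
  # diverged lines separate completely on PC1
  cfg <- sim_config(n_individuals = 150, n_variants = 800, n_lines = 2,
                    drift_var = 0.05, key_taxon = FALSE, seed = 21)
  g <- simulate_genotypes(cfg)
  pcs <- kernel_pca(build_grm(quiet(filter_variants(g))), 2)
  line <- attr(g, "line")
  pc1 <- pcs$scores[, 1]
  expect_true(max(pc1[line == "ZF"]) < min(pc1[line == "CF"]) ||
                min(pc1[line == "ZF"]) > max(pc1[line == "CF"]))
})

test_that("kernels round-trip through square TSV and GCTA triangle text", {
  set.seed(2)
  grm <- sim_cohort(n = 12, p = 60, seed = 2)$grm
  path <- tempfile(fileext = ".tsv")
  write_kernel(grm, path, "tsv")
  back <- read_kernel(path, "GRM")
  expect_equal(back$values, grm$values, tolerance = 1e-12)
  gcta <- tempfile(fileext = ".grm.txt")
  write_kernel(grm, gcta, "gcta", n_markers = 60)
  tri <- read.table(gcta)
  expect_equal(nrow(tri), 12 * 13 / 2)
  expect_equal(tri$V4[tri$V1 == tri$V2], unname(diag(grm$values)))
  expect_true(file.exists(paste0(gcta, ".id")))
})
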