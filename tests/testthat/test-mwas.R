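# Two-part association, BH adjustment, genotype-stratified tests,
# correlations and the evidence intersection.

test_that("BH step-up matches the hand example, p.adjust and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  brute <- function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) {
      min(1, min(vapply(which(p >= p[i] - 1e-15), function(j) {
        p[j] * m / sum(p <= p[j] + 1e-15)
      }, numeric(1))))
    }, numeric(1))
  }
  set.seed(67)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(bh_adjust(p), brute(p), tolerance = 1e-12)
  }
  # order preservation
  p <- runif(30)
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
})

test_that("two-part model matches regression and t-test oracles", {
  y <- c(2.1, 2.4, 2.2, 2.6, 2.0, 2.5, 2.3, 2.35)
  # taxon A present everywhere (binary part inapplicable), B mixed
  ab <- cbind(A = c(0.2, 0.25, 0.22, 0.3, 0.21, 0.28, 0.24, 0.26),
              B = c(0.1, 0, 0.15, 0.2, 0, 0.12, 0, 0.18))
  ab <- cbind(ab, C = 1 - rowSums(ab))
  t <- abundance_table(ab, "jejunum", scale = "relative")
  res <- two_part_mwas(y, t, min_present = 3)
  a <- res[res$taxon == "A", ]
  expect_true(is.na(a$p_bin))
  ora <- summary(lm(y ~ log10(ab[, "A"])))$coefficients[2, ]
  expect_equal(a$beta_ab, unname(ora[1]))
  expect_equal(a$p_ab, unname(ora[4]))
  b <- res[res$taxon == "B", ]
  tt <- t.test(y[ab[, "B"] > 0], y[ab[, "B"] == 0], var.equal = TRUE)
  expect_equal(b$p_bin, tt$p.value)
  # too few present samples: quantitative part inapplicable
  res10 <- two_part_mwas(y, t, min_present = 10)
  expect_true(is.na(res10$p_ab[res10$taxon == "B"]))
  # rescaling all relative abundances leaves the quantitative t unchanged
  # (log10 of a constant multiple is an affine shift)
  y2 <- y
  ab2 <- ab / rowSums(ab)                 # closure is such a rescale per sample
  expect_equal(two_part_mwas(y2, abundance_table(ab2, "jejunum",
                                                 scale = "relative"),
                             min_present = 3)$p_bin,
               res$p_bin)
})

test_that("two-part results are invariant to sample and taxon order", {
  set.seed(71)
  n <- 40
  ab <- matrix(rexp(n * 4) * rbinom(n * 4, 1, 0.8), n)
  colnames(ab) <- letters[1:4]
  ab <- ab / rowSums(ab)
  rownames(ab) <- sprintf("s%02d", 1:n)
  y <- rnorm(n)
  t1 <- abundance_table(ab, "ileum", scale = "relative")
  r1 <- two_part_mwas(y, t1)
  perm <- sample(n)
  t2 <- abundance_table(ab[perm, c(3, 1, 4, 2)], "ileum", scale = "relative")
  r2 <- two_part_mwas(y[perm], t2)
  r2 <- r2[match(r1$taxon, r2$taxon), ]
  expect_equal(r1$p_bin, r2$p_bin)
  expect_equal(r1$p_ab, r2$p_ab)
  expect_equal(r1$q_ab, r2$q_ab)
})

test_that("genotype-stratified tests match exact Wilcoxon and hand ANOVA", {
  res <- genotype_differential(c(1, 2, 3, 4), c("TT", "TT", "GG", "GG"))
  expect_equal(res$pairwise$p, 1 / 3)     # enumeration of 6 rank assignments
  # textbook three-group ANOVA
  v <- c(1, 2, 3, 5, 6, 7, 9, 10, 11)
  gcl <- rep(c("AA", "AB", "BB"), each = 3)
  means <- tapply(v, gcl, mean)
  ssb <- 3 * sum((means - mean(v))^2)
  ssw <- sum((v - means[gcl])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res2 <- genotype_differential(v, gcl)
  expect_equal(res2$F, f_hand)
  expect_equal(res2$p_anova, pf(f_hand, 2, 6, lower.tail = FALSE))
  # classes with < 2 observations are dropped with a warning
  expect_warning(r3 <- genotype_differential(c(v, 99), c(gcl, "BC")),
                 "dropped")
  expect_equal(sum(r3$group_sizes), 9)
  expect_error(suppressWarnings(
    genotype_differential(c(1, 2, 3), c("a", "b", "c"))), "2 genotype")
})

test_that("ANOVA across genotypes holds its size under the null", {
  set.seed(73)
  rej <- vapply(1:400, function(i) {
    v <- rnorm(45)
    gcl <- sample(rep(c("TT", "TG", "GG"), each = 15))
    genotype_differential(v, gcl)$p_anova < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)
})

test_that("taxon-trait correlation matches the Pearson formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(taxon_trait_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(taxon_trait_correlation(x, -x)$r, -1)
  y <- c(2.0, 2.6, 2.1, 2.9, 2.4)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ct <- taxon_trait_correlation(x, y)
  expect_equal(ct$r, hand_r)
  expect_error(taxon_trait_correlation(rep(1, 5), y), "constant")
})

test_that("integration follows the four-set overlap logic", {
  two_part <- data.frame(
    segment = "cecum", taxon = c("A", "B", "C", "D"),
    prevalence = 0.8, beta_bin = 0.1,
    p_bin = c(0.001, 0.001, 0.5, 0.5), q_bin = c(0.01, 0.01, 0.9, 0.9),
    beta_ab = 0.1, p_ab = 0.5, q_ab = c(0.9, 0.9, 0.02, 0.9),
    key = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  differential <- data.frame(segment = "cecum", taxon = c("B", "C", "D"),
                             snp = "10:1", p_anova = c(0.01, 0.01, 0.5),
                             stringsAsFactors = FALSE)
  mg <- data.frame(segment = "cecum", taxon = "B", stringsAsFactors = FALSE)
  set.seed(79)
  n <- 30
  vals <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  tables <- list(cecum = abundance_table(vals, "cecum", scale = "clr"))
  y <- vals[, "B"] * -0.5 + rnorm(n, sd = 0.5)
  res <- integrate_taxa(two_part, mg, differential, y, tables)
  expect_equal(res$included, c(FALSE, TRUE, TRUE, FALSE))  # diff AND either part
  expect_equal(res$mgwas_hit, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$direction[2], "negative")
  expect_equal(sign(res$r[2]), -1)
  # empty mGWAS set: memberships false, overlaps unchanged
  res0 <- integrate_taxa(two_part, mg[0, ], differential, y, tables)
  expect_false(any(res0$mgwas_hit))
  expect_equal(res0$included, res$included)
  # unmatched keys are an error
  bad <- data.frame(segment = "cecum", taxon = "ZZZ", snp = "x",
                    p_anova = 0.01, stringsAsFactors = FALSE)
  expect_error(integrate_taxa(two_part, mg, bad, y, tables), "ZZZ")
})
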