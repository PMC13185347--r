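# The synthetic-data generator: determinism, the two-line construction,
# zero inflation, the reconstruction identity and on-disk bundles.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 60, n_variants = 150,
                    taxa_per_segment = c(duodenum = 10, jejunum = 10,
                                         ileum = 10, cecum = 10),
                    heritable_taxa_per_segment = c(duodenum = 1, jejunum = 1,
                                                   ileum = 1, cecum = 1),
                    seed = 83)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  m1 <- simulate_microbiota(cfg, g1); m2 <- simulate_microbiota(cfg, g2)
  expect_identical(m1$tables$cecum$values, m2$tables$cecum$values)
  p1 <- simulate_phenotype(cfg, g1, m1); p2 <- simulate_phenotype(cfg, g2, m2)
  expect_identical(p1$phenotypes$FCR, p2$phenotypes$FCR)
})

test_that("zero drift leaves the two lines undifferentiated", {
  cfg <- sim_config(n_individuals = 200, n_variants = 2000, drift_var = 0,
                    key_taxon = FALSE, seed = 89)
  g <- simulate_genotypes(cfg)
  line <- attr(g, "line")
  # Hudson-style Fst estimate per variant, averaged
  p1 <- colMeans(g$dosages[line == "ZF", ]) / 2
  p2 <- colMeans(g$dosages[line == "CF", ]) / 2
  n1 <- sum(line == "ZF"); n2 <- sum(line == "CF")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
    p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- mean(num) / mean(den)
  expect_lt(abs(fst), 0.01)
})

test_that("zero inflation is honored and vanishes in the zero limit", {
  cfg0 <- sim_config(n_individuals = 150, n_variants = 100,
                     zero_inflation_range = c(0, 0), key_taxon = FALSE,
                     taxa_per_segment = c(duodenum = 15, jejunum = 15,
                                          ileum = 15, cecum = 15),
                     heritable_taxa_per_segment = c(duodenum = 1, jejunum = 1,
                                                    ileum = 1, cecum = 1),
                     seed = 97)
  g <- simulate_genotypes(cfg0)
  mic0 <- simulate_microbiota(cfg0, g)
  expect_true(all(vapply(mic0$tables, function(t) all(t$values > 0),
                         logical(1))))
  cfg <- sim_config(n_individuals = 400, n_variants = 100,
                    zero_inflation_range = c(0.1, 0.4), key_taxon = FALSE,
                    taxa_per_segment = c(duodenum = 30, jejunum = 30,
                                         ileum = 30, cecum = 30),
                    heritable_taxa_per_segment = c(duodenum = 2, jejunum = 2,
                                                   ileum = 2, cecum = 2),
                    seed = 97)
  g <- simulate_genotypes(cfg)
  mic <- simulate_microbiota(cfg, g)
  for (s in c("duodenum", "cecum")) {
    zi <- mic$truth[[s]]$zero_inflation
    absent <- colMeans(mic$tables[[s]]$values == 0)
    sd3 <- 3 * sqrt(zi * (1 - zi) / 400)
    expect_true(all(abs(absent - zi) <= sd3 + 1e-9))
  }
})

test_that("the phenotype reconstructs exactly and hits its target fractions", {
  # key_taxon off: the planted taxon deliberately correlates the genetic
  # and cecal components (a mediated channel), so orthogonality of the
  # realized fractions is a property of the unplanted generator
  cfg <- sim_config(n_individuals = 500, n_variants = 400,
                    taxa_per_segment = c(duodenum = 25, jejunum = 25,
                                         ileum = 25, cecum = 25),
                    heritable_taxa_per_segment = c(duodenum = 2, jejunum = 2,
                                                   ileum = 2, cecum = 2),
                    key_taxon = FALSE, seed = 101)
  g <- simulate_genotypes(cfg)
  mic <- simulate_microbiota(cfg, g)
  ph <- simulate_phenotype(cfg, g, mic)
  tr <- ph$truth
  recon <- tr$fixed + tr$g + Reduce(`+`, tr$m) + tr$e
  expect_equal(tr$y, recon, tolerance = 1e-12)
  expect_true(all(abs(tr$realized_fractions[c("genetic", "duodenum",
                                              "jejunum", "ileum", "cecum")] -
                        cfg$var_fractions) <= 0.02))
  # FCR calibration and FI/BWG consistency
  expect_equal(mean(ph$phenotypes$FCR), 2.3, tolerance = 1e-9)
  expect_equal(sd(ph$phenotypes$FCR), 0.25, tolerance = 1e-9)
  expect_equal(ph$phenotypes$FI / ph$phenotypes$BWG, ph$phenotypes$FCR)
})

test_that("null phenotypes yield near-zero explainability everywhere", {
  ratios <- sapply(1:5, function(s) {
    cfg <- sim_config(n_individuals = 300, n_variants = 300,
                      var_fractions = c(genetic = 0, duodenum = 0,
                                        jejunum = 0, ileum = 0, cecum = 0),
                      taxa_per_segment = c(duodenum = 15, jejunum = 15,
                                           ileum = 15, cecum = 15),
                      heritable_taxa_per_segment = c(duodenum = 0,
                                                     jejunum = 0, ileum = 0,
                                                     cecum = 0),
                      key_taxon = FALSE, n_lines = 1, seed = 200 + s)
    g <- simulate_genotypes(cfg)
    mic <- simulate_microbiota(cfg, g)
    ph <- simulate_phenotype(cfg, g, mic)
    grm <- build_grm(quiet(filter_variants(g)))
    mrms <- lapply(mic$tables, function(t) {
      build_mrm(clr_transform(quiet(filter_core_taxa(t))))
    })
    fit <- quiet(reml_fit(ph$phenotypes$FCR, NULL,
                          c(list(genetic = grm), mrms)))
    fit$components$ratio[fit$components$component != "residual"]
  })
  expect_true(all(rowMeans(ratios) < 0.05))
})

test_that("generated bundles are consistent on disk and reproducible", {
  dir1 <- file.path(tempdir(), "bundle1")
  dir2 <- file.path(tempdir(), "bundle2")
  cfg <- sim_config(n_individuals = 313, n_variants = 120,
                    taxa_per_segment = c(duodenum = 8, jejunum = 8,
                                         ileum = 8, cecum = 8),
                    heritable_taxa_per_segment = c(duodenum = 1, jejunum = 1,
                                                   ileum = 1, cecum = 1),
                    seed = 103)
  b1 <- generate_dataset(cfg, dir1)
  b2 <- generate_dataset(cfg, dir2)
  expect_true(all(file.exists(unlist(b1$paths))))
  # same seed: byte-identical ground truth
  expect_identical(readLines(b1$paths$truth), readLines(b2$paths$truth))
  # sample ids consistent across every output
  g <- read_genotypes(b1$paths$genotypes, "vcf")
  ph <- read_phenotypes(b1$paths$phenotypes)
  expect_equal(ph$sample, rownames(g$dosages))
  ab <- read_abundance(b1$paths$abundance_cecum, "cecum")
  expect_equal(rownames(ab$values), ph$sample)
  # cohort bookkeeping: 313 rows, line labels match simulated membership
  expect_equal(nrow(ph), 313L)
  expect_equal(unname(table(ph$line)[c("ZF", "CF")]), c(151L, 162L),
               ignore_attr = TRUE)
  expect_equal(ph$line, unname(attr(b1$genotypes, "line")[ph$sample]))
})
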