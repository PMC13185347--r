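# Shared fixtures and quiet wrappers for the suite. All fixtures are built
# in code; nothing is read from disk except files the tests themselves
# write to tempdir().

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Small genotype matrix with hand-set dosages.
toy_genotypes <- function(dosages, chrom = "1", pos = NULL) {
  dosages <- as.matrix(dosages)
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(p) * 100
  genotype_matrix(dosages,
                  data.frame(chrom = rep(chrom, p), pos = pos,
                             ref = rep("A", p), alt = rep("G", p)))
}

# Simulated single-line cohort reused by REML/association tests.
sim_cohort <- function(n = 200, p = 400, seed = 1, ...) {
  cfg <- sim_config(n_individuals = n, n_variants = p, n_lines = 1,
                    key_taxon = FALSE,
                    taxa_per_segment = c(duodenum = 8, jejunum = 8,
                                         ileum = 8, cecum = 8),
                    heritable_taxa_per_segment = c(duodenum = 0, jejunum = 0,
                                                   ileum = 0, cecum = 0),
                    seed = seed, ...)
  g <- simulate_genotypes(cfg)
  list(cfg = cfg, g = g, grm = build_grm(quiet(filter_variants(g))))
}

# Relative-abundance table from a raw nonnegative matrix.
toy_abundance <- function(values, segment = "cecum",
                          scale = c("relative", "counts")) {
  scale <- match.arg(scale)
  if (scale == "relative") values <- values / rowSums(values)
  abundance_table(values, segment, scale = scale)
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal VCF with the given GT strings (variants x samples).
toy_vcf <- function(gt, chrom = "1", pos = NULL, ref = "A", alt = "G",
                    samples = paste0("S", seq_len(ncol(gt)))) {
  p <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(p) * 10
  ref <- rep_len(ref, p); alt <- rep_len(alt, p)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(p), function(j) {
    paste(c(chrom, pos[j], ".", ref[j], alt[j], ".", "PASS", ".", "GT",
            gt[j, ]), collapse = "\t")
  }, character(1))
  write_lines_tmp(c(header, body))
}
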