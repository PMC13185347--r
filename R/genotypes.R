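#' Genotype matrix container
#'
#' Holds an individuals-by-variants dosage matrix together with variant
#' metadata. Dosages count copies of the REFERENCE allele (0, 1, 2, or `NA`
#' for missing). This orientation matches the relationship-matrix definition
#' used throughout the package; note that many GWAS stacks count the
#' alternate allele instead, which flips effect signs but not magnitudes or
#' p-values.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`; one row per variant. Positions are 1-based.
#' @param samples character vector of unique sample identifiers (defaults to
#'   `rownames(dosages)`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (named matrix) and `variants` (data.frame, sorted by
#'   chromosome then position).
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) {
    samples <- sprintf("S%03d", seq_len(nrow(dosages)))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicated sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (length(samples) != nrow(dosages)) {
    stop("length(samples) does not match nrow(dosages)")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variants is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("nrow(variants) does not match ncol(dosages)")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad])[1:min(3, sum(bad))], collapse = ", "))
  }
  if (is.null(variants$id) || all(is.na(variants$id))) {
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%d chromosome%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from VCF or PLINK additive text
#'
#' `format = "vcf"` parses a (possibly gzipped) VCF 4.x via
#' \pkg{vcfR} and converts GT fields to reference-allele dosages
#' (GT `0/0` -> 2, `0/1` -> 1, `1/1` -> 0, `./.` -> `NA`). Multiallelic
#' records are dropped with a warning reporting the count.
#' `format = "plink_text"` reads PLINK's additive-transpose text table
#' (`--recode A-transpose`, one variant per row with columns
#' `CHR SNP (C)M POS COUNTED ALT` followed by one dosage per sample); the
#' COUNTED allele is taken as the reference allele so round-trips are exact.
#'
#' @param path file path.
#' @param format `"vcf"` or `"plink_text"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_traw(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    warning(sprintf("dropped %d non-biallelic record(s) from %s",
                    sum(multi), path))
  }
  if (all(multi)) stop("no biallelic records left in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  samples <- colnames(gt)
  if (anyDuplicated(samples)) {
    stop("duplicated sample identifiers in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  gtc <- gsub("|", "/", as.character(gt), fixed = TRUE)
  lookup <- c("0/0" = 2, "0/1" = 1, "1/0" = 1, "1/1" = 0)
  dos <- unname(lookup[gtc])
  unknown <- is.na(dos) & !(is.na(gtc) | gtc %in% c("./.", "."))
  if (any(unknown)) {
    stop("malformed GT field(s) in ", path, ": ",
         paste(unique(gtc[unknown])[1:min(3, sum(unknown))], collapse = ", "),
         " (record ", which(unknown)[1], ")")
  }
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, samples)
}

read_genotypes_traw <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("CHR", "SNP", "POS", "COUNTED", "ALT")
  if (!all(required %in% names(tab))) {
    stop("not a PLINK A-transpose table (missing ",
         paste(setdiff(required, names(tab)), collapse = ", "), "): ", path)
  }
  meta_cols <- intersect(c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT"),
                         names(tab))
  samples <- setdiff(names(tab), meta_cols)
  if (!length(samples)) stop("no sample columns in ", path)
  dos <- t(as.matrix(tab[, samples, drop = FALSE]))
  variants <- data.frame(chrom = as.character(tab$CHR), pos = as.integer(tab$POS),
                         ref = tab$COUNTED, alt = tab$ALT, id = tab$SNP,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}

#' Write genotypes to VCF or PLINK additive text
#'
#' The VCF writer emits a minimal VCF 4.2 with GT fields only; reference
#' dosage 2 becomes `0/0`, 1 becomes `0/1`, 0 becomes `1/1` and `NA` becomes
#' `./.`, so `read_genotypes(write_genotypes(g))` reproduces dosages exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"plink_text"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format == "vcf") {
    gt_codes <- c(`2` = "0/0", `1` = "0/1", `0` = "1/1")
    dos <- g$dosages
    gt <- matrix(gt_codes[as.character(dos)], nrow = nrow(dos))
    gt[is.na(dos)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##source=microfe",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
    v <- g$variants
    body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    for (j in seq_len(nrow(v))) {
      body[j] <- paste(c(body[j], gt[, j]), collapse = "\t")
    }
    writeLines(c(header, body), path)
  } else {
    v <- g$variants
    tab <- data.frame(CHR = v$chrom, SNP = v$id, `(C)M` = 0, POS = v$pos,
                      COUNTED = v$ref, ALT = v$alt, check.names = FALSE,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(t(g$dosages), check.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Mean-impute missing dosages per variant (used inside kernel/association
# computations only; storage keeps the explicit NA).
impute_dosages <- function(g) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosages else g
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  dos
}
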