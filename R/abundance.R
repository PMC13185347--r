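#' Taxon abundance table for one gut segment
#'
#' Samples-by-taxa abundance matrix tagged with the intestinal segment it was
#' sampled from and with the scale its values are on. Raw scales (`counts`,
#' `relative`) must be non-negative; transformed scales (`clr`, `log10`,
#' `zscore`) may be negative. Rows of a `relative`-scale table must sum to 1
#' (within 1e-9) over the retained taxa.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param segment one of `"duodenum"`, `"jejunum"`, `"ileum"`, `"cecum"`.
#' @param samples,taxa identifiers (default from dimnames).
#' @param scale one of `"counts"`, `"relative"`, `"clr"`, `"log10"`,
#'   `"zscore"`.
#' @param rank taxonomic rank tag, `"genus"` (default) or `"asv"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, segment,
                            samples = rownames(values),
                            taxa = colnames(values),
                            scale = c("counts", "relative", "clr", "log10",
                                      "zscore"),
                            rank = "genus") {
  scale <- match.arg(scale)
  segment <- match.arg(segment, SEGMENTS)
  values <- as.matrix(values)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(ncol(values)))
  samples <- as.character(samples); taxa <- as.character(taxa)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (anyDuplicated(taxa)) stop("duplicated taxon labels")
  if (length(samples) != nrow(values) || length(taxa) != ncol(values)) {
    stop("sample/taxon labels do not match matrix dimensions")
  }
  if (anyNA(values)) stop("abundance values must not be missing")
  if (scale %in% c("counts", "relative") && any(values < 0)) {
    stop("negative abundance value on a ", scale, "-scale table")
  }
  if (scale == "relative") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("relative-scale rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
    }
  }
  dimnames(values) <- list(samples, taxa)
  structure(list(values = values, segment = segment, scale = scale,
                 rank = rank),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %s: %d samples x %d taxa (%s, scale=%s)\n",
              x$segment, nrow(x$values), ncol(x$values), x$rank, x$scale))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a taxon abundance table from TSV
#'
#' Expects a header row of taxon labels and a first column of sample
#' identifiers. The scale is inferred: all-integer values are tagged
#' `counts`, otherwise `relative` (re-closure is NOT applied on read; rows
#' of a relative table must already sum to 1). Negative entries are
#' rejected.
#'
#' @param path TSV file path.
#' @param segment gut segment label.
#' @inheritParams abundance_table
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, segment, rank = "genus") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("abundance TSV needs a sample column plus taxa: ",
                          path)
  samples <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric abundance entries in ", path)
  if (any(values < 0)) stop("negative abundance entry in ", path)
  scale <- if (all(values == round(values))) "counts" else "relative"
  rownames(values) <- samples
  abundance_table(values, segment, scale = scale, rank = rank)
}

#' Write a taxon abundance table to TSV
#'
#' @param t an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  # %.17g keeps doubles bit-exact through a write/read round trip
  vals <- apply(t$values, 2, function(x) sprintf("%.17g", x))
  tab <- data.frame(sample = rownames(t$values), vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("sample", colnames(t$values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Convert counts or relative abundances to a row-closed relative table.
to_relative <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$scale == "relative") return(t)
  if (t$scale != "counts") {
    stop("cannot convert a ", t$scale, "-scale table to relative abundances")
  }
  rs <- rowSums(t$values)
  if (any(rs <= 0)) stop("sample(s) with zero total abundance: ",
                         paste(rownames(t$values)[rs <= 0], collapse = ", "))
  abundance_table(t$values / rs, t$segment, scale = "relative", rank = t$rank)
}
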