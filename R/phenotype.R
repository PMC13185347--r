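#' Feed conversion ratio
#'
#' FCR = feed intake / body-weight gain over the test period; lower values
#' mean more efficient feed use. Vectorized; the ratio is invariant to
#' rescaling both inputs by the same positive constant.
#'
#' @param fi cumulative feed intake (g), `>= 0`.
#' @param bwg body-weight gain (g), strictly positive.
#' @return `fi / bwg`.
#' @export
compute_fcr <- function(fi, bwg) {
  if (length(fi) != length(bwg)) stop("fi and bwg must have equal length")
  if (any(!is.finite(bwg)) || any(bwg <= 0)) {
    stop("body-weight gain must be positive (biologically invalid otherwise)")
  }
  if (any(fi < 0, na.rm = TRUE)) stop("feed intake must be non-negative")
  fi / bwg
}

#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper around [stats::shapiro.test()], used to check
#' that a trait (typically FCR) is close enough to normal for the
#' mixed-model analyses.
#'
#' @param values numeric vector, `3 <= n <= 5000`, non-constant.
#' @return list with elements `W` and `p`.
#' @export
check_normality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (sd(values) == 0) stop("constant vector: normality statistic undefined")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' Read a phenotype/covariate table from TSV
#'
#' First column is the sample identifier; remaining columns are kept as-is.
#' If `FI` and `BWG` are present but `FCR` is not, FCR is derived. Positive
#' checks on FI/BWG/FCR are enforced where the columns are present.
#'
#' @param path TSV file path.
#' @return data.frame with a `sample` column.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1] <- "sample"
  tab$sample <- as.character(tab$sample)
  if (anyDuplicated(tab$sample)) stop("duplicated sample identifiers in ", path)
  for (col in c("FI", "BWG", "FCR")) {
    if (col %in% names(tab) && any(tab[[col]] <= 0, na.rm = TRUE)) {
      stop(col, " must be positive where present")
    }
  }
  if (all(c("FI", "BWG") %in% names(tab)) && !"FCR" %in% names(tab)) {
    tab$FCR <- compute_fcr(tab$FI, tab$BWG)
  }
  tab
}

#' Write a phenotype table to TSV
#'
#' @param phenotypes data.frame with a `sample` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(is.data.frame(phenotypes), "sample" %in% names(phenotypes))
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
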