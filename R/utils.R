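# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report percentages use the
#' conventional half-up rule so that e.g. 76.5 prints as 77.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator
#'
#' Returns `100 * k / n` rounded half-up to an integer, or `NA` when the
#' denominator is zero (an undefined percentage is reported as missing,
#' never as 0).
#'
#' @param k numerator count.
#' @param n denominator count.
#' @return integer percentage, or `NA_real_` if `n == 0`.
#' @export
percent_of <- function(k, n) {
  if (length(n) == 1L && n == 0) return(NA_real_)
  ifelse(n == 0, NA_real_, round_half_up(100 * k / n))
}

# Read a TSV with header into a data.frame, no factors, preserving names.
read_tsv_strict <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}

# Require columns in a data.frame; error names the missing ones.
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Convert a 0-based half-open region data.frame to GRanges (1-based closed).
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

# Fail loudly when two inputs share no chromosome names (e.g. "chr1" vs "1").
check_shared_chroms <- function(a, b, what_a = "regions", what_b = "annotation") {
  shared <- intersect(unique(a), unique(b))
  if (length(shared) == 0) {
    stop(sprintf(
      "no chromosome names shared between %s (%s) and %s (%s); supply a chrom_map instead of relying on silent harmonization",
      what_a, paste(utils::head(unique(a), 3), collapse = ","),
      what_b, paste(utils::head(unique(b), 3), collapse = ",")), call. = FALSE)
  }
  invisible(shared)
}

# Apply an optional chromosome rename map (named character vector old -> new).
apply_chrom_map <- function(chrom, chrom_map = NULL) {
  if (is.null(chrom_map)) return(chrom)
  hit <- chrom %in% names(chrom_map)
  chrom[hit] <- unname(chrom_map[chrom[hit]])
  chrom
}
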