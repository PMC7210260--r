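# Odds-ratio enrichment of differential regions within a chromatin-state
# segmentation.
#
# The 2x2 construction: the observed rows are differential-region counts
# in/out of the state (k vs n - k); the expected column is the state's
# share of the genome (s_bp vs G_bp - s_bp), so
#   OR = [k / (n - k)] / [s_bp / (G_bp - s_bp)].

#' Load a chromatin-state segmentation (BED4, ChromHMM dense style)
#'
#' @param path BED4 path: chrom, start, end (0-based half-open), state
#'   label.
#' @param chrom_sizes chromosome sizes: a two-column data.frame
#'   (`chrom`, `size`), a named numeric vector, or a path to a
#'   chrom.sizes TSV without header.
#' @return object of class `state_segmentation`: list with `segments`
#'   (data.frame `chrom`, `start`, `end`, `state`), `state_bp` (named
#'   numeric, cumulative bp per state) and `genome_bp` (sum of chromosome
#'   sizes).
#' @export
load_segmentation <- function(path, chrom_sizes) {
  seg <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(seg) < 4) stop("segmentation BED needs 4 columns (chrom, start, end, state)", call. = FALSE)
  segments <- data.frame(chrom = as.character(seg[[1]]),
                         start = as.integer(seg[[2]]), end = as.integer(seg[[3]]),
                         state = as.character(seg[[4]]), stringsAsFactors = FALSE)
  if (any(segments$start >= segments$end)) stop("segment with start >= end", call. = FALSE)

  sizes <- .as_chrom_sizes(chrom_sizes)
  unknown <- setdiff(unique(segments$chrom), names(sizes))
  if (length(unknown) > 0) {
    stop(sprintf("segmentation chromosome(s) missing from chrom sizes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(segments$end > sizes[segments$chrom])) {
    stop("segment exceeds chromosome size", call. = FALSE)
  }
  # non-overlap within each chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop(sprintf("overlapping segments on %s", ch), call. = FALSE)
    }
  }
  state_bp <- tapply(segments$end - segments$start, segments$state, sum)
  state_bp <- stats::setNames(as.numeric(state_bp), names(state_bp))
  structure(list(segments = segments, state_bp = state_bp,
                 genome_bp = sum(sizes)),
            class = "state_segmentation")
}

.as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1 && file.exists(chrom_sizes)) {
    df <- utils::read.table(chrom_sizes, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
    return(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])))
  }
  if (is.data.frame(chrom_sizes)) {
    return(stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]])))
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) return(chrom_sizes)
  stop("chrom_sizes must be a path, data.frame or named numeric vector", call. = FALSE)
}

#' Odds-ratio enrichment of regions within each chromatin state
#'
#' For each state, `k` is the number of distinct regions overlapping at
#' least one segment of that state by >= 1 bp (a region may count toward
#' several states), `n` the total number of distinct regions, `s_bp` the
#' cumulative state size and `G_bp` the genome size. Duplicate regions
#' (identical coordinates) are counted once. When `k = 0` or `k = n` the
#' Haldane-Anscombe correction adds 0.5 to the two count cells. States
#' covering the whole genome or nothing have no defined enrichment and
#' are reported with `odds_ratio = NA`.
#'
#' With `unit = "bp"` the count cells are replaced by overlap basepairs
#' (overlapping bp vs non-overlapping bp of the regions).
#'
#' @param regions differential-region data.frame.
#' @param segmentation a `state_segmentation` (see [load_segmentation()]).
#' @param unit `"count"` (default) or `"bp"`.
#' @param flag_threshold odds ratio at/above which a state is flagged a
#'   primary reprogramming target (default 100).
#' @return data.frame `state`, `k`, `n`, `s_bp`, `G_bp`, `odds_ratio`,
#'   `flag_primary_target`, one row per state, ordered by state label.
#' @export
state_odds_ratio <- function(regions, segmentation, unit = c("count", "bp"),
                             flag_threshold = 100) {
  unit <- match.arg(unit)
  stopifnot(inherits(segmentation, "state_segmentation"))
  regions <- unique(regions[, c("chrom", "start", "end"), drop = FALSE])
  n <- nrow(regions)
  if (n < 1) stop("state_odds_ratio requires at least one region", call. = FALSE)
  check_shared_chroms(regions$chrom, segmentation$segments$chrom,
                      "regions", "segmentation")

  reg_gr <- regions_to_granges(regions)
  seg <- segmentation$segments
  seg_gr <- GenomicRanges::GRanges(seqnames = seg$chrom,
                                   ranges = IRanges::IRanges(seg$start + 1L, seg$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, seg_gr)
  G <- segmentation$genome_bp
  states <- sort(names(segmentation$state_bp))

  total_region_bp <- sum(regions$end - regions$start)
  rows <- lapply(states, function(st) {
    s_bp <- segmentation$state_bp[[st]]
    sel <- S4Vectors::subjectHits(hits)[seg$state[S4Vectors::subjectHits(hits)] == st]
    qsel <- S4Vectors::queryHits(hits)[seg$state[S4Vectors::subjectHits(hits)] == st]
    k <- length(unique(qsel))
    if (unit == "count") {
      a <- k; b <- n - k
    } else {
      # overlap bp of regions with this state's segments
      # every (region, segment) pair here overlaps, so pintersect is
      # well defined; segments of one state never overlap each other
      ov <- IRanges::pintersect(IRanges::ranges(reg_gr[qsel]),
                                IRanges::ranges(seg_gr[sel]))
      a <- sum(IRanges::width(ov))
      b <- total_region_bp - a
    }
    or <- if (s_bp <= 0 || s_bp >= G) {
      NA_real_
    } else {
      if (a == 0 || b == 0) { a <- a + 0.5; b <- b + 0.5 }
      (a / b) / (s_bp / (G - s_bp))
    }
    data.frame(state = st, k = k, n = n, s_bp = s_bp, G_bp = G,
               odds_ratio = or,
               flag_primary_target = !is.na(or) & or >= flag_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
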