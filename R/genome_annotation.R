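# Genomic input loading and region -> gene / enhancer annotation.
#
# All coordinates are held internally as 0-based half-open intervals; the
# loaders convert from each file dialect exactly once (diffReps emits
# 1-based inclusive coordinates, BED is already 0-based half-open).

#' Load gene models from a TSS table or a GTF file
#'
#' A gene model is reduced to its transcription start site (TSS): the
#' strand-aware outermost boundary of the gene in 0-based coordinates
#' (the half-open start for `+` genes, the half-open end for `-` genes).
#'
#' @param path path to a tab-separated TSS table with columns
#'   `gene_id`, `chrom`, `tss`, `strand`, or a GTF file.
#' @param format `"tss"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   one row per gene, ordered by `gene_id`.
#' @export
load_gene_models <- function(path, format = c("tss", "gtf")) {
  format <- match.arg(format)
  if (format == "tss") {
    df <- read_tsv_strict(path)
    require_columns(df, c("gene_id", "chrom", "tss", "strand"), "TSS table")
    genes <- data.frame(gene_id = as.character(df$gene_id),
                        chrom = as.character(df$chrom),
                        tss = as.integer(df$tss),
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    ids <- as.character(gr$gene_id)
    if (any(is.na(ids) | ids == "")) {
      stop("GTF records without a gene_id attribute", call. = FALSE)
    }
    strand <- as.character(GenomicRanges::strand(gr))
    # rtracklayer returns 1-based closed intervals; 0-based half-open is
    # [start - 1, end). Outermost boundary per gene on the annotated strand.
    df <- data.frame(gene_id = ids,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start0 = GenomicRanges::start(gr) - 1L,
                     end0 = GenomicRanges::end(gr),
                     strand = strand, stringsAsFactors = FALSE)
    parts <- split(df, df$gene_id)
    genes <- do.call(rbind, lapply(parts, function(p) {
      s <- unique(p$strand)
      if (length(s) > 1) stop(sprintf("gene %s annotated on both strands", p$gene_id[1]), call. = FALSE)
      data.frame(gene_id = p$gene_id[1], chrom = p$chrom[1],
                 tss = if (s == "+") min(p$start0) else max(p$end0),
                 strand = s, stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL
  }
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop(sprintf("unknown strand symbol(s): %s",
                 paste(unique(genes$strand[bad_strand]), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop(sprintf("duplicate gene_id(s): %s",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(genes$tss < 0)) stop("negative TSS coordinate", call. = FALSE)
  genes[order(genes$gene_id), , drop = FALSE]
}

#' Load a differential-region table
#'
#' Reads a diffReps-style tab-separated table of differential histone-mark
#' regions, converts coordinates to the internal 0-based half-open
#' convention, and applies the significance filters. The table must carry
#' `chrom`, `start`, `end`, `q_value` (or `q`/`padj`) and either a
#' `direction` + `fold_change` pair or a signed `log2FC` column.
#'
#' Defaults follow the differential-peak definition used for the Venn and
#' Circos analyses (q < 0.01, fold change exceeding 2x); both thresholds
#' are configurable (the looser 1.5x peak-calling threshold is a valid
#' alternative).
#'
#' @param path path to the TSV.
#' @param mark histone-mark label attached to every kept region.
#' @param contrast contrast label (e.g. `"AGE"`, `"NEONATAL"`, `"ADULT"`).
#' @param convention `"diffreps"` (1-based inclusive, the default) or
#'   `"bed"` (0-based half-open).
#' @param q_max keep rows with `q_value < q_max` (default 0.01).
#' @param fc_min keep rows with `fold_change > fc_min` (default 2; strict,
#'   "exceeding").
#' @param chrom_map optional named character vector renaming chromosomes.
#' @return data.frame with columns `chrom`, `start`, `end`, `direction`,
#'   `fold_change`, `q_value`, `mark`, `contrast`.
#' @export
load_differential_regions <- function(path, mark, contrast,
                                      convention = c("diffreps", "bed"),
                                      q_max = 0.01, fc_min = 2,
                                      chrom_map = NULL) {
  convention <- match.arg(convention)
  df <- read_tsv_strict(path)
  names(df)[names(df) %in% c("q", "padj", "qvalue")] <- "q_value"
  require_columns(df, c("chrom", "start", "end", "q_value"), "differential-region table")
  if (!"fold_change" %in% names(df)) {
    if (!"log2FC" %in% names(df)) {
      stop("differential-region table needs either fold_change (+direction) or log2FC", call. = FALSE)
    }
    df$direction <- ifelse(df$log2FC >= 0, "up", "down")
    df$fold_change <- 2^abs(df$log2FC)
  }
  require_columns(df, c("direction", "fold_change"), "differential-region table")

  start0 <- as.integer(df$start)
  end0 <- as.integer(df$end)
  if (convention == "diffreps") start0 <- start0 - 1L
  if (any(start0 >= end0)) {
    stop("region with start >= end after coordinate conversion", call. = FALSE)
  }
  if (any(df$q_value < 0 | df$q_value > 1)) stop("q_value outside [0, 1]", call. = FALSE)
  if (any(df$fold_change <= 0)) stop("fold_change must be positive", call. = FALSE)
  if (!all(df$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }

  keep <- df$q_value < q_max & df$fold_change > fc_min
  out <- data.frame(chrom = apply_chrom_map(as.character(df$chrom), chrom_map),
                    start = start0, end = end0,
                    direction = as.character(df$direction),
                    fold_change = as.numeric(df$fold_change),
                    q_value = as.numeric(df$q_value),
                    mark = mark, contrast = contrast,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("load_differential_regions[%s/%s]: kept %d/%d rows (q<%g, FC>%g)",
                  mark, contrast, nrow(out), nrow(df), q_max, fc_min))
  out
}

#' Load an enhancer BED file
#'
#' BED3/BED4, 0-based half-open. When the name column is absent enhancers
#' are identified as `enh_<i>` in file order.
#'
#' @param path BED path.
#' @param chrom_map optional named character vector renaming chromosomes.
#' @return data.frame with `enhancer_id`, `chrom`, `start`, `end`.
#' @export
load_enhancers <- function(path, chrom_map = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("enhancer BED needs at least 3 columns", call. = FALSE)
  ids <- if (ncol(df) >= 4) as.character(df[[4]]) else sprintf("enh_%d", seq_len(nrow(df)))
  if (anyDuplicated(ids)) stop("duplicate enhancer_id in BED", call. = FALSE)
  out <- data.frame(enhancer_id = ids,
                    chrom = apply_chrom_map(as.character(df[[1]]), chrom_map),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("enhancer with start >= end", call. = FALSE)
  out
}

#' Annotate differential regions to genes by TSS window
#'
#' A gene is assigned a region when the closed window
#' `[tss - window_bp, tss + window_bp]` (inclusive at both ends, in
#' 0-based base coordinates) intersects the region. The per-(mark,
#' direction, contrast) feature sets consumed by the reprogramming
#' classifier are derived from the assignments.
#'
#' @param regions differential-region data.frame
#'   (see [load_differential_regions()]).
#' @param genes gene-model data.frame (see [load_gene_models()]).
#' @param window_bp half-width of the TSS window in bp (default 3000).
#' @return list with `assignments` (data.frame `gene_id`, `region_idx`,
#'   `mark`, `direction`, `contrast`) and `feature_sets` (unique
#'   data.frame `feature_id`, `mark`, `direction`, `contrast`, ordered by
#'   feature_id).
#' @export
annotate_regions_to_genes <- function(regions, genes, window_bp = 3000) {
  if (window_bp < 0) stop("window_bp must be non-negative", call. = FALSE)
  if (nrow(regions) > 0) {
    check_shared_chroms(regions$chrom, genes$chrom, "regions", "gene models")
  }
  # Closed window [tss-w, tss+w] on 0-based bases is [tss-w+1, tss+w+1]
  # 1-based closed; regions [s,e) 0-based are [s+1, e] 1-based closed.
  win <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$tss - as.integer(window_bp) + 1L),
                              end = genes$tss + as.integer(window_bp) + 1L)
  )
  hits <- if (nrow(regions) > 0) {
    GenomicRanges::findOverlaps(regions_to_granges(regions), win)
  } else S4Vectors::Hits()
  assignments <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    region_idx = S4Vectors::queryHits(hits),
    mark = regions$mark[S4Vectors::queryHits(hits)],
    direction = regions$direction[S4Vectors::queryHits(hits)],
    contrast = regions$contrast[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  .finish_annotation(assignments, id_col = "gene_id")
}

#' Annotate differential regions to enhancers by interval overlap
#'
#' An enhancer is assigned a region when the two half-open intervals
#' overlap by at least one base (adjacency is not overlap).
#'
#' @param regions differential-region data.frame.
#' @param enhancers enhancer data.frame (see [load_enhancers()]).
#' @return same shape as [annotate_regions_to_genes()], with
#'   `enhancer_id` as the feature identifier.
#' @export
annotate_regions_to_enhancers <- function(regions, enhancers) {
  if (nrow(regions) > 0) {
    check_shared_chroms(regions$chrom, enhancers$chrom, "regions", "enhancers")
  }
  enh <- GenomicRanges::GRanges(
    seqnames = enhancers$chrom,
    ranges = IRanges::IRanges(start = enhancers$start + 1L, end = enhancers$end)
  )
  hits <- if (nrow(regions) > 0) {
    GenomicRanges::findOverlaps(regions_to_granges(regions), enh)
  } else S4Vectors::Hits()
  assignments <- data.frame(
    enhancer_id = enhancers$enhancer_id[S4Vectors::subjectHits(hits)],
    region_idx = S4Vectors::queryHits(hits),
    mark = regions$mark[S4Vectors::queryHits(hits)],
    direction = regions$direction[S4Vectors::queryHits(hits)],
    contrast = regions$contrast[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  .finish_annotation(assignments, id_col = "enhancer_id")
}

.finish_annotation <- function(assignments, id_col) {
  o <- order(assignments[[id_col]], assignments$region_idx)
  assignments <- assignments[o, , drop = FALSE]
  rownames(assignments) <- NULL
  fs <- unique(data.frame(feature_id = assignments[[id_col]],
                          mark = assignments$mark,
                          direction = assignments$direction,
                          contrast = assignments$contrast,
                          stringsAsFactors = FALSE))
  fs <- fs[order(fs$feature_id, fs$mark, fs$direction, fs$contrast), , drop = FALSE]
  rownames(fs) <- NULL
  list(assignments = assignments, feature_sets = fs)
}

#' Write differential regions as BED
#'
#' Emits `chrom`, `start`, `end` (0-based half-open), a composite name
#' `mark:contrast:direction`, and the fold change as score.
#'
#' @param regions differential-region data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    paste(regions$mark, regions$contrast, regions$direction, sep = ":"),
                    regions$fold_change)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read regions back from a BED written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return differential-region data.frame (without q-values, which BED
#'   does not carry; `q_value` is set to 0).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  parts <- strsplit(as.character(df[[4]]), ":", fixed = TRUE)
  data.frame(chrom = as.character(df[[1]]),
             start = as.integer(df[[2]]), end = as.integer(df[[3]]),
             direction = vapply(parts, `[`, "", 3),
             fold_change = as.numeric(df[[5]]),
             q_value = 0,
             mark = vapply(parts, `[`, "", 1),
             contrast = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}
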