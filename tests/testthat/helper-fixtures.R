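# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

region_df <- function(chrom, start, end, direction = "up", fold_change = 3,
                      q_value = 0.001, mark = "H3K4me1", contrast = "AGE") {
  data.frame(chrom = chrom, start = start, end = end, direction = direction,
             fold_change = fold_change, q_value = q_value, mark = mark,
             contrast = contrast, stringsAsFactors = FALSE)
}

toy_genes <- function(gene_id, chrom, tss, strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
             strand = rep_len(strand, length(gene_id)), stringsAsFactors = FALSE)
}

write_tmp_tsv <- function(df, header = TRUE) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  p
}

# Quadratic all-pairs oracle for TSS-window assignment: a region [s, e)
# is assigned to a gene iff the closed window [tss - w, tss + w] contains
# any of its bases s .. e-1.
brute_force_gene_hits <- function(regions, genes, window_bp) {
  hits <- list()
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(genes))) {
    if (regions$chrom[i] != genes$chrom[j]) next
    lo <- genes$tss[j] - window_bp
    hi <- genes$tss[j] + window_bp
    if (regions$start[i] <= hi && (regions$end[i] - 1) >= lo) {
      hits[[length(hits) + 1L]] <- data.frame(gene_id = genes$gene_id[j],
                                              region_idx = i)
    }
  }
  if (length(hits) == 0) return(data.frame(gene_id = character(), region_idx = integer()))
  out <- do.call(rbind, hits)
  out[order(out$gene_id, out$region_idx), ]
}

# Quadratic oracle for half-open interval overlap.
brute_force_enh_hits <- function(regions, enhancers) {
  hits <- list()
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(enhancers))) {
    if (regions$chrom[i] != enhancers$chrom[j]) next
    if (regions$start[i] < enhancers$end[j] && enhancers$start[j] < regions$end[i]) {
      hits[[length(hits) + 1L]] <- data.frame(enhancer_id = enhancers$enhancer_id[j],
                                              region_idx = i)
    }
  }
  if (length(hits) == 0) return(data.frame(enhancer_id = character(), region_idx = integer()))
  out <- do.call(rbind, hits)
  out[order(out$enhancer_id, out$region_idx), ]
}

# Contrast sets realizing a given precocious count within a given
# age-associated set size (features in A only make up the rest).
sets_with_precocious <- function(n_precocious, n_age) {
  prec <- sprintf("p%05d", seq_len(n_precocious))
  rest <- sprintf("a%05d", seq_len(n_age - n_precocious))
  build_contrast_sets(age = c(prec, rest), neonatal = prec, adult = NULL,
                      mark = "H3K4me1", direction = "up")
}

# Reduced-scale simulation config for fast tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 60, n_enhancers = 30, n_chroms = 2,
             chrom_size_bp = 2e6, n_distractors = 20,
             omics = list(n_features = 50, n_veh = 5, n_edc = 5, n_days = 2,
                          planted_up = 6, planted_down = 4,
                          effect_sd_units = 3, missing_rate = 0.05),
             de = list(n_up = 12, n_down = 8),
             pathways = list(n_pathways = 10, pathway_size = 8,
                             planted_genes = 4, planted_metabolites = 2),
             ...)
}

# Manual Benjamini-Hochberg step-up, used as an oracle for q-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
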