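# Gene-model loading, differential-region ingestion and interval
# annotation.

test_that("TSS table loading maps fields and enforces uniqueness and strand", {
  p <- write_tmp_tsv(toy_genes(c("g1", "g2"), "chr1", c(1000, 5000), c("+", "-")))
  genes <- load_gene_models(p, format = "tss")
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$tss, c(1000L, 5000L))

  dup <- write_tmp_tsv(toy_genes(c("g1", "g1"), "chr1", c(1000, 5000)))
  expect_error(load_gene_models(dup, format = "tss"), "duplicate gene_id")

  bad <- write_tmp_tsv(toy_genes("g1", "chr1", 1000, "*"))
  expect_error(load_gene_models(bad, format = "tss"), "strand")
})

test_that("GTF TSS is the strand-aware outermost boundary", {
  # toy GTF: plus-strand gene [1001, 2000] 1-based, minus-strand gene
  # spanning [5001, 8000] 1-based, i.e. [5000, 8000) half-open
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tgene_id "gplus";',
    'chr1\ttoy\texon\t5001\t6000\t.\t-\t.\tgene_id "gminus";',
    'chr1\ttoy\texon\t7001\t8000\t.\t-\t.\tgene_id "gminus";',
    'chr2\ttoy\tgene\t101\t300\t.\t+\t.\tgene_id "gother";'), gtf)
  genes <- load_gene_models(gtf, format = "gtf")
  expect_equal(genes$tss[genes$gene_id == "gplus"], 1000)
  expect_equal(genes$tss[genes$gene_id == "gminus"], 8000)
  expect_equal(genes$tss[genes$gene_id == "gother"], 100)
})

test_that("diffReps loader converts coordinates and applies both filters", {
  tbl <- data.frame(chrom = "chr1", start = c(100, 300, 500, 700),
                    end = c(200, 400, 600, 800),
                    direction = "up",
                    fold_change = c(3, 3, 1.4, 3),
                    q_value = c(0.001, 0.02, 0.001, 0.005))
  p <- write_tmp_tsv(tbl)
  suppressMessages({
    kept <- load_differential_regions(p, "H3K4me1", "AGE", q_max = 0.01, fc_min = 2)
  })
  # 1-based inclusive (100, 200) becomes [99, 200)
  expect_equal(kept$start[1], 99L)
  expect_equal(kept$end[1], 200L)
  # q = 0.02 fails q < 0.01; FC = 1.4 fails both the 1.5x and 2x thresholds
  expect_equal(nrow(kept), 2)
  suppressMessages({
    kept15 <- load_differential_regions(p, "H3K4me1", "AGE", q_max = 0.01, fc_min = 1.5)
  })
  expect_equal(nrow(kept15), 2)

  # signed log2FC dialect
  tbl2 <- data.frame(chrom = "chr1", start = 100, end = 200,
                     log2FC = -2, q = 0.001)
  suppressMessages({
    neg <- load_differential_regions(write_tmp_tsv(tbl2), "H3K4me1", "AGE")
  })
  expect_equal(neg$direction, "down")
  expect_equal(neg$fold_change, 4)

  bad <- data.frame(chrom = "chr1", start = 201, end = 200,
                    direction = "up", fold_change = 3, q_value = 0.001)
  expect_error(suppressMessages(
    load_differential_regions(write_tmp_tsv(bad), "m", "AGE")),
    "start >= end")
  expect_error(suppressMessages(load_differential_regions(
    write_tmp_tsv(data.frame(chrom = "chr1", start = 1, end = 2)), "m", "AGE")),
    "missing required column|fold_change or log2FC")
})

test_that("TSS window is inclusive at both ends", {
  genes <- toy_genes("g1", "chr1", 5000)
  # nearest base 2099 is 2901 bp away -> assigned
  r_in <- region_df("chr1", 1999, 2100)
  expect_equal(annotate_regions_to_genes(r_in, genes, 3000)$feature_sets$feature_id, "g1")
  # base 8000 is exactly tss + 3000 -> still assigned (inclusive)
  r_edge <- region_df("chr1", 8000, 8100)
  expect_equal(annotate_regions_to_genes(r_edge, genes, 3000)$feature_sets$feature_id, "g1")
  # nearest base 8001 exceeds tss + 3000 -> not assigned
  r_out <- region_df("chr1", 8001, 8100)
  expect_equal(nrow(annotate_regions_to_genes(r_out, genes, 3000)$feature_sets), 0)
  expect_error(annotate_regions_to_genes(r_in, genes, -1), "window_bp")
})

test_that("gene annotation matches the quadratic oracle and ignores row order", {
  set.seed(42)
  for (rep in 1:20) {
    genes <- toy_genes(sprintf("g%d", 1:5), "chr1", sort(sample(1000:60000, 5)))
    s <- sample(0:65000, 20)
    regions <- region_df("chr1", s, s + sample(50:2000, 20, replace = TRUE))
    got <- annotate_regions_to_genes(regions, genes, 3000)$assignments
    want <- brute_force_gene_hits(regions, genes, 3000)
    expect_equal(got[, c("gene_id", "region_idx")], want,
                 ignore_attr = TRUE)
    # permuting input rows permutes region_idx accordingly but leaves the
    # assigned (gene, interval) pairs unchanged
    perm <- sample(nrow(regions))
    got_p <- annotate_regions_to_genes(regions[perm, ], genes, 3000)$assignments
    pairs <- function(a, r) sort(paste(a$gene_id, r$start[a$region_idx]))
    expect_equal(pairs(got_p, regions[perm, ]), pairs(got, regions))
  }
})

test_that("enhancer overlap is half-open: 1 bp counts, adjacency does not", {
  enh <- data.frame(enhancer_id = "e1", chrom = "chr1", start = 100, end = 200)
  expect_equal(annotate_regions_to_enhancers(region_df("chr1", 199, 300), enh)$feature_sets$feature_id, "e1")
  expect_equal(nrow(annotate_regions_to_enhancers(region_df("chr1", 200, 300), enh)$feature_sets), 0)

  set.seed(7)
  for (rep in 1:10) {
    s1 <- sample(0:5000, 8)
    enh <- data.frame(enhancer_id = sprintf("e%d", 1:8), chrom = "chr1",
                      start = s1, end = s1 + sample(50:500, 8, replace = TRUE))
    s2 <- sample(0:5000, 15)
    regions <- region_df("chr1", s2, s2 + sample(50:500, 15, replace = TRUE))
    got <- annotate_regions_to_enhancers(regions, enh)$assignments
    want <- brute_force_enh_hits(regions, enh)
    expect_equal(got[, c("enhancer_id", "region_idx")], want, ignore_attr = TRUE)
  }
})

test_that("disjoint chromosome namespaces error unless mapped", {
  genes <- toy_genes("g1", "1", 5000)
  r <- region_df("chr1", 4000, 4100)
  expect_error(annotate_regions_to_genes(r, genes), "no chromosome names shared")
  # rename map applied at load time fixes the mismatch
  p <- write_tmp_tsv(data.frame(chrom = "chr1", start = 4001, end = 4100,
                                direction = "up", fold_change = 3, q_value = 1e-4))
  suppressMessages({
    mapped <- load_differential_regions(p, "m", "AGE", chrom_map = c(chr1 = "1"))
  })
  expect_equal(annotate_regions_to_genes(mapped, genes)$feature_sets$feature_id, "g1")
})

test_that("regions round-trip through BED with identical annotation", {
  set.seed(11)
  genes <- toy_genes(sprintf("g%d", 1:4), "chr1", c(5000, 15000, 25000, 35000))
  s <- sample(0:40000, 12)
  regions <- region_df("chr1", s, s + 300)
  p <- tempfile(fileext = ".bed")
  write_regions_bed(regions, p)
  back <- read_regions_bed(p)
  expect_equal(back[, c("chrom", "start", "end", "direction", "mark", "contrast")],
               regions[, c("chrom", "start", "end", "direction", "mark", "contrast")])
  expect_equal(annotate_regions_to_genes(back, genes)$assignments$gene_id,
               annotate_regions_to_genes(regions, genes)$assignments$gene_id)
})
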