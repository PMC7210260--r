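# The ground-truth generator: determinism, layout guarantees, loader
# round-trips, planted-truth realization and dropout behaviour.

test_that("identical config and seed give byte-identical outputs", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  suppressMessages(simulate_study(small_sim_config(seed = 3), d1))
  suppressMessages(simulate_study(small_sim_config(seed = 3), d2))
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("genome layout: state partition, disjoint TSS windows, remote distractors", {
  set.seed(4)
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  # chromatin states partition every chromosome exactly
  bp <- tapply(g$states$end - g$states$start, g$states$chrom, sum)
  expect_true(all(bp == cfg$chrom_size_bp))
  expect_equal(sum(g$states$end - g$states$start), sum(g$chrom_sizes))
  # no two gene windows overlap (scan per chromosome)
  for (ch in unique(g$genes$chrom)) {
    tss <- sort(g$genes$tss[g$genes$chrom == ch])
    if (length(tss) > 1) expect_true(all(diff(tss) > 2 * cfg$window_bp))
  }
  # enhancers and distractor anchors are outside every TSS window
  for (df in list(data.frame(chrom = g$enhancers$chrom,
                             pos = (g$enhancers$start + g$enhancers$end) / 2),
                  g$distractor_anchors)) {
    for (i in seq_len(nrow(df))) {
      same <- g$genes$chrom == df$chrom[i]
      if (any(same)) {
        expect_gt(min(abs(g$genes$tss[same] - df$pos[i])), 2 * cfg$window_bp)
      }
    }
  }
  # over-dense config errors with advice
  expect_error(simulate_genome(sim_config(n_genes = 5000, chrom_size_bp = 1e6)),
               "density too high")
})

test_that("planted memberships appear in exactly the right contrast tables", {
  cfg <- small_sim_config(seed = 5)
  sim <- suppressMessages(simulate_study(cfg))
  gt <- sim$regions$gene_truth
  genes <- sim$genome$genes
  in_table <- function(gene, mark, ct) {
    tab <- sim$regions$tables[[paste(mark, ct, sep = "_")]]
    if (nrow(tab) == 0) return(FALSE)
    tss <- genes$tss[genes$gene_id == gene]
    chrom <- genes$chrom[genes$gene_id == gene]
    any(tab$chrom == chrom & tab$start - 1 <= tss + cfg$window_bp &
          tab$end - 1 >= tss - cfg$window_bp)
  }
  planted <- gt[!is.na(gt$klass), ]
  for (i in seq_len(min(nrow(planted), 25))) {
    p <- planted[i, ]
    expect_equal(in_table(p$feature_id, p$mark, "AGE"), p$in_A)
    expect_equal(in_table(p$feature_id, p$mark, "NEONATAL"), p$in_N)
    expect_equal(in_table(p$feature_id, p$mark, "ADULT"), p$in_D)
  }
})

test_that("every emitted file parses through its loader", {
  d <- file.path(tempdir(), "sim_parse")
  sim <- suppressMessages(simulate_study(small_sim_config(seed = 6), d))
  expect_silent(genes <- load_gene_models(file.path(d, "genes.tsv")))
  expect_equal(nrow(genes), 60)
  expect_silent(enh <- load_enhancers(file.path(d, "enhancers.bed")))
  expect_silent(seg <- load_segmentation(file.path(d, "states.bed"),
                                         file.path(d, "chrom.sizes")))
  for (f in list.files(d, pattern = "^diff_")) {
    parts <- strsplit(sub("\\.tsv$", "", sub("^diff_", "", f)), "_")[[1]]
    expect_no_warning(suppressMessages(load_differential_regions(
      file.path(d, f), mark = paste(parts[-length(parts)], collapse = "_"),
      contrast = parts[length(parts)])))
  }
  expect_silent(om <- load_omics_matrix(file.path(d, "omics.tsv"),
                                        file.path(d, "omics_meta.tsv")))
  expect_equal(dim(om$values), c(50, 10))
  expect_silent(pw <- load_gene_sets(file.path(d, "pathways.gmt")))
  expect_equal(length(pw), 11)
  expect_silent(suppressMessages(build_signature(
    read.table(file.path(d, "de_table.tsv"), header = TRUE, sep = "\t"))))
  unlink(d, recursive = TRUE)
})

test_that("omics generator realizes its planted recurrence truth and missingness rate", {
  cfg <- small_sim_config(seed = 8)
  set.seed(cfg$seed)
  om <- suppressMessages(simulate_omics(cfg))
  z <- compute_zscores(normalize_log_median(suppressMessages(knn_impute(om$values)),
                                            om$meta$day),
                       om$meta$group)
  rec <- recurrence_select(z)
  expect_equal(rec$status, om$truth$planted_status)
  expect_equal(sum(rec$status == "RECURRENT_UP"), cfg$omics$planted_up)
  expect_equal(sum(rec$status == "RECURRENT_DOWN"), cfg$omics$planted_down)
  # observed missing fraction within a generous binomial band of the rate
  n_cells <- length(om$values)
  miss <- mean(is.na(om$values))
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(miss - 0.05), 5 * se + 0.01)
})

test_that("membership dropout degrades class recovery monotonically", {
  recovery_at <- function(dropout, seed) {
    cfg <- small_sim_config(seed = seed, membership_dropout = dropout)
    set.seed(cfg$seed)
    genome <- simulate_genome(cfg)
    reg <- simulate_differential_regions(cfg, genome)
    # annotate and classify gene strata directly (no files)
    sets_by_ct <- list()
    for (ct in c("AGE", "NEONATAL", "ADULT")) {
      for (mark in cfg$marks) {
        tab <- reg$tables[[paste(mark, ct, sep = "_")]]
        if (nrow(tab) == 0) next
        regions <- data.frame(chrom = tab$chrom, start = tab$start - 1L,
                              end = tab$end, direction = tab$direction,
                              fold_change = tab$fold_change,
                              q_value = tab$q_value, mark = mark,
                              contrast = ct, stringsAsFactors = FALSE)
        sets_by_ct[[ct]] <- rbind(sets_by_ct[[ct]],
          annotate_regions_to_genes(regions, genome$genes)$feature_sets)
      }
    }
    strata <- unique(do.call(rbind, unname(sets_by_ct))[, c("mark", "direction")])
    calls <- do.call(rbind, lapply(seq_len(nrow(strata)), function(j) {
      classify_reprogramming(build_contrast_sets(
        sets_by_ct[["AGE"]], sets_by_ct[["NEONATAL"]], sets_by_ct[["ADULT"]],
        mark = strata$mark[j], direction = strata$direction[j]))
    }))
    score_class_recovery(calls, reg$gene_truth)$recovery
  }
  seeds <- 1:8
  mean_rec <- vapply(c(0, 0.15, 0.3), function(dp) {
    mean(vapply(seeds, function(s) recovery_at(dp, s), numeric(1)))
  }, numeric(1))
  expect_equal(mean_rec[1], 1)
  expect_true(all(diff(mean_rec) < 0))
})
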