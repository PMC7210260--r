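# Synthetic-data generator with planted ground truth.
#
# Emulates the pipeline's three input families at desk scale:
#   (a) per-mark, per-direction differential-region tables across the
#       AGE / NEONATAL / ADULT contrasts, with reprogramming classes
#       planted per gene and enhancer;
#   (b) a metabolite-style abundance matrix with vehicle/exposed groups,
#       acquisition-day batches, missing values and planted recurrent
#       features;
#   (c) a hybrid gene+metabolite pathway compendium with one planted
#       enriched pathway, plus a matching differential-expression table.
#
# The genome layout is slot-based: genes, enhancers and distractor
# regions live on a common grid whose pitch exceeds twice the TSS window,
# so gene windows never overlap each other, enhancers never fall inside a
# TSS window, and distractor regions stay at least two windows away from
# every TSS. Identical config + seed gives byte-identical output files.

#' Simulation configuration with study-scale defaults
#'
#' Defaults mirror the study design at desk scale: four histone marks,
#' three contrasts, five vehicle and five exposed animals, 16 planted
#' recurrently increased and 10 recurrently decreased metabolites, and a
#' planted hybrid pathway.
#'
#' @param seed integer seed; fully determines all output.
#' @param n_genes,n_enhancers,n_chroms,chrom_size_bp genome scale.
#' @param window_bp TSS annotation window the layout must respect.
#' @param marks histone-mark labels.
#' @param class_fractions named fractions of features planted per
#'   reprogramming class (remainder unchanged); must sum to <= 1.
#' @param membership_dropout probability that an expected differential
#'   row is deleted (noise on the planted memberships).
#' @param n_distractors differential regions placed far from every TSS
#'   and enhancer.
#' @param n_states number of chromatin states tiling each chromosome.
#' @param omics list: `n_features`, `n_veh`, `n_edc`, `n_days`,
#'   `planted_up`, `planted_down`, `effect_sd_units` (planted shift in
#'   vehicle-sd units), `missing_rate`.
#' @param de list: `n_up`, `n_down` planted differentially expressed
#'   genes.
#' @param pathways list: `n_pathways` background pathways,
#'   `pathway_size`, `planted_genes` and `planted_metabolites` seeded
#'   into the planted pathway.
#' @return config list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 500, n_enhancers = 200,
                       n_chroms = 2, chrom_size_bp = 1e7,
                       window_bp = 3000,
                       marks = c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3"),
                       class_fractions = c(PRECOCIOUS = 0.25, EDC_SPECIFIC = 0.05,
                                           CUMULATIVE = 0.05, LATER_ONSET = 0.05,
                                           AGE_ONLY = 0.10, NEONATAL_TRANSIENT = 0.05,
                                           AGE_AND_ADULT = 0.05),
                       membership_dropout = 0,
                       n_distractors = 60,
                       n_states = 8,
                       omics = list(n_features = 120, n_veh = 5, n_edc = 5,
                                    n_days = 2, planted_up = 16, planted_down = 10,
                                    effect_sd_units = 3, missing_rate = 0.05),
                       de = list(n_up = 40, n_down = 30),
                       pathways = list(n_pathways = 20, pathway_size = 10,
                                       planted_genes = 5, planted_metabolites = 3)) {
  stopifnot(sum(class_fractions) <= 1,
            all(names(class_fractions) %in% REPROGRAMMING_CLASSES),
            membership_dropout >= 0, membership_dropout <= 1,
            n_genes > 0, n_enhancers > 0, n_chroms > 0, chrom_size_bp > 0)
  if (omics$planted_up + omics$planted_down > omics$n_features) {
    stop("planted omics features exceed n_features", call. = FALSE)
  }
  list(seed = as.integer(seed), n_genes = n_genes, n_enhancers = n_enhancers,
       n_chroms = n_chroms, chrom_size_bp = as.integer(chrom_size_bp),
       window_bp = window_bp, marks = marks,
       class_fractions = class_fractions,
       membership_dropout = membership_dropout,
       n_distractors = n_distractors, n_states = n_states,
       omics = omics, de = de, pathways = pathways)
}

CONTRASTS <- c("AGE", "NEONATAL", "ADULT")

# membership triple (A, N, D) per class
.class_membership <- list(PRECOCIOUS = c(1, 1, 0), EDC_SPECIFIC = c(0, 1, 1),
                          CUMULATIVE = c(1, 1, 1), LATER_ONSET = c(0, 0, 1),
                          AGE_ONLY = c(1, 0, 0), NEONATAL_TRANSIENT = c(0, 1, 0),
                          AGE_AND_ADULT = c(1, 0, 1))

#' Simulate the genome layout
#'
#' Places genes, enhancers and distractor anchor slots on a common grid
#' (pitch > 2 x `window_bp` + maximal region extent), tiles each
#' chromosome with a chromatin-state partition, and returns chromosome
#' sizes.
#'
#' @param config a [sim_config()].
#' @return list with `genes`, `enhancers`, `chrom_sizes`, `states`
#'   (segments data.frame) and `distractor_anchors` (data.frame
#'   `chrom`, `pos`).
#' @export
simulate_genome <- function(config) {
  pitch <- 2L * as.integer(config$window_bp) + 8000L
  margin <- 10000L
  per_chrom <- (config$chrom_size_bp - 2L * margin) %/% pitch
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, pos = margin + pitch * seq_len(per_chrom),
               stringsAsFactors = FALSE)
  }))
  need <- config$n_genes + config$n_enhancers + max(10L, config$n_distractors %/% 2L)
  if (nrow(slots) < need) {
    stop(sprintf("gene/enhancer density too high for the genome: %d slots available, %d needed; increase chrom_size_bp or n_chroms",
                 nrow(slots), need), call. = FALSE)
  }
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  g_idx <- seq_len(config$n_genes)
  e_idx <- config$n_genes + seq_len(config$n_enhancers)
  d_idx <- setdiff(seq_len(nrow(slots)), c(g_idx, e_idx))

  genes <- data.frame(gene_id = sprintf("g%04d", g_idx),
                      chrom = slots$chrom[g_idx], tss = slots$pos[g_idx],
                      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  ew <- sample(400:800, config$n_enhancers, replace = TRUE)
  enhancers <- data.frame(enhancer_id = sprintf("e%04d", seq_len(config$n_enhancers)),
                          chrom = slots$chrom[e_idx],
                          start = slots$pos[e_idx] - ew %/% 2L,
                          end = slots$pos[e_idx] + ew %/% 2L,
                          stringsAsFactors = FALSE)
  chrom_sizes <- stats::setNames(rep(config$chrom_size_bp, config$n_chroms), chroms)

  state_labels <- c("TssA", "TssFlnk", "EnhA", "EnhWk", "Tx", "ReprPC",
                    "TssBiv", "Quies")[seq_len(min(config$n_states, 8))]
  if (config$n_states > 8) {
    state_labels <- c(state_labels, sprintf("S%d", 9:config$n_states))
  }
  states <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- 0L; segs <- list()
    while (pos < config$chrom_size_bp) {
      len <- min(sample(20000:500000, 1), config$chrom_size_bp - pos)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = pos + len,
        state = sample(state_labels, 1), stringsAsFactors = FALSE)
      pos <- pos + len
    }
    do.call(rbind, segs)
  }))
  list(genes = genes, enhancers = enhancers, chrom_sizes = chrom_sizes,
       states = states,
       distractor_anchors = slots[d_idx, , drop = FALSE])
}

# Plant a class, mark and direction on a fraction of features.
.plant_classes <- function(ids, class_fractions, marks) {
  n <- length(ids)
  counts <- floor(class_fractions * n)
  planted_ids <- sample(ids, sum(counts))
  klass <- rep(names(counts), counts)
  truth <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  truth$klass <- NA_character_
  truth$klass[match(planted_ids, truth$feature_id)] <- klass
  truth$mark <- NA_character_
  truth$direction <- NA_character_
  planted <- !is.na(truth$klass)
  truth$mark[planted] <- sample(marks, sum(planted), replace = TRUE)
  truth$direction[planted] <- sample(c("up", "down"), sum(planted), replace = TRUE)
  mem <- t(vapply(truth$klass, function(k) {
    if (is.na(k)) c(0, 0, 0) else .class_membership[[k]]
  }, numeric(3)))
  truth$in_A <- mem[, 1] == 1
  truth$in_N <- mem[, 2] == 1
  truth$in_D <- mem[, 3] == 1
  truth
}

#' Simulate differential-region tables with planted reprogramming classes
#'
#' For every feature planted with a class whose membership includes a
#' contrast, one region is emitted in that contrast's table for the
#' feature's mark and direction, placed within the TSS window (genes) or
#' overlapping the element (enhancers), with q and fold change passing
#' the loader defaults. `membership_dropout` independently deletes
#' expected rows. Distractor regions are placed on anchors at least two
#' windows away from every TSS.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list with `tables` (named list `<mark>_<contrast>` of
#'   diffReps-convention data.frames), `gene_truth`, `enhancer_truth`.
#' @export
simulate_differential_regions <- function(config, genome) {
  gene_truth <- .plant_classes(genome$genes$gene_id, config$class_fractions,
                               config$marks)
  enh_truth <- .plant_classes(genome$enhancers$enhancer_id,
                              config$class_fractions, config$marks)

  mk_row <- function(chrom, start0, end0, direction) {
    data.frame(chrom = chrom, start = start0 + 1L, end = end0,  # diffReps 1-based inclusive
               direction = direction,
               fold_change = round(stats::runif(1, 2.2, 6), 3),
               q_value = signif(10^-stats::runif(1, 3, 8), 4),
               stringsAsFactors = FALSE)
  }
  tables <- list()
  for (mark in config$marks) for (ct in CONTRASTS) {
    tables[[paste(mark, ct, sep = "_")]] <- list()
  }
  add_row <- function(mark, ct, row) {
    key <- paste(mark, ct, sep = "_")
    tables[[key]][[length(tables[[key]]) + 1L]] <<- row
  }

  in_ct <- function(truth, i, ct) switch(ct, AGE = truth$in_A[i],
                                         NEONATAL = truth$in_N[i],
                                         ADULT = truth$in_D[i])
  # gene-anchored regions
  for (i in seq_len(nrow(gene_truth))) {
    if (is.na(gene_truth$klass[i])) next
    g <- genome$genes[i, ]
    for (ct in CONTRASTS) {
      if (!in_ct(gene_truth, i, ct)) next
      if (stats::runif(1) < config$membership_dropout) next
      centre <- g$tss + sample(-1800:1800, 1)
      w <- sample(200:800, 1)
      add_row(gene_truth$mark[i], ct,
              mk_row(g$chrom, centre - w %/% 2L, centre + w %/% 2L,
                     gene_truth$direction[i]))
    }
  }
  # enhancer-anchored regions
  for (i in seq_len(nrow(enh_truth))) {
    if (is.na(enh_truth$klass[i])) next
    e <- genome$enhancers[i, ]
    for (ct in CONTRASTS) {
      if (!in_ct(enh_truth, i, ct)) next
      if (stats::runif(1) < config$membership_dropout) next
      add_row(enh_truth$mark[i], ct,
              mk_row(e$chrom, e$start - sample(0:200, 1), e$end + sample(0:200, 1),
                     enh_truth$direction[i]))
    }
  }
  # distractors, far from every TSS and enhancer
  if (config$n_distractors > 0) {
    anc <- genome$distractor_anchors
    pick <- anc[sample.int(nrow(anc), config$n_distractors, replace = TRUE), ]
    for (j in seq_len(nrow(pick))) {
      centre <- pick$pos[j] + sample(-1500:1500, 1)
      w <- sample(200:800, 1)
      add_row(sample(config$marks, 1), sample(CONTRASTS, 1),
              mk_row(pick$chrom[j], centre - w %/% 2L, centre + w %/% 2L,
                     sample(c("up", "down"), 1)))
    }
  }
  tables <- lapply(tables, function(rows) {
    if (length(rows) == 0) {
      return(data.frame(chrom = character(), start = integer(), end = integer(),
                        direction = character(), fold_change = numeric(),
                        q_value = numeric(), stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, rows)
    df[order(df$chrom, df$start), , drop = FALSE]
  })
  list(tables = tables, gene_truth = gene_truth, enhancer_truth = enh_truth)
}

#' Simulate an omics matrix with planted recurrent features
#'
#' Baseline abundances are log-normal per feature; acquisition days add a
#' shared batch offset; planted features are shifted by
#' `effect_sd_units` vehicle standard deviations in at least `min_count`
#' randomly chosen exposed samples (never in the opposite direction);
#' entries go missing at `missing_rate`. The generator then verifies the
#' declared truth against the package's own processing chain (KNN
#' imputation, log2 day-median normalization, vehicle z-scores,
#' recurrence rule) and resamples any feature whose realized data
#' contradict its planted status, so emitted matrices realize the truth
#' exactly.
#'
#' @param config a [sim_config()].
#' @param z_thresh,min_count recurrence-rule parameters the truth is
#'   realized against (defaults 1.5 and 3).
#' @return list with `values` (raw abundance matrix, NAs for missing),
#'   `meta` (sample metadata) and `truth` (data.frame `feature_id`,
#'   `planted_status`).
#' @export
simulate_omics <- function(config, z_thresh = 1.5, min_count = 3) {
  oc <- config$omics
  n_feat <- oc$n_features
  samples <- c(sprintf("VEH_%d", seq_len(oc$n_veh)),
               sprintf("EDC_%d", seq_len(oc$n_edc)))
  group <- rep(c("VEH", "EDC"), c(oc$n_veh, oc$n_edc))
  day <- c(rep_len(sprintf("day%d", seq_len(oc$n_days)), oc$n_veh),
           rep_len(sprintf("day%d", seq_len(oc$n_days)), oc$n_edc))
  meta <- data.frame(sample_id = samples, group = group, day = day,
                     stringsAsFactors = FALSE)

  feat_ids <- sprintf("met%03d", seq_len(n_feat))
  status <- rep("NOT_RECURRENT", n_feat)
  planted <- sample.int(n_feat, oc$planted_up + oc$planted_down)
  status[planted[seq_len(oc$planted_up)]] <- "RECURRENT_UP"
  status[planted[oc$planted_up + seq_len(oc$planted_down)]] <- "RECURRENT_DOWN"

  mu <- stats::runif(n_feat, 8, 16)
  sigma <- stats::runif(n_feat, 0.3, 0.8)
  day_eff <- stats::setNames(stats::rnorm(oc$n_days, 0, 0.4),
                             sprintf("day%d", seq_len(oc$n_days)))
  edc_cols <- which(group == "EDC")

  gen_row <- function(i) {
    v <- mu[i] + day_eff[day] + stats::rnorm(length(samples), 0, sigma[i])
    if (status[i] != "NOT_RECURRENT") {
      n_aff <- sample(min_count:oc$n_edc, 1)
      aff <- sample(edc_cols, n_aff)
      shift <- oc$effect_sd_units * sigma[i]
      v[aff] <- v[aff] + if (status[i] == "RECURRENT_UP") shift else -shift
    }
    raw <- 2^v
    if (oc$missing_rate > 0) {
      miss <- stats::runif(length(raw)) < oc$missing_rate
      # keep enough observations for imputation and the vehicle reference
      if (sum(!miss) >= 4 && sum(!miss[group == "VEH"]) >= 2) raw[miss] <- NA
    }
    raw
  }
  x <- t(vapply(seq_len(n_feat), gen_row, numeric(length(samples))))
  dimnames(x) <- list(feat_ids, samples)

  # constrained resampling: emitted data must realize the declared truth
  # under the package's own processing chain
  for (iter in seq_len(100)) {
    z <- compute_zscores(normalize_log_median(knn_impute(x), day), group)
    rec <- recurrence_select(z, z_thresh = z_thresh, min_count = min_count)
    bad <- which(rec$status != status)
    if (length(bad) == 0) break
    for (i in bad) x[i, ] <- gen_row(i)
    if (iter == 100) stop("simulate_omics failed to realize the planted truth", call. = FALSE)
  }
  list(values = x, meta = meta,
       truth = data.frame(feature_id = feat_ids, planted_status = status,
                          stringsAsFactors = FALSE))
}

#' Simulate a differential-expression table with planted signature genes
#'
#' Planted up genes get fold change >= 1.25 and q < 0.1, planted down
#' genes fold change <= 0.8 and q < 0.1; background genes fail both the
#' q and the fold-change thresholds.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list with `de_table` (data.frame `gene`, `fold_change`, `q`)
#'   and `truth` (data.frame `gene`, `planted` in up/down/none).
#' @export
simulate_de <- function(config, genome) {
  ids <- genome$genes$gene_id
  n <- length(ids)
  if (config$de$n_up + config$de$n_down > n) {
    stop("planted DE genes exceed n_genes", call. = FALSE)
  }
  planted <- sample(ids, config$de$n_up + config$de$n_down)
  up <- planted[seq_len(config$de$n_up)]
  down <- planted[config$de$n_up + seq_len(config$de$n_down)]
  fc <- stats::runif(n, 0.85, 1.18)
  q <- stats::runif(n, 0.15, 0.95)
  fc[match(up, ids)] <- stats::runif(length(up), 1.4, 3.5)
  fc[match(down, ids)] <- stats::runif(length(down), 0.3, 0.75)
  q[match(planted, ids)] <- stats::runif(length(planted), 1e-4, 0.05)
  de_table <- data.frame(gene = ids, fold_change = round(fc, 4),
                         q = signif(q, 4), stringsAsFactors = FALSE)
  truth <- data.frame(gene = ids,
                      planted = ifelse(ids %in% up, "up",
                                ifelse(ids %in% down, "down", "none")),
                      stringsAsFactors = FALSE)
  list(de_table = de_table, truth = truth)
}

#' Simulate a hybrid pathway compendium with one planted pathway
#'
#' The planted pathway carries planted differentially expressed genes and
#' planted recurrent metabolites (filled up to `pathway_size` with
#' non-signature members); background pathways are uniform draws from the
#' universe.
#'
#' @param config a [sim_config()].
#' @param de_truth truth from [simulate_de()].
#' @param omics_truth truth from [simulate_omics()].
#' @return list with `pathways` (as [load_gene_sets()]), `universe`
#'   (namespaced character vector) and `truth` (data.frame `pathway_id`,
#'   `planted`).
#' @export
simulate_pathways <- function(config, de_truth, omics_truth) {
  pc <- config$pathways
  genes <- paste0("GENE:", de_truth$gene)
  mets <- paste0("MET:", omics_truth$feature_id)
  universe <- c(genes, mets)
  if (pc$pathway_size > length(universe)) {
    stop("pathway_size exceeds universe size", call. = FALSE)
  }
  sig_genes <- paste0("GENE:", de_truth$gene[de_truth$planted != "none"])
  sig_mets <- paste0("MET:", omics_truth$feature_id[omics_truth$planted_status != "NOT_RECURRENT"])
  background_pool <- setdiff(universe, c(sig_genes, sig_mets))

  stopifnot(pc$planted_genes <= length(sig_genes),
            pc$planted_metabolites <= length(sig_mets))
  filler <- pc$pathway_size - pc$planted_genes - pc$planted_metabolites
  planted_members <- c(sample(sig_genes, pc$planted_genes),
                       sample(sig_mets, pc$planted_metabolites),
                       sample(background_pool, max(0, filler)))
  pathways <- list(PW_planted = list(pathway_id = "PW_planted",
                                     name = "planted hybrid pathway",
                                     members = planted_members))
  for (i in seq_len(pc$n_pathways)) {
    id <- sprintf("PW_%03d", i)
    pathways[[id]] <- list(pathway_id = id, name = "background pathway",
                           members = sample(universe, pc$pathway_size))
  }
  truth <- data.frame(pathway_id = names(pathways),
                      planted = names(pathways) == "PW_planted",
                      stringsAsFactors = FALSE)
  list(pathways = pathways, universe = universe, truth = truth)
}

#' Run the full simulation and optionally write all pipeline inputs
#'
#' @param config a [sim_config()].
#' @param out_dir when given, all input files and truth tables are
#'   written there (created if absent): `genes.tsv`, `enhancers.bed`,
#'   `chrom.sizes`, `states.bed`, `diff_<mark>_<contrast>.tsv`,
#'   `omics.tsv`, `omics_meta.tsv`, `de_table.tsv`, `pathways.gmt`,
#'   `universe.txt` and `truth/*.tsv`.
#' @return (invisibly when writing) list with `genome`, `regions`,
#'   `omics`, `de`, `pathways` and `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  genome <- simulate_genome(config)
  regions <- simulate_differential_regions(config, genome)
  omics <- simulate_omics(config)
  de <- simulate_de(config, genome)
  pathways <- simulate_pathways(config, de$truth, omics$truth)
  sim <- list(genome = genome, regions = regions, omics = omics,
              de = de, pathways = pathways, config = config)
  if (!is.null(out_dir)) {
    write_simulation(sim, out_dir)
    return(invisible(sim))
  }
  sim
}

#' Write a simulation to disk
#'
#' @param sim output of [simulate_study()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  g <- sim$genome
  write_tsv_strict(g$genes, file.path(out_dir, "genes.tsv"))
  utils::write.table(g$enhancers[, c("chrom", "start", "end", "enhancer_id")],
                     file.path(out_dir, "enhancers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n")
  utils::write.table(data.frame(names(g$chrom_sizes), unname(g$chrom_sizes)),
                     file.path(out_dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n")
  utils::write.table(g$states, file.path(out_dir, "states.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n")
  for (key in names(sim$regions$tables)) {
    write_tsv_strict(sim$regions$tables[[key]],
                     file.path(out_dir, sprintf("diff_%s.tsv", key)))
  }
  om <- data.frame(feature_id = rownames(sim$omics$values),
                   sim$omics$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(om, file.path(out_dir, "omics.tsv"))
  write_tsv_strict(sim$omics$meta, file.path(out_dir, "omics_meta.tsv"))
  write_tsv_strict(sim$de$de_table, file.path(out_dir, "de_table.tsv"))
  gmt <- vapply(sim$pathways$pathways, function(pw) {
    paste(c(pw$pathway_id, pw$name, pw$members), collapse = "\t")
  }, character(1))
  writeLines(unname(gmt), file.path(out_dir, "pathways.gmt"))
  writeLines(sim$pathways$universe, file.path(out_dir, "universe.txt"))
  write_truth <- function(df, name) {
    path <- file.path(out_dir, "truth", name)
    writeLines("#truth_schema\t1", path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = TRUE,
                                        append = TRUE, eol = "\n"))
  }
  write_truth(sim$regions$gene_truth, "genes.tsv")
  write_truth(sim$regions$enhancer_truth, "enhancers.tsv")
  write_truth(sim$omics$truth, "omics.tsv")
  write_truth(sim$de$truth, "de.tsv")
  write_truth(sim$pathways$truth, "pathways.tsv")
  invisible(out_dir)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param path truth TSV path (first line is the schema header).
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Score recovery of planted reprogramming classes
#'
#' Joins classifier calls against the planted truth and reports the
#' fraction of planted features whose called class equals the planted
#' class within their (mark, direction) stratum.
#'
#' @param calls data.frame of calls (columns `feature_id`, `mark`,
#'   `direction`, `class`), typically rbind-ed over strata.
#' @param truth a gene or enhancer truth table from the simulation.
#' @return list with `n_planted`, `n_recovered`, `recovery` (fraction in
#'   \[0, 1\]).
#' @export
score_class_recovery <- function(calls, truth) {
  planted <- truth[!is.na(truth$klass), , drop = FALSE]
  key_t <- paste(planted$feature_id, planted$mark, planted$direction)
  key_c <- paste(calls$feature_id, calls$mark, calls$direction)
  got <- calls$class[match(key_t, key_c)]
  n_rec <- sum(!is.na(got) & got == planted$klass)
  list(n_planted = nrow(planted), n_recovered = n_rec,
       recovery = if (nrow(planted) == 0) NA_real_ else n_rec / nrow(planted))
}
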