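# End-to-end pipeline driver: annotate -> classify -> state-enrich ->
# omics-test -> recurrence -> MetSEA, from a single config, with a
# consolidated JSON + Markdown report.

#' Build a pipeline configuration
#'
#' All thresholds carry the analysis defaults; the flags record which of
#' the documented alternatives is active (Welch vs pooled t-test, mean vs
#' median z-score centre, count- vs bp-based odds ratio) and are echoed
#' in the report.
#'
#' @param genes path to gene models; `genes_format` `"tss"` or `"gtf"`.
#' @param enhancers enhancer BED path.
#' @param chrom_sizes chrom.sizes path.
#' @param states segmentation BED4 path.
#' @param regions data.frame with columns `path`, `mark`, `contrast`
#'   (contrast one of AGE/NEONATAL/ADULT), one row per differential
#'   table.
#' @param omics_matrix,omics_meta omics matrix and metadata paths.
#' @param de_table DE table path.
#' @param pathways hybrid GMT path.
#' @param universe path to a one-id-per-line universe file.
#' @param genes_format gene-model dialect.
#' @param window_bp,region_q_max,region_fc_min annotation thresholds.
#' @param z_thresh,min_count recurrence rule.
#' @param t_q_max lipid/metabolite t-test significance threshold.
#' @param de_q_max,de_fc_up,de_fc_down DE signature thresholds.
#' @param ora_q_max enrichment threshold.
#' @param knn_k imputation neighbours.
#' @param var_equal,z_center,or_unit documented alternative flags.
#' @param seed integer seed recorded in the report (the pipeline itself
#'   is deterministic).
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, enhancers, chrom_sizes, states, regions,
                            omics_matrix, omics_meta, de_table, pathways,
                            universe, genes_format = "tss",
                            window_bp = 3000, region_q_max = 0.01,
                            region_fc_min = 2, z_thresh = 1.5, min_count = 3,
                            t_q_max = 0.25, de_q_max = 0.1, de_fc_up = 1.25,
                            de_fc_down = 0.8, ora_q_max = 0.2, knn_k = 5,
                            var_equal = FALSE, z_center = "mean",
                            or_unit = "count", seed = 1) {
  structure(list(genes = genes, enhancers = enhancers,
                 chrom_sizes = chrom_sizes, states = states,
                 regions = regions, omics_matrix = omics_matrix,
                 omics_meta = omics_meta, de_table = de_table,
                 pathways = pathways, universe = universe,
                 genes_format = genes_format, window_bp = window_bp,
                 region_q_max = region_q_max, region_fc_min = region_fc_min,
                 z_thresh = z_thresh, min_count = min_count,
                 t_q_max = t_q_max, de_q_max = de_q_max,
                 de_fc_up = de_fc_up, de_fc_down = de_fc_down,
                 ora_q_max = ora_q_max, knn_k = knn_k,
                 var_equal = var_equal, z_center = z_center,
                 or_unit = or_unit, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Pipeline configuration pointing at a simulation directory
#'
#' @param sim_dir directory written by [simulate_study()].
#' @param ... threshold/flag overrides forwarded to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_simulation <- function(sim_dir, ...) {
  diff_files <- list.files(sim_dir, pattern = "^diff_.*\\.tsv$")
  parts <- sub("^diff_", "", sub("\\.tsv$", "", diff_files))
  mark <- sub("_[^_]+$", "", parts)
  contrast <- sub("^.*_", "", parts)
  regions <- data.frame(path = file.path(sim_dir, diff_files),
                        mark = mark, contrast = contrast,
                        stringsAsFactors = FALSE)
  pipeline_config(genes = file.path(sim_dir, "genes.tsv"),
                  enhancers = file.path(sim_dir, "enhancers.bed"),
                  chrom_sizes = file.path(sim_dir, "chrom.sizes"),
                  states = file.path(sim_dir, "states.bed"),
                  regions = regions,
                  omics_matrix = file.path(sim_dir, "omics.tsv"),
                  omics_meta = file.path(sim_dir, "omics_meta.tsv"),
                  de_table = file.path(sim_dir, "de_table.tsv"),
                  pathways = file.path(sim_dir, "pathways.gmt"),
                  universe = file.path(sim_dir, "universe.txt"), ...)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; `regions` is a list
#' of `{path, mark, contrast}` mappings.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$regions <- do.call(rbind, lapply(y$regions, function(r) {
    data.frame(path = r$path, mark = r$mark, contrast = r$contrast,
               stringsAsFactors = FALSE)
  }))
  do.call(pipeline_config, y)
}

.validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$genes, config$enhancers, config$chrom_sizes,
             config$states, config$regions$path, config$omics_matrix,
             config$omics_meta, config$de_table, config$pathways,
             config$universe)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("pipeline validation error: missing input file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!all(config$regions$contrast %in% CONTRASTS)) {
    stop("pipeline validation error: region contrasts must be AGE/NEONATAL/ADULT",
         call. = FALSE)
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes annotate, classify, state-enrich, omics-test, recurrence and
#' MetSEA in order, writing each stage's outputs under a stage-named
#' subdirectory of `out_dir` plus a consolidated `report.json` and
#' `report.md` (content deterministic; timings go to `run.log` only). A
#' stage failure leaves a `FAILED` marker naming the stage and rethrows.
#'
#' @param config a `pipeline_config` (or a YAML path).
#' @param out_dir output directory.
#' @return the report, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline started (seed %d)\n", config$seed), file = log_path)
  log_line <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_line("stage %s done in %.1fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  set.seed(config$seed)

  # --- annotate ---------------------------------------------------------
  ann <- stage("annotate", function() {
    d <- file.path(out_dir, "annotate"); dir.create(d, showWarnings = FALSE)
    genes <- load_gene_models(config$genes, format = config$genes_format)
    enhancers <- load_enhancers(config$enhancers)
    gene_sets <- list(); enh_sets <- list(); all_regions <- list()
    for (i in seq_len(nrow(config$regions))) {
      r <- config$regions[i, ]
      regions <- suppressMessages(load_differential_regions(
        r$path, mark = r$mark, contrast = r$contrast,
        q_max = config$region_q_max, fc_min = config$region_fc_min))
      all_regions[[paste(r$mark, r$contrast, sep = "_")]] <- regions
      if (nrow(regions) == 0) next
      gene_sets[[r$contrast]] <- rbind(
        gene_sets[[r$contrast]],
        annotate_regions_to_genes(regions, genes, config$window_bp)$feature_sets)
      enh_sets[[r$contrast]] <- rbind(
        enh_sets[[r$contrast]],
        annotate_regions_to_enhancers(regions, enhancers)$feature_sets)
    }
    for (ct in names(gene_sets)) {
      write_tsv_strict(gene_sets[[ct]], file.path(d, sprintf("gene_sets_%s.tsv", ct)))
      write_tsv_strict(enh_sets[[ct]], file.path(d, sprintf("enhancer_sets_%s.tsv", ct)))
    }
    list(gene_sets = gene_sets, enh_sets = enh_sets, regions = all_regions)
  })

  # --- classify ---------------------------------------------------------
  cls <- stage("classify", function() {
    d <- file.path(out_dir, "classify"); dir.create(d, showWarnings = FALSE)
    classify_kind <- function(sets_by_contrast, kind) {
      present <- unique(do.call(rbind, unname(sets_by_contrast))[, c("mark", "direction")])
      calls <- list(); summaries <- list()
      for (j in seq_len(nrow(present))) {
        m <- present$mark[j]; dr <- present$direction[j]
        sets <- build_contrast_sets(sets_by_contrast[["AGE"]],
                                    sets_by_contrast[["NEONATAL"]],
                                    sets_by_contrast[["ADULT"]],
                                    mark = m, direction = dr,
                                    feature_kind = kind)
        cl <- classify_reprogramming(sets)
        sm <- summarize_classes(cl, sets)
        calls[[j]] <- cl
        summaries[[j]] <- data.frame(
          feature_kind = kind, mark = m, direction = dr,
          t(sm$counts), n_A = sm$n_A, n_N = sm$n_N, n_D = sm$n_D,
          pct_precocious_of_age = sm$pct_precocious_of_age,
          adult_signature_count = sm$adult_signature_count,
          stringsAsFactors = FALSE)
      }
      list(calls = do.call(rbind, calls), summary = do.call(rbind, summaries))
    }
    gene_res <- classify_kind(ann$gene_sets, "gene")
    enh_res <- classify_kind(ann$enh_sets, "enhancer")
    write_tsv_strict(gene_res$calls, file.path(d, "gene_calls.tsv"))
    write_tsv_strict(enh_res$calls, file.path(d, "enhancer_calls.tsv"))
    summary <- rbind(gene_res$summary, enh_res$summary)
    summary <- summary[order(summary$feature_kind, summary$mark, summary$direction), ]
    rownames(summary) <- NULL
    write_tsv_strict(summary, file.path(d, "class_summary.tsv"))
    list(gene_calls = gene_res$calls, enh_calls = enh_res$calls,
         summary = summary)
  })

  # --- state enrichment -------------------------------------------------
  enr <- stage("state_enrich", function() {
    d <- file.path(out_dir, "state_enrich"); dir.create(d, showWarnings = FALSE)
    seg <- load_segmentation(config$states, config$chrom_sizes)
    out <- list()
    for (key in names(ann$regions)) {
      regions <- ann$regions[[key]]
      if (nrow(regions) == 0) next
      for (dr in unique(regions$direction)) {
        sub <- regions[regions$direction == dr, , drop = FALSE]
        res <- state_odds_ratio(sub, seg, unit = config$or_unit)
        out[[length(out) + 1L]] <- cbind(mark = sub$mark[1],
                                         contrast = sub$contrast[1],
                                         direction = dr, res)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    write_tsv_strict(res, file.path(d, "state_enrichment.tsv"))
    res
  })

  # --- omics testing + recurrence --------------------------------------
  om <- stage("omics", function() {
    d <- file.path(out_dir, "omics"); dir.create(d, showWarnings = FALSE)
    dat <- load_omics_matrix(config$omics_matrix, config$omics_meta)
    imputed <- suppressMessages(knn_impute(dat$values, k = config$knn_k))
    day <- if ("day" %in% names(dat$meta)) dat$meta$day else NULL
    norm <- normalize_log_median(imputed, day = day)
    tests <- feature_t_test(norm, dat$meta$group, q_max = config$t_q_max,
                            var_equal = config$var_equal)
    z <- compute_zscores(norm, dat$meta$group, center = config$z_center)
    rec <- recurrence_select(z, z_thresh = config$z_thresh,
                             min_count = config$min_count)
    norm_out <- data.frame(feature_id = rownames(norm), round(norm, 6),
                           check.names = FALSE)
    write_tsv_strict(norm_out, file.path(d, "normalized_matrix.tsv"))
    write_tsv_strict(tests, file.path(d, "t_tests.tsv"))
    write_tsv_strict(rec, file.path(d, "recurrence.tsv"))
    write_tsv_strict(zscore_long(z, config$z_thresh),
                     file.path(d, "oncoprint_long.tsv"))
    list(tests = tests, recurrence = rec)
  })

  # --- enrichment (signature + MetSEA) ---------------------------------
  met <- stage("metsea", function() {
    d <- file.path(out_dir, "metsea"); dir.create(d, showWarnings = FALSE)
    de <- read_tsv_strict(config$de_table)
    sig <- suppressMessages(build_signature(de, q_max = config$de_q_max,
                                            fc_up = config$de_fc_up,
                                            fc_down = config$de_fc_down))
    rec <- om$recurrence
    mets <- paste0("MET:", rec$feature_id[rec$status != "NOT_RECURRENT"])
    genes <- paste0("GENE:", sig$all)
    pathways <- load_gene_sets(config$pathways)
    universe <- readLines(config$universe, warn = FALSE)
    res <- run_metsea(genes, mets, pathways, universe,
                      q_max = config$ora_q_max)
    write_tsv_strict(res, file.path(d, "metsea.tsv"))
    barplot_tsv <- data.frame(pathway_id = res$pathway_id,
                              neg_log10_q = round(-log10(pmax(res$q_value, 1e-300)), 4))
    write_tsv_strict(barplot_tsv, file.path(d, "metsea_neglog10q.tsv"))
    list(signature = sig, metabolites = mets, results = res)
  })

  # --- report -----------------------------------------------------------
  report <- list(
    parameters = unclass(config)[c("genes_format", "window_bp", "region_q_max",
                                   "region_fc_min", "z_thresh", "min_count",
                                   "t_q_max", "de_q_max", "de_fc_up",
                                   "de_fc_down", "ora_q_max", "knn_k",
                                   "var_equal", "z_center", "or_unit", "seed")],
    class_summary = cls$summary,
    n_regions = vapply(ann$regions, nrow, integer(1)),
    state_enrichment_top = utils::head(
      enr[order(-ifelse(is.na(enr$odds_ratio), -Inf, enr$odds_ratio)), ], 10),
    omics = list(n_features = nrow(om$tests),
                 n_significant = sum(om$tests$significant, na.rm = TRUE),
                 n_recurrent_up = sum(om$recurrence$status == "RECURRENT_UP"),
                 n_recurrent_down = sum(om$recurrence$status == "RECURRENT_DOWN")),
    signature = list(n_up = length(met$signature$up),
                     n_down = length(met$signature$down),
                     n_metabolites = length(met$metabolites)),
    metsea_top = utils::head(met$results, 10))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  md <- c("# Pipeline report", "",
          sprintf("- differential tables: %d (kept regions: %s)",
                  length(ann$regions),
                  paste(report$n_regions, collapse = ", ")),
          sprintf("- class strata summarized: %d", nrow(cls$summary)),
          sprintf("- omics features tested: %d, significant at q<%g: %d",
                  report$omics$n_features, config$t_q_max,
                  report$omics$n_significant),
          sprintf("- recurrent metabolites: %d up, %d down",
                  report$omics$n_recurrent_up, report$omics$n_recurrent_down),
          sprintf("- hybrid signature: %d genes up, %d down, %d metabolites",
                  report$signature$n_up, report$signature$n_down,
                  report$signature$n_metabolites),
          sprintf("- top MetSEA pathway: %s (q = %.3g)",
                  met$results$pathway_id[1], met$results$q_value[1]),
          "",
          sprintf("Active alternatives: t-test = %s; z centre = %s; odds-ratio unit = %s; region thresholds q<%g FC>%gx; enrichment q<%g.",
                  ifelse(config$var_equal, "pooled", "Welch"),
                  config$z_center, config$or_unit, config$region_q_max,
                  config$region_fc_min, config$ora_q_max))
  writeLines(md, file.path(out_dir, "report.md"))
  log_line("pipeline finished")
  invisible(report)
}
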