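# Signature construction, gene-only over-representation analysis and the
# hybrid gene+metabolite MetSEA enrichment.
#
# Hybrid identifiers carry a kind namespace: "GENE:<id>" for genes and
# "MET:<id>" for metabolites. Plain (un-prefixed) ids are treated as
# genes where a kind matters.

#' Build a differential-expression signature
#'
#' Thresholds follow the transcriptomic signature definition: FDR q-value
#' below `q_max` and fold change at or above `fc_up` (up) or at or below
#' `fc_down` (down); the fold-change bounds are inclusive.
#'
#' @param de_table data.frame with columns `gene`, `q` (or `q_value`),
#'   and either `fold_change` (x scale) or `log2FC`.
#' @param q_max q-value threshold (default 0.1, strict).
#' @param fc_up minimum up fold change (default 1.25, inclusive).
#' @param fc_down maximum down fold change (default 0.8, inclusive).
#' @return object of class `signature`: list with character sets `up`,
#'   `down` and `all` (their union).
#' @export
build_signature <- function(de_table, q_max = 0.1, fc_up = 1.25, fc_down = 0.8) {
  names(de_table)[names(de_table) %in% c("q_value", "qvalue", "padj")] <- "q"
  names(de_table)[names(de_table) %in% c("gene_id", "feature_id")] <- "gene"
  require_columns(de_table, c("gene", "q"), "DE table")
  if (!"fold_change" %in% names(de_table)) {
    if (!"log2FC" %in% names(de_table)) {
      stop("DE table needs a fold_change or log2FC column", call. = FALSE)
    }
    de_table$fold_change <- 2^de_table$log2FC
  }
  sig_q <- de_table$q < q_max
  up <- unique(de_table$gene[sig_q & de_table$fold_change >= fc_up])
  down <- unique(de_table$gene[sig_q & de_table$fold_change <= fc_down])
  message(sprintf("build_signature: %d up, %d down of %d genes (q<%g, FC>=%gx or <=%gx)",
                  length(up), length(down), nrow(de_table), q_max, fc_up, fc_down))
  structure(list(up = sort(up), down = sort(down),
                 all = sort(union(up, down))), class = "signature")
}

#' Load pathways from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>member...`. Hybrid pathways may mix
#' `GENE:`/`MET:` namespaced members. Duplicate members within a line are
#' collapsed.
#'
#' @param path GMT path.
#' @return named list of pathways, each a list with `pathway_id`,
#'   `name` (the description field) and `members` (character set).
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    out[[fields[1]]] <- list(pathway_id = fields[1], name = fields[2],
                             members = unique(fields[-(1:2)]))
  }
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: drawing `n` features
#' from a universe of `M` containing `K` pathway members. Exact
#' (no normal approximation).
#'
#' @param k observed overlap.
#' @param n signature size (in-universe).
#' @param K pathway size (in-universe).
#' @param M universe size.
#' @return the p-value.
#' @export
hypergeometric_tail <- function(k, n, K, M) {
  if (k < 0 || n < 0 || K < 0 || M < 1 || n > M || K > M || k > min(n, K)) {
    stop(sprintf("impossible hypergeometric configuration (k=%s, n=%s, K=%s, M=%s)",
                 k, n, K, M), call. = FALSE)
  }
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a signature against pathway sets
#'
#' The signature and every pathway are first restricted to the declared
#' universe; each pathway's overlap with the signature is scored by the
#' exact hypergeometric upper tail and BH q-values are computed over all
#' pathways tested. Results are sorted by q, then p, then pathway id, so
#' output is invariant to pathway input order.
#'
#' @param signature a `signature` object or character vector of feature
#'   ids.
#' @param pathways list of pathways (see [load_gene_sets()]).
#' @param universe character vector of measurable feature ids.
#' @param q_max enrichment threshold on the q-value (default 0.2).
#' @return data.frame `pathway_id`, `name`, `k`, `n`, `K`, `M`, `p_value`,
#'   `q_value`, `enriched`, `gene_overlap`, `met_overlap`.
#' @export
run_ora <- function(signature, pathways, universe, q_max = 0.2) {
  ids <- if (inherits(signature, "signature")) signature$all else unique(signature)
  universe <- unique(universe)
  M <- length(universe)
  sig <- intersect(ids, universe)
  if (length(sig) == 0) warning("signature is empty after restriction to the universe")
  n <- length(sig)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(unique(pw$members), universe)
    hit <- intersect(sig, members)
    data.frame(pathway_id = pw$pathway_id, name = pw$name,
               k = length(hit), n = n, K = length(members), M = M,
               p_value = hypergeometric_tail(length(hit), n, length(members), M),
               gene_overlap = sum(!startsWith(hit, "MET:")),
               met_overlap = sum(startsWith(hit, "MET:")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$q_value < q_max
  out <- out[order(out$q_value, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway_id", "name", "k", "n", "K", "M", "p_value", "q_value",
          "enriched", "gene_overlap", "met_overlap")]
}

#' Hybrid gene+metabolite set enrichment (MetSEA)
#'
#' The hybrid signature is the union of the gene signature and the
#' recurrent metabolites (both restricted to the universe of measurable
#' genes and metabolites); enrichment against hybrid pathways is then the
#' same exact hypergeometric contract as [run_ora()], with the gene and
#' metabolite parts of each overlap reported separately. On a gene-only
#' signature and gene-only pathways this reduces exactly to [run_ora()].
#'
#' @param gene_signature a `signature` object or character vector of
#'   `GENE:`-namespaced (or plain) gene ids.
#' @param metabolites character vector of `MET:`-namespaced metabolite
#'   ids (for example recurrent metabolites from [recurrence_select()]).
#' @param pathways list of hybrid pathways.
#' @param universe measurable genes and metabolites, namespaced.
#' @param q_max enrichment threshold on the q-value (default 0.2; the
#'   looser 0.25 variant is a valid alternative).
#' @return as [run_ora()].
#' @export
run_metsea <- function(gene_signature, metabolites, pathways, universe,
                       q_max = 0.2) {
  genes <- if (inherits(gene_signature, "signature")) gene_signature$all else unique(gene_signature)
  hybrid <- union(genes, unique(metabolites))
  run_ora(hybrid, pathways, universe, q_max = q_max)
}

#' Overlap of a signature with a target gene set
#'
#' Counts signature features (overall and per direction) falling in an
#' external target set, for instance the targets of a transcription
#' factor.
#'
#' @param signature a `signature` object or character vector.
#' @param targets character vector of target feature ids.
#' @return data.frame with rows `all`, `up`, `down` (vector input yields
#'   only `all`) and columns `n_signature`, `n_overlap`, `pct`.
#' @export
target_overlap <- function(signature, targets) {
  targets <- unique(targets)
  one <- function(ids) {
    ids <- unique(ids)
    k <- length(intersect(ids, targets))
    data.frame(n_signature = length(ids), n_overlap = k,
               pct = percent_of(k, length(ids)))
  }
  if (inherits(signature, "signature")) {
    out <- rbind(one(signature$all), one(signature$up), one(signature$down))
    out <- cbind(set = c("all", "up", "down"), out)
  } else {
    out <- cbind(set = "all", one(signature))
  }
  rownames(out) <- NULL
  out
}
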