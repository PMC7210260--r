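# Differential testing of metabolite/lipid matrices and the z-score
# recurrence rule.
#
# Matrices are features x samples. Sample metadata is a data.frame with
# columns sample_id, group ("VEH"/"EDC") and optionally day (acquisition
# batch). Missing values are NA.

#' Read an omics matrix and its sample metadata
#'
#' @param matrix_path TSV with features in rows; first column is the
#'   feature id, remaining columns one per sample.
#' @param meta_path TSV with columns `sample_id`, `group` and optionally
#'   `day`.
#' @return list with `values` (numeric matrix, feature ids as rownames)
#'   and `meta` (data.frame ordered as the matrix columns).
#' @export
load_omics_matrix <- function(matrix_path, meta_path) {
  df <- read_tsv_strict(matrix_path)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- as.character(df[[1]])
  meta <- read_tsv_strict(meta_path)
  require_columns(meta, c("sample_id", "group"), "sample metadata")
  missing <- setdiff(colnames(x), meta$sample_id)
  if (length(missing) > 0) {
    stop(sprintf("samples absent from metadata: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(values = x, meta = meta)
}

#' K-nearest-neighbour imputation of missing matrix entries
#'
#' Neighbours are features. For each missing cell, the distance between
#' the target feature and every candidate feature is the Euclidean
#' distance over their co-observed samples, scaled to a per-sample root
#' mean square so features sharing few samples are comparable to features
#' sharing many. Candidates must themselves be observed in the target
#' sample. The imputed value is the mean of the `k` nearest candidates'
#' values in that sample; when fewer than `k` candidates exist all of
#' them are used (with a message). Observed entries are never altered.
#'
#' @param x numeric matrix (features x samples), NAs mark missing values.
#' @param k number of neighbours (default 5).
#' @return the completed matrix.
#' @export
knn_impute <- function(x, k = 5) {
  stopifnot(is.matrix(x), k >= 1)
  zero_obs <- rowSums(!is.na(x)) == 0
  if (any(zero_obs)) {
    stop(sprintf("feature(s) with zero observations: %s",
                 paste(rownames(x)[zero_obs], collapse = ", ")), call. = FALSE)
  }
  if (!anyNA(x)) return(x)
  out <- x
  for (i in which(rowSums(is.na(x)) > 0)) {
    target <- x[i, ]
    cand <- setdiff(seq_len(nrow(x)), i)
    # rms distance over co-observed samples
    d <- vapply(cand, function(j) {
      co <- !is.na(target) & !is.na(x[j, ])
      if (!any(co)) return(Inf)
      sqrt(mean((target[co] - x[j, co])^2))
    }, numeric(1))
    for (s in which(is.na(target))) {
      ok <- cand[!is.na(x[cand, s]) & is.finite(d)]
      if (length(ok) == 0) {
        stop(sprintf("no neighbour observed in sample %s for feature %s",
                     colnames(x)[s] %||% s, rownames(x)[i] %||% i), call. = FALSE)
      }
      if (length(ok) < k) {
        message(sprintf("knn_impute: only %d neighbour(s) available for feature %s, sample %s (k = %d)",
                        length(ok), rownames(x)[i] %||% i, colnames(x)[s] %||% s, k))
      }
      nn <- ok[order(d[match(ok, cand)])][seq_len(min(k, length(ok)))]
      out[i, s] <- mean(x[nn, s])
    }
  }
  out
}

#' Log2 transform and day-median normalization
#'
#' Values are log2 transformed, then the median of all entries of each
#' acquisition day's samples is subtracted from those samples, so each
#' day's value distribution is centred at zero. With a single day (or
#' `day = NULL`) this reduces to global median centring.
#'
#' @param x numeric matrix of strictly positive abundances.
#' @param day per-sample day labels (length `ncol(x)`), or `NULL`.
#' @param log_transform set `FALSE` if `x` is already on the log2 scale.
#' @return normalized matrix.
#' @export
normalize_log_median <- function(x, day = NULL, log_transform = TRUE) {
  stopifnot(is.matrix(x))
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE)) {
      stop("non-positive value: log2 transform requires strictly positive abundances",
           call. = FALSE)
    }
    x <- log2(x)
  }
  if (is.null(day)) day <- rep("all", ncol(x))
  stopifnot(length(day) == ncol(x))
  for (d in unique(day)) {
    cols <- day == d
    x[, cols] <- x[, cols] - stats::median(x[, cols], na.rm = TRUE)
  }
  x
}

#' Per-feature two-sample t-test with BH FDR
#'
#' A two-sided t-test (Welch by default, pooled-variance behind
#' `var_equal = TRUE`) compares the two groups feature by feature;
#' Benjamini-Hochberg q-values are computed over all tested features.
#' Features with zero variance in both groups and equal means get
#' `t = 0`, `p = 1` by convention.
#'
#' @param x numeric matrix (features x samples), assumed already
#'   normalized on the log2 scale.
#' @param group per-sample group labels.
#' @param group_a reference group label (default `"VEH"`).
#' @param group_b test group label (default `"EDC"`).
#' @param q_max significance threshold on the q-value (default 0.25).
#' @param var_equal `FALSE` for Welch (default), `TRUE` for pooled.
#' @return data.frame `feature_id`, `t_statistic`, `p_value`, `q_value`,
#'   `mean_log2fc` (mean of `group_b` minus mean of `group_a`),
#'   `significant`.
#' @export
feature_t_test <- function(x, group, group_a = "VEH", group_b = "EDC",
                           q_max = 0.25, var_equal = FALSE) {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  a_cols <- group == group_a
  b_cols <- group == group_b
  if (sum(a_cols) < 2 || sum(b_cols) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  res <- t(apply(x, 1, function(v) {
    a <- v[a_cols][!is.na(v[a_cols])]
    b <- v[b_cols][!is.na(v[b_cols])]
    if (length(a) < 2 || length(b) < 2) return(c(NA_real_, NA_real_, mean(b) - mean(a)))
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(c(0, 1, 0))
      return(c(Inf * sign(mean(b) - mean(a)), 0, mean(b) - mean(a)))
    }
    tt <- stats::t.test(b, a, var.equal = var_equal)
    c(unname(tt$statistic), tt$p.value, mean(b) - mean(a))
  }))
  out <- data.frame(feature_id = rownames(x),
                    t_statistic = res[, 1], p_value = res[, 2],
                    q_value = stats::p.adjust(res[, 2], method = "BH"),
                    mean_log2fc = res[, 3], stringsAsFactors = FALSE)
  out$significant <- !is.na(out$q_value) & out$q_value < q_max
  rownames(out) <- NULL
  out
}

#' Per-feature z-scores of exposed samples against the vehicle reference
#'
#' For every feature, the centre (mean by default, median behind
#' `center = "median"`) and the sample standard deviation (n - 1
#' denominator) are computed within the reference group; each exposed
#' sample's z-score is its distance from the centre in reference standard
#' deviations. Features whose reference standard deviation is zero get
#' `NA` z-scores and are reported with a warning.
#'
#' @param x numeric matrix (features x samples), normalized.
#' @param group per-sample group labels.
#' @param reference reference group label (default `"VEH"`).
#' @param target exposed group label (default `"EDC"`).
#' @param center `"mean"` (default) or `"median"`.
#' @return numeric matrix features x exposed-samples of z-scores.
#' @export
compute_zscores <- function(x, group, reference = "VEH", target = "EDC",
                            center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.matrix(x), length(group) == ncol(x))
  ref <- x[, group == reference, drop = FALSE]
  tgt <- x[, group == target, drop = FALSE]
  if (ncol(ref) < 2) stop("need at least two reference samples", call. = FALSE)
  ctr <- apply(ref, 1, if (center == "mean") mean else stats::median, na.rm = TRUE)
  sdv <- apply(ref, 1, stats::sd, na.rm = TRUE)
  degenerate <- !is.na(sdv) & sdv == 0
  if (any(degenerate)) {
    warning(sprintf("zero reference sd, z undefined for: %s",
                    paste(rownames(x)[degenerate], collapse = ", ")))
    sdv[degenerate] <- NA_real_
  }
  z <- sweep(sweep(tgt, 1, ctr, "-"), 1, sdv, "/")
  dimnames(z) <- list(rownames(x), colnames(tgt))
  z
}

#' Recurrence-based metabolite selection (Oncoprint rule)
#'
#' A feature is `RECURRENT_UP` when its z-score is at least `z_thresh`
#' in at least `min_count` exposed animals and at most `-z_thresh` in
#' none; `RECURRENT_DOWN` is the mirror image; anything else is
#' `NOT_RECURRENT`. Both thresholds are inclusive ("at least").
#'
#' @param z z-score matrix (features x exposed samples), as produced by
#'   [compute_zscores()].
#' @param z_thresh z-score threshold in reference standard deviations
#'   (default 1.5).
#' @param min_count minimum number of concordant animals (default 3).
#' @return data.frame `feature_id`, `n_up`, `n_down`, `status`.
#' @export
recurrence_select <- function(z, z_thresh = 1.5, min_count = 3) {
  stopifnot(is.matrix(z), z_thresh > 0, min_count >= 1)
  n_up <- rowSums(z >= z_thresh, na.rm = TRUE)
  n_down <- rowSums(z <= -z_thresh, na.rm = TRUE)
  status <- ifelse(n_up >= min_count & n_down == 0, "RECURRENT_UP",
            ifelse(n_down >= min_count & n_up == 0, "RECURRENT_DOWN",
                   "NOT_RECURRENT"))
  data.frame(feature_id = rownames(z) %||% as.character(seq_len(nrow(z))),
             n_up = as.integer(n_up), n_down = as.integer(n_down),
             status = status, stringsAsFactors = FALSE)
}

#' Long-format z-score table for Oncoprint-style plotting
#'
#' @param z z-score matrix.
#' @param z_thresh category threshold (default 1.5).
#' @return data.frame `feature_id`, `sample_id`, `z`, `category`
#'   (`up` / `down` / `none`).
#' @export
zscore_long <- function(z, z_thresh = 1.5) {
  df <- data.frame(feature_id = rep(rownames(z), times = ncol(z)),
                   sample_id = rep(colnames(z), each = nrow(z)),
                   z = as.vector(z), stringsAsFactors = FALSE)
  df$category <- ifelse(is.na(df$z), NA_character_,
                 ifelse(df$z >= z_thresh, "up",
                 ifelse(df$z <= -z_thresh, "down", "none")))
  df
}
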