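# Classification of features into reprogramming classes from their
# membership across the three contrasts:
#   A — AGE      (vehicle PND5 vs vehicle D70; normal liver maturation)
#   N — NEONATAL (PND5 EDC vs vehicle)
#   D — ADULT    (D70 EDC vs vehicle)
#
# The seven non-empty membership triples (in A, in N, in D) partition
# A union N union D:
#   (1,1,0) PRECOCIOUS          exposure pre-installs the adult signature;
#                               adults are indistinguishable from controls
#   (0,1,1) EDC_SPECIFIC        acute change persisting to adulthood,
#                               absent from normal maturation
#   (1,1,1) CUMULATIVE          maturation change exaggerated by exposure
#   (0,0,1) LATER_ONSET         adult-only difference, neither acute nor
#                               age-associated
#   (1,0,0) AGE_ONLY            maturation change untouched by exposure
#   (0,1,0) NEONATAL_TRANSIENT  acute change that resolves by adulthood
#   (1,0,1) AGE_AND_ADULT       age change also different in exposed adults
#                               without an acute neonatal effect

#' The seven reprogramming class labels
#' @export
REPROGRAMMING_CLASSES <- c("PRECOCIOUS", "EDC_SPECIFIC", "CUMULATIVE",
                           "LATER_ONSET", "AGE_ONLY", "NEONATAL_TRANSIENT",
                           "AGE_AND_ADULT")

#' Build the contrast set triple for one (mark, direction) stratum
#'
#' @param age,neonatal,adult feature-set data.frames (columns
#'   `feature_id`, `mark`, `direction`, `contrast`; see
#'   [annotate_regions_to_genes()]) or plain character vectors of feature
#'   ids. A missing/empty input yields the empty set, which is valid.
#' @param mark,direction the stratum; when the inputs are feature-set
#'   data.frames carrying several strata, rows are filtered to this one.
#'   Mandatory when inputs are plain vectors.
#' @param feature_kind `"gene"` or `"enhancer"` (metadata only).
#' @return an object of class `contrast_sets`: list with character-set
#'   members `A`, `N`, `D` and fields `mark`, `direction`, `feature_kind`.
#' @export
build_contrast_sets <- function(age = NULL, neonatal = NULL, adult = NULL,
                                mark, direction = c("up", "down"),
                                feature_kind = c("gene", "enhancer")) {
  direction <- match.arg(direction)
  feature_kind <- match.arg(feature_kind)
  pick <- function(x) {
    if (is.null(x)) return(character())
    if (is.character(x)) return(unique(x))
    require_columns(x, c("feature_id", "mark", "direction"), "feature-set table")
    known <- unique(x$mark)
    # a single-stratum table of a different mark is a caller error; a
    # multi-mark table is simply filtered to the requested stratum
    if (nrow(x) > 0 && length(known) == 1 && known != mark) {
      stop(sprintf("feature-set table carries mark %s but stratum requests %s",
                   known, mark), call. = FALSE)
    }
    unique(x$feature_id[x$mark == mark & x$direction == direction])
  }
  structure(list(A = sort(pick(age)), N = sort(pick(neonatal)),
                 D = sort(pick(adult)),
                 mark = mark, direction = direction,
                 feature_kind = feature_kind),
            class = "contrast_sets")
}

# The truth table: names are "A N D" membership bits.
.class_table <- c("110" = "PRECOCIOUS",
                  "011" = "EDC_SPECIFIC",
                  "111" = "CUMULATIVE",
                  "001" = "LATER_ONSET",
                  "100" = "AGE_ONLY",
                  "010" = "NEONATAL_TRANSIENT",
                  "101" = "AGE_AND_ADULT")

#' Classify features into reprogramming classes
#'
#' Every feature in `A | N | D` receives exactly one class determined
#' by its membership triple; features in none of the sets receive no call.
#'
#' @param sets a `contrast_sets` object (see [build_contrast_sets()]).
#' @return data.frame `feature_id`, `mark`, `direction`, `in_A`, `in_N`,
#'   `in_D`, `class`, ordered by `feature_id`.
#' @export
classify_reprogramming <- function(sets) {
  stopifnot(inherits(sets, "contrast_sets"))
  universe <- sort(unique(c(sets$A, sets$N, sets$D)))
  if (length(universe) == 0) {
    return(data.frame(feature_id = character(), mark = character(),
                      direction = character(), in_A = logical(),
                      in_N = logical(), in_D = logical(),
                      class = character(), stringsAsFactors = FALSE))
  }
  in_A <- universe %in% sets$A
  in_N <- universe %in% sets$N
  in_D <- universe %in% sets$D
  key <- paste0(as.integer(in_A), as.integer(in_N), as.integer(in_D))
  calls <- data.frame(feature_id = universe,
                      mark = sets$mark, direction = sets$direction,
                      in_A = in_A, in_N = in_N, in_D = in_D,
                      class = unname(.class_table[key]),
                      stringsAsFactors = FALSE)
  # partition property, asserted on every run
  stopifnot(!anyNA(calls$class), !anyDuplicated(calls$feature_id))
  calls
}

#' Summarize reprogramming calls
#'
#' @param calls output of [classify_reprogramming()].
#' @param sets the `contrast_sets` the calls were produced from.
#' @return an object of class `class_summary`: list with `counts` (named
#'   integer vector over the seven classes), set sizes `n_A`, `n_N`,
#'   `n_D`, `pct_precocious_of_age` (`100 * PRECOCIOUS / |A|`, rounded
#'   half-up; `NA` when `|A| = 0`), `adult_signature_count`
#'   (`PRECOCIOUS + CUMULATIVE`), and `mark`/`direction`/`feature_kind`.
#' @export
summarize_classes <- function(calls, sets) {
  stopifnot(inherits(sets, "contrast_sets"))
  counts <- vapply(REPROGRAMMING_CLASSES,
                   function(k) sum(calls$class == k), integer(1))
  n_union <- length(unique(c(sets$A, sets$N, sets$D)))
  stopifnot(sum(counts) == n_union)
  structure(list(
    counts = counts,
    n_A = length(sets$A), n_N = length(sets$N), n_D = length(sets$D),
    pct_precocious_of_age = percent_of(counts[["PRECOCIOUS"]], length(sets$A)),
    adult_signature_count = counts[["PRECOCIOUS"]] + counts[["CUMULATIVE"]],
    mark = sets$mark, direction = sets$direction,
    feature_kind = sets$feature_kind), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("Reprogramming summary [%s %s, %s]\n", x$mark, x$direction, x$feature_kind))
  cat(sprintf("  |A|=%d |N|=%d |D|=%d\n", x$n_A, x$n_N, x$n_D))
  for (k in names(x$counts)) cat(sprintf("  %-18s %d\n", k, x$counts[[k]]))
  cat(sprintf("  precocious %% of age-associated set: %s\n",
              ifelse(is.na(x$pct_precocious_of_age), "undefined",
                     paste0(x$pct_precocious_of_age, "%"))))
  cat(sprintf("  adult-signature features (precocious + cumulative): %d\n",
              x$adult_signature_count))
  invisible(x)
}

#' Overlap of a class with an external feature signature
#'
#' Counts how many features of a given reprogramming class fall in an
#' external signature (for example a differential-expression signature or
#' a transcription-factor target set).
#'
#' @param calls output of [classify_reprogramming()], or any data.frame
#'   with `feature_id` and `class` columns.
#' @param signature character vector of feature ids.
#' @param klass optional class filter (one of [REPROGRAMMING_CLASSES]);
#'   `NULL` uses all called features.
#' @return list with `n_class` (size of the filtered set), `n_overlap`,
#'   and `pct` (`100 * n_overlap / n_class`, rounded half-up; `NA` when
#'   the filtered set is empty).
#' @export
intersect_with_signature <- function(calls, signature, klass = NULL) {
  feats <- if (is.null(klass)) calls$feature_id else calls$feature_id[calls$class == klass]
  feats <- unique(feats)
  ov <- intersect(feats, unique(signature))
  list(n_class = length(feats), n_overlap = length(ov),
       pct = percent_of(length(ov), length(feats)),
       overlap = sort(ov))
}
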