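#' Screening performance metrics
#'
#' Confusion counts and the derived recall, specificity and Matthews
#' correlation coefficient:
#'
#' \deqn{R = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}
#'
#' When any factor of the MCC denominator is zero the coefficient is
#' reported as not determined (`"ND"`) -- in particular whenever a selective
#' model retrieves no true positive. Because the refinement protocol only
#' retains models that retrieve zero decoys, FP is always 0 and Sp always 1
#' for its ensembles.
#'
#' @name metrics
NULL

#' Confusion counts of a screening outcome
#'
#' @param hits character vector of retrieved molecule ids (must be a subset
#'   of actives plus decoys).
#' @param actives character vector of active molecule ids.
#' @param decoys character vector of decoy (inactive) molecule ids; must not
#'   overlap the actives.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(hits, actives, decoys) {
  if (length(intersect(actives, decoys))) {
    stop("active and decoy id sets overlap")
  }
  if (length(setdiff(hits, c(actives, decoys)))) {
    stop("hits contain ids outside the actives and decoys")
  }
  hits <- unique(hits)
  list(TP = length(intersect(hits, actives)),
       FP = length(intersect(hits, decoys)),
       TN = length(setdiff(decoys, hits)),
       FN = length(setdiff(actives, hits)))
}

#' Recall, specificity and MCC from confusion counts
#'
#' @param c4 list with `TP`, `FP`, `TN`, `FN` (as from [confusion()]).
#' @return list with `recall`, `specificity` and `mcc`; `mcc` is the string
#'   `"ND"` when its denominator vanishes, and recall/specificity are `NaN`
#'   when their own denominators are zero.
#' @export
compute_metrics <- function(c4) {
  tp <- c4$TP; fp <- c4$FP; tn <- c4$TN; fn <- c4$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  r <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  denom_factors <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  mcc <- if (any(denom_factors == 0)) "ND" else {
    (tp * tn - fp * fn) / sqrt(prod(denom_factors))
  }
  list(recall = r, specificity = sp, mcc = mcc)
}

#' Composition statistics of a pharmacophore set
#'
#' Counts enabled features (required and optional) per type and per model;
#' exclusion spheres are never counted as features.
#'
#' @param models list of [pharmacophore()]s.
#' @return list with `type_fractions` (named numeric summing to 1),
#'   `type_counts`, `feature_count_histogram` (table over per-model feature
#'   counts) and `median_features`. Empty list input yields empty stats.
#' @export
composition_stats <- function(models) {
  if (!length(models)) {
    return(list(type_fractions = numeric(0), type_counts = integer(0),
                feature_count_histogram = table(integer(0)),
                median_features = NA_real_))
  }
  per_model <- vapply(models, function(p) sum(!p$features$disabled), integer(1L))
  types <- unlist(lapply(models, function(p) {
    p$features$type[!p$features$disabled]
  }))
  counts <- table(factor(types, levels = FEATURE_TYPES))
  list(type_fractions = stats::setNames(as.numeric(counts) / sum(counts),
                                        FEATURE_TYPES),
       type_counts = stats::setNames(as.integer(counts), FEATURE_TYPES),
       feature_count_histogram = table(per_model),
       median_features = stats::median(per_model))
}

#' Compare feature-type composition between two pharmacophore sets
#'
#' Two-sided test on the per-model counts of each feature type
#' (Mann-Whitney U by default, Welch t as an alternative), reported with and
#' without Benjamini-Hochberg adjustment. With a single model on either side
#' the test is skipped with a warning.
#'
#' @param models_a,models_b lists of [pharmacophore()]s.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return data.frame with columns `type`, `p_value`, `p_adjusted` (BH), or
#'   `NULL` when skipped.
#' @export
compare_composition <- function(models_a, models_b,
                                test = c("wilcox", "t")) {
  test <- match.arg(test)
  stopifnot(length(models_a) >= 1L, length(models_b) >= 1L)
  if (length(models_a) < 2L || length(models_b) < 2L) {
    warning("composition comparison skipped: need >= 2 models per set",
            call. = FALSE)
    return(NULL)
  }
  count_types <- function(models) {
    t(vapply(models, function(p) {
      tab <- table(factor(p$features$type[!p$features$disabled],
                          levels = FEATURE_TYPES))
      as.numeric(tab)
    }, numeric(length(FEATURE_TYPES))))
  }
  a <- count_types(models_a); b <- count_types(models_b)
  pv <- vapply(seq_along(FEATURE_TYPES), function(k) {
    if (all(a[, k] == a[1L, k]) && all(b[, k] == b[1L, k]) &&
        a[1L, k] == b[1L, k]) return(1.0)
    suppressWarnings(
      if (test == "wilcox") stats::wilcox.test(a[, k], b[, k])$p.value
      else tryCatch(stats::t.test(a[, k], b[, k])$p.value,
                    error = function(e) NA_real_))  # zero-variance groups
  }, numeric(1L))
  data.frame(type = FEATURE_TYPES, p_value = pv,
             p_adjusted = stats::p.adjust(pv, method = "BH"))
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list with `tau` and `p_value` (normal approximation); both `"ND"`
#'   when either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(tau = "ND", p_value = "ND"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Screening report row (dataset x approach)
#'
#' @param dataset dataset label.
#' @param approach approach label (`"SB"`, `"LB"`, `"SBLB"`).
#' @param m a [compute_metrics()] result.
#' @return one-row data.frame with columns dataset, approach, R, Sp, MCC
#'   (MCC serialized as the literal string `"ND"` when not determined).
#' @export
metrics_report_row <- function(dataset, approach, m) {
  data.frame(dataset = dataset, approach = approach,
             R = round(m$recall, 3L), Sp = round(m$specificity, 3L),
             MCC = if (identical(m$mcc, "ND")) "ND" else
               sprintf("%.3f", m$mcc))
}
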