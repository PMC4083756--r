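#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative counts of true positives, false
#'   positives, true negatives, false negatives.
#' @return Named numeric vector of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cm <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cm)) || any(cm < 0)) {
    stop("confusion-matrix counts must be finite and non-negative",
         call. = FALSE)
  }
  structure(cm, class = "confusion_matrix")
}

#' Confusion matrix from predictions and truth
#'
#' @param prediction Character vector of `"damaging"` / `"tolerated"` calls.
#' @param positive Logical vector: is each case a true positive-class case?
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(prediction, positive) {
  stopifnot(length(prediction) == length(positive))
  called <- prediction == "damaging"
  confusion_matrix(tp = sum(called & positive),
                   fp = sum(called & !positive),
                   tn = sum(!called & !positive),
                   fn = sum(!called & positive))
}

# The six performance statistics on arbitrary (possibly fractional) cells.
# MCC is defined as 0 when its denominator vanishes (degenerate classifier).
six_stats <- function(tp, fp, tn, fn) {
  den <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / den
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    specificity = tn / (fp + tn),
    sensitivity = tp / (tp + fn),
    npv = if (tn + fn == 0) 0 else tn / (tn + fn),
    mcc = mcc)
}

check_both_classes <- function(cm) {
  if (cm[["tp"]] + cm[["fn"]] <= 0 || cm[["fp"]] + cm[["tn"]] <= 0) {
    stop("both classes must be non-empty (tp+fn > 0 and fp+tn > 0)",
         call. = FALSE)
  }
}

#' Class-normalized performance statistics
#'
#' Computes accuracy, precision, specificity, sensitivity, negative
#' predictive value and Matthews correlation coefficient after rescaling
#' each class to unit mass: with sensitivity `s = tp/(tp+fn)` and
#' false-positive rate `f = fp/(fp+tn)`, the statistics are evaluated on the
#' normalized cells `tp' = s`, `fn' = 1-s`, `fp' = f`, `tn' = 1-f`.
#' Sensitivity and specificity are unchanged by the rescaling; accuracy
#' becomes `(sensitivity + specificity)/2` and precision, NPV and MCC become
#' independent of class imbalance. This is the convention behind published
#' benchmark tables where the negative class is far larger than the positive
#' one.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector: `accuracy`, `precision`, `specificity`,
#'   `sensitivity`, `npv`, `mcc`.
#' @export
#' @examples
#' normalized_stats(confusion_matrix(tp = 4120, fp = 3123,
#'                                   tn = 77675, fn = 1983))
normalized_stats <- function(cm) {
  check_both_classes(cm)
  s <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
  f <- cm[["fp"]] / (cm[["fp"]] + cm[["tn"]])
  six_stats(tp = s, fn = 1 - s, fp = f, tn = 1 - f)
}

#' Raw (unnormalized) performance statistics
#'
#' The same six statistics evaluated directly on the raw counts. With heavy
#' class imbalance these can differ substantially from [normalized_stats()]
#' (precision and NPV in particular).
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector as in [normalized_stats()].
#' @export
raw_stats <- function(cm) {
  check_both_classes(cm)
  six_stats(tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]],
            fn = cm[["fn"]])
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score threshold (equal scores grouped into one
#' step) and accumulates the ROC curve; the AUC is the trapezoidal area,
#' which equals the Mann-Whitney concordance probability with ties counted
#' one half. By default a LOWER score means more positive (damaging), the
#' orientation of [weighted_score()].
#'
#' @param scores Finite numeric scores.
#' @param labels Logical vector (`TRUE` = positive class) or a vector
#'   coercible to one.
#' @param lower_is_positive Orientation; default `TRUE`.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
#' @examples
#' roc_auc(c(-3, -1, -2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc
roc_auc <- function(scores, labels, lower_is_positive = TRUE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  s <- if (lower_is_positive) scores else -scores
  ord <- order(s)
  s <- s[ord]
  lab <- labels[ord]
  # group ties: one ROC point per distinct score
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- cumsum(lab)[last] / P
  fpr <- cumsum(!lab)[last] / N
  thr <- s[last]
  points <- data.frame(threshold = c(-Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1L) +
                                 utils::tail(points$tpr, -1L)) / 2)
  list(points = points, auc = auc)
}

#' Protein-level k-fold cross-validation
#'
#' Partitions proteins (not variants) into `k` folds by a seeded shuffle,
#' re-estimates pathogenicity weights from the training folds only, scores
#' the held-out variants, and reports per-fold and pooled class-normalized
#' statistics. Folding by protein prevents weight leakage between training
#' and test through shared models.
#'
#' @param dataset A `mutation_dataset`.
#' @param set A [profile_set()].
#' @param scheme A [weight_scheme()].
#' @param k Number of folds (default 20).
#' @param seed Integer seed for the fold shuffle.
#' @param threshold Classification cut-off.
#' @param background Background composition.
#' @return List: `fold_assignment` (named by protein), `per_fold`
#'   (data.frame of fold statistics; `NA` where a fold lacks a class),
#'   `pooled` (stats + `auc` over all held-out scores), `scores` (all
#'   held-out scored variants, each exactly once), `confusion` (pooled
#'   [confusion_matrix()]).
#' @export
kfold_cv <- function(dataset, set, scheme, k = 20L, seed = 1L,
                     threshold = 0, background = aa_background()) {
  proteins <- unique(dataset$protein_id)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > length(proteins)) {
    stop("k = ", k, " exceeds the number of proteins (", length(proteins),
         ")", call. = FALSE)
  }
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  shuffled <- sample(proteins)
  fold <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                          shuffled)
  model_index <- variant_model_index(set, dataset)
  positive <- pathogenic_side(dataset, scheme)
  all_scores <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- dataset$protein_id %in% names(fold)[fold == f]
    train_counts <- count_mappings(dataset[!test, , drop = FALSE], scheme,
                                   model_index[!test])
    scored <- score_variants(dataset[test, , drop = FALSE], set,
                             train_counts, scheme, loo = FALSE,
                             background = background, threshold = threshold,
                             model_index = model_index[test])
    scored$fold <- f
    scored$positive <- positive[test]
    all_scores[[f]] <- scored
    stats_f <- tryCatch({
      cmf <- confusion_from_predictions(scored$prediction, scored$positive)
      normalized_stats(cmf)
    }, error = function(e) {
      stats::setNames(rep(NA_real_, 6L),
                      c("accuracy", "precision", "specificity",
                        "sensitivity", "npv", "mcc"))
    })
    per_fold[[f]] <- data.frame(fold = f, n = sum(test), t(stats_f))
  }
  scores <- do.call(rbind, all_scores)
  cm <- confusion_from_predictions(scores$prediction, scores$positive)
  pooled <- c(normalized_stats(cm),
              auc = roc_auc(scores$score, scores$positive)$auc)
  list(fold_assignment = fold,
       per_fold = do.call(rbind, per_fold),
       pooled = pooled,
       scores = scores,
       confusion = cm)
}

#' Benchmark scoring methods on a concept
#'
#' Scores the dataset with the requested methods and reports one row per
#' method with raw confusion counts, the six class-normalized statistics and
#' the AUC, with positives/negatives defined by [concept_split()]. Built-in
#' methods: `"disease_specific"` (weighted score under the concept's
#' disease-specific weights), `"inherited"` (weighted score under
#' whole-spectrum inherited-disease weights), `"naive"` (weights-only score
#' under the disease-specific weights). Externally computed score vectors
#' (lower = damaging) can be supplied via `extra_scores`.
#'
#' @param dataset A `mutation_dataset`.
#' @param set A [profile_set()].
#' @param concept Concept defining the positive class.
#' @param methods Character subset of the built-ins above.
#' @param extra_scores Named list of numeric score vectors aligned with
#'   `dataset` rows.
#' @param loo Leave-one-out weight adjustment for the built-in methods.
#' @param threshold Classification cut-off.
#' @param background Background composition.
#' @return Data.frame: `algorithm`, `tp`, `fp`, `tn`, `fn`, the six
#'   normalized statistics, `auc`.
#' @export
benchmark <- function(dataset, set, concept,
                      methods = c("disease_specific", "inherited", "naive"),
                      extra_scores = NULL, loo = TRUE, threshold = 0,
                      background = aa_background()) {
  concept <- match.arg(concept, disease_concepts())
  methods <- match.arg(methods, several.ok = TRUE)
  positive <- has_concept(dataset, concept) & dataset$label == "disease"
  if (!any(positive)) {
    stop("dataset has no positives for concept '", concept, "'",
         call. = FALSE)
  }
  model_index <- variant_model_index(set, dataset)
  ds_scheme <- weight_scheme("disease_specific", concept)
  score_sets <- list()
  if (any(c("disease_specific", "naive") %in% methods)) {
    ds_counts <- count_mappings(dataset, ds_scheme, model_index)
    ds <- score_variants(dataset, set, ds_counts, ds_scheme, loo = loo,
                         background = background, threshold = threshold,
                         model_index = model_index)
    if ("disease_specific" %in% methods) {
      score_sets[["disease_specific"]] <- ds$score
    }
    if ("naive" %in% methods) {
      score_sets[["naive"]] <- naive_score(ds$Wd, ds$Wn)
    }
  }
  if ("inherited" %in% methods) {
    in_scheme <- weight_scheme("inherited")
    in_counts <- count_mappings(dataset, in_scheme, model_index)
    inh <- score_variants(dataset, set, in_counts, in_scheme, loo = loo,
                          background = background, threshold = threshold,
                          model_index = model_index)
    score_sets[["inherited"]] <- inh$score
  }
  for (nm in names(extra_scores)) score_sets[[nm]] <- extra_scores[[nm]]
  rows <- lapply(names(score_sets), function(nm) {
    sc <- score_sets[[nm]]
    stopifnot(length(sc) == nrow(dataset))
    pred <- classify(sc, threshold)
    cm <- confusion_from_predictions(pred, positive)
    data.frame(algorithm = nm, tp = cm[["tp"]], fp = cm[["fp"]],
               tn = cm[["tn"]], fn = cm[["fn"]],
               t(normalized_stats(cm)),
               auc = roc_auc(sc, positive)$auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
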