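#' Fit a pathogenicity-weight model to labelled variants
#'
#' The central fitting function. Maps every training substitution onto the
#' models covering its residue (the protein's ab initio profile plus any
#' annotated domain models), tallies pathogenic- and neutral-side counts per
#' model under the chosen weighting scheme, and converts them to
#' pathogenicity weights `Wd = d/(d+n)`, `Wn = n/(d+n)`. The fitted object
#' carries everything needed to score new substitutions with
#' [predict.pathmm()].
#'
#' @param variants A `mutation_dataset` (see [read_variant_table()]).
#' @param profiles A [profile_set()].
#' @param scheme `"inherited"` or `"disease_specific"`.
#' @param concept Disease concept, required for the disease-specific scheme.
#' @param background Background amino-acid composition used for
#'   informativeness-based model selection; see [aa_background()].
#' @param threshold Default classification cut-off for predictions.
#' @return An object of class `pathmm` with components `weights` (per-model
#'   counts and weights), `scheme`, `profiles`, `data`, `model_index`,
#'   `background`, `threshold`.
#' @seealso [predict.pathmm()], [summary.pathmm()], [kfold_cv()],
#'   [benchmark()]
#' @export
#' @examples
#' sim <- simulate_dataset(fixture_config(seed = 7, n_proteins = 8,
#'                                        n_variants = c(30, 30, 30)))
#' fit <- pathmm(sim$variants, sim$profiles,
#'               scheme = "disease_specific", concept = "metabolic")
#' head(coef(fit))
pathmm <- function(variants, profiles,
                   scheme = c("inherited", "disease_specific"),
                   concept = NULL, background = aa_background(),
                   threshold = 0) {
  if (!inherits(variants, "mutation_dataset")) {
    variants <- mutation_dataset(variants)
  }
  stopifnot(inherits(profiles, "profile_set"))
  if (nrow(variants) == 0L) {
    stop("cannot fit on an empty variant set", call. = FALSE)
  }
  scheme <- weight_scheme(match.arg(scheme), concept)
  model_index <- variant_model_index(profiles, variants)
  counts <- count_mappings(variants, scheme, model_index)
  weights <- weights_from_counts(counts)
  src <- vapply(weights$model_id, function(id) {
    if (!is.null(profiles$domains[[id]])) profiles$domains[[id]]$source
    else "ab_initio"
  }, character(1L))
  weights <- data.frame(model_id = weights$model_id, source = src,
                        weights[c("d_count", "n_count", "Wd", "Wn")],
                        stringsAsFactors = FALSE)
  structure(
    list(weights = weights, counts = counts, scheme = scheme,
         profiles = profiles, data = variants, model_index = model_index,
         background = background, threshold = threshold),
    class = "pathmm"
  )
}

#' @export
print.pathmm <- function(x, ...) {
  cat("Pathogenicity-weight model (profile-HMM conservation + weights)\n")
  cat("  scheme:   ", x$scheme$kind,
      if (!is.null(x$scheme$concept)) paste0(" (", x$scheme$concept, ")"),
      "\n", sep = "")
  cat("  training: ", nrow(x$data), " substitutions on ",
      length(unique(x$data$protein_id)), " proteins\n", sep = "")
  cat("  weights:  ", nrow(x$weights), " models (",
      sum(x$weights$source != "ab_initio"), " domain)\n", sep = "")
  invisible(x)
}

#' Extract fitted pathogenicity weights
#'
#' @param object A fitted [pathmm()] model.
#' @param ... Unused.
#' @return Data.frame `model_id`, `source`, `d_count`, `n_count`, `Wd`,
#'   `Wn`, sorted by model id.
#' @export
coef.pathmm <- function(object, ...) {
  object$weights
}

#' Score substitutions with a fitted model
#'
#' Runs the per-site pipeline of [score_variants()] using the fitted
#' weights. With `newdata = NULL` the training variants are scored with
#' leave-one-out weight adjustment (each variant's own contribution removed
#' from its models' counts), the honest in-sample evaluation; supply
#' `newdata` to score unseen substitutions with the full training weights.
#'
#' @param object A fitted [pathmm()] model.
#' @param newdata Optional `mutation_dataset` of substitutions to score.
#' @param loo Leave-one-out adjustment; defaults to `TRUE` when scoring the
#'   training data and is invalid for genuinely new data.
#' @param threshold Classification cut-off; defaults to the fitted one.
#' @param ... Unused.
#' @return Scored data.frame, see [score_variants()].
#' @export
predict.pathmm <- function(object, newdata = NULL, loo = is.null(newdata),
                           threshold = object$threshold, ...) {
  if (is.null(newdata)) {
    score_variants(object$data, object$profiles, object$counts,
                   object$scheme, loo = loo, background = object$background,
                   threshold = threshold, model_index = object$model_index)
  } else {
    if (!inherits(newdata, "mutation_dataset")) {
      newdata <- mutation_dataset(newdata)
    }
    if (loo) {
      stop("leave-one-out adjustment applies only to the training data",
           call. = FALSE)
    }
    score_variants(newdata, object$profiles, object$counts, object$scheme,
                   loo = FALSE, background = object$background,
                   threshold = threshold)
  }
}

#' Summarize in-sample performance of a fitted model
#'
#' Scores the training data with leave-one-out weights, classifies at the
#' fitted threshold and reports the confusion matrix, the six
#' class-normalized statistics and the AUC. Positives are defined by the
#' fitted scheme (disease vs neutral for `"inherited"`; concept vs
#' everything else for `"disease_specific"`).
#'
#' @param object A fitted [pathmm()] model.
#' @param ... Unused.
#' @return Object of class `summary.pathmm`.
#' @export
summary.pathmm <- function(object, ...) {
  scored <- predict(object)
  positive <- pathogenic_side(object$data, object$scheme)
  cm <- confusion_from_predictions(scored$prediction, positive)
  out <- list(scheme = object$scheme, threshold = object$threshold,
              n = nrow(object$data), n_positive = sum(positive),
              confusion = cm, stats = normalized_stats(cm),
              auc = roc_auc(scored$score, positive)$auc,
              scored = scored, positive = positive)
  class(out) <- "summary.pathmm"
  out
}

#' @export
print.summary.pathmm <- function(x, ...) {
  cat("Leave-one-out performance (", x$scheme$kind,
      if (!is.null(x$scheme$concept)) paste0(", ", x$scheme$concept),
      ", threshold ", format(x$threshold), ")\n", sep = "")
  cat("  n = ", x$n, " (", x$n_positive, " positives)\n", sep = "")
  cm <- x$confusion
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", cm[["tp"]], cm[["fp"]],
              cm[["tn"]], cm[["fn"]]))
  st <- round(c(x$stats, auc = x$auc), 3)
  cat("  ", paste(names(st), st, sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Plot the leave-one-out ROC curve of a fitted model
#'
#' @param x A fitted [pathmm()] model.
#' @param ... Passed to [graphics::plot()].
#' @return The ROC object from [roc_auc()], invisibly.
#' @export
plot.pathmm <- function(x, ...) {
  s <- summary(x)
  roc <- roc_auc(s$scored$score, s$positive)
  graphics::plot(roc$points$fpr, roc$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(roc)
}
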