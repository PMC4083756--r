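#' Conservation-and-weights pathogenicity score
#'
#' The core prediction score combines position-specific conservation with
#' the chosen model's pathogenicity weights:
#' \deqn{\ln \frac{(1 - P_w)\,(W_n + 1)}{(1 - P_m)\,(W_d + 1)}}
#' where \eqn{P_w} and \eqn{P_m} are the match-state emission probabilities
#' of the wild-type and mutant residues and \eqn{W_d}, \eqn{W_n} the
#' model's pathogenic/neutral weights. High wild-type conservation (large
#' \eqn{P_w}) and a mutation-intolerant model (large \eqn{W_d}) both drive
#' the score negative; negative scores indicate damaging substitutions.
#' `1 - P` terms are floored at 1e-9 so the score is always finite.
#'
#' @param Pw,Pm Emission probabilities of the wild-type and mutant residues
#'   at the selected match state, in `[1e-9, 1]`. Vectorized.
#' @param Wd,Wn Pathogenicity weights in `[0, 1]`.
#' @return Numeric score(s); lower = more damaging.
#' @export
#' @examples
#' weighted_score(Pw = 0.9, Pm = 0.1, Wd = 0, Wn = 0)  # ln(1/9)
weighted_score <- function(Pw, Pm, Wd = 0, Wn = 0) {
  stopifnot(all(Pw >= 0 & Pw <= 1), all(Pm >= 0 & Pm <= 1),
            all(Wd >= 0 & Wd <= 1), all(Wn >= 0 & Wn <= 1))
  log(pmax(1 - Pw, 1e-9) * (Wn + 1)) - log(pmax(1 - Pm, 1e-9) * (Wd + 1))
}

#' Weights-only (naive) score
#'
#' Baseline that drops conservation entirely: `ln((Wn+1)/(Wd+1))`. Every
#' variant falling on a model shares this score, so models dominated by
#' pathogenic-side training mutations predict all their variants as
#' damaging and vice versa.
#'
#' @param Wd,Wn Pathogenicity weights in `[0, 1]`. Vectorized.
#' @return Numeric score(s); lower = more damaging.
#' @export
naive_score <- function(Wd, Wn) {
  stopifnot(all(Wd >= 0 & Wd <= 1), all(Wn >= 0 & Wn <= 1))
  log1p(Wn) - log1p(Wd)
}

#' Classify a score against a threshold
#'
#' A variant is called `"damaging"` when its score is strictly below the
#' threshold, `"tolerated"` otherwise; a score exactly at the threshold is
#' tolerated. The default threshold 0 is the natural sign boundary of the
#' log-ratio score.
#'
#' @param score Numeric score(s).
#' @param threshold Cut-off (default 0).
#' @return Character vector of `"damaging"` / `"tolerated"`.
#' @export
classify <- function(score, threshold = 0) {
  stopifnot(all(is.finite(score)))
  ifelse(score < threshold, "damaging", "tolerated")
}

#' Score variants through the full per-site pipeline
#'
#' For each record: collect the models covering its residue, select the most
#' informative one by Kullback-Leibler divergence at the covering match
#' state, read off the wild-type and mutant emission probabilities, fetch
#' the chosen model's pathogenicity weights (leave-one-out adjusted when
#' `loo = TRUE`), and compute the weighted score and classification. A
#' wild-type residue that disagrees with the chosen state's dominant
#' (highest-emission) residue is flagged in the `warning` column, not an
#' error.
#'
#' @param dataset A `mutation_dataset` to score.
#' @param set A [profile_set()].
#' @param counts Mapped counts (from [count_mappings()]) under `scheme`.
#' @param scheme A [weight_scheme()].
#' @param loo Remove each record's own contribution from its models' counts
#'   before scoring (valid only when the record was counted in `counts`).
#' @param background Background composition for informativeness.
#' @param threshold Classification cut-off, see [classify()].
#' @param model_index Optional precomputed [variant_model_index()].
#' @return Data.frame with one row per record: identity columns, chosen
#'   `model_id`/`source`/`state`, `Pw`, `Pm`, `Wd`, `Wn`, `informativeness`
#'   (nats), `score`, `prediction`, `warning`.
#' @export
score_variants <- function(dataset, set, counts, scheme,
                           loo = FALSE, background = aa_background(),
                           threshold = 0, model_index = NULL) {
  stopifnot(inherits(set, "profile_set"), inherits(scheme, "weight_scheme"))
  if (is.null(model_index)) model_index <- variant_model_index(set, dataset)
  n <- nrow(dataset)
  out <- data.frame(
    protein_id = dataset$protein_id, substitution = dataset$substitution,
    label = dataset$label, concepts = dataset$concepts,
    model_id = character(n), source = character(n), state = integer(n),
    Pw = numeric(n), Pm = numeric(n), Wd = numeric(n), Wn = numeric(n),
    informativeness = numeric(n), score = numeric(n),
    prediction = character(n), warning = character(n),
    stringsAsFactors = FALSE
  )
  weight_lookup <- function(cnt, id) {
    row <- cnt[cnt$model_id == id, , drop = FALSE]
    if (nrow(row) == 0L) return(c(Wd = 0, Wn = 0))
    w <- weights_from_counts(row)
    c(Wd = w$Wd[[1L]], Wn = w$Wn[[1L]])
  }
  for (i in seq_len(n)) {
    cands <- candidates_in_set(set, dataset$protein_id[[i]],
                               dataset$position[[i]])
    chosen <- select_informative_model(cands, background)
    em <- chosen$model$emissions[chosen$state, ]
    cnt <- counts
    if (loo) {
      cnt <- loo_adjust(cnt, dataset[i, , drop = FALSE], scheme,
                        model_index[[i]])
    }
    w <- weight_lookup(cnt, chosen$model$model_id)
    sc <- weighted_score(em[[dataset$wildtype[[i]]]],
                         em[[dataset$mutant[[i]]]], w[["Wd"]], w[["Wn"]])
    dominant <- names(em)[which.max(em)]
    out$model_id[[i]] <- chosen$model$model_id
    out$source[[i]] <- chosen$model$source
    out$state[[i]] <- chosen$state
    out$Pw[[i]] <- em[[dataset$wildtype[[i]]]]
    out$Pm[[i]] <- em[[dataset$mutant[[i]]]]
    out$Wd[[i]] <- w[["Wd"]]
    out$Wn[[i]] <- w[["Wn"]]
    out$informativeness[[i]] <- chosen$informativeness
    out$score[[i]] <- sc
    out$warning[[i]] <-
      if (dominant != dataset$wildtype[[i]]) {
        paste0("wild-type ", dataset$wildtype[[i]],
               " is not the dominant residue (", dominant, ") at state ",
               chosen$state, " of ", chosen$model$model_id)
      } else ""
  }
  out$prediction <- classify(out$score, threshold)
  out
}
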