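#' Define a pathogenicity weighting scheme
#'
#' Two schemes are supported. Under `"inherited"`, the pathogenic side of
#' the weights counts every disease-labelled mutation and the neutral side
#' counts neutral polymorphisms. Under `"disease_specific"`, the pathogenic
#' side counts only mutations tagged with the chosen concept, and everything
#' else — mutations causing other diseases as well as neutral polymorphisms —
#' feeds the neutral side.
#'
#' @param kind `"inherited"` or `"disease_specific"`.
#' @param concept Required when `kind = "disease_specific"`; one of
#'   [disease_concepts()].
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(kind = c("inherited", "disease_specific"),
                          concept = NULL) {
  kind <- match.arg(kind)
  if (kind == "disease_specific") {
    if (is.null(concept)) {
      stop("disease_specific scheme requires a concept", call. = FALSE)
    }
    concept <- match.arg(concept, disease_concepts())
  } else if (!is.null(concept)) {
    stop("inherited scheme takes no concept", call. = FALSE)
  }
  structure(list(kind = kind, concept = concept), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> ", x$kind,
      if (!is.null(x$concept)) paste0(" (", x$concept, ")"), "\n", sep = "")
  invisible(x)
}

# Which side of the weights does each record feed under the scheme?
# TRUE = pathogenic side (d), FALSE = neutral side (n).
pathogenic_side <- function(dataset, scheme) {
  if (scheme$kind == "inherited") {
    dataset$label == "disease"
  } else {
    has_concept(dataset, scheme$concept) & dataset$label == "disease"
  }
}

#' Map every variant onto its covering models
#'
#' For each record, the ids of all models covering its position: the
#' protein's ab initio model plus any annotated domain models. Variants
#' whose residue is not covered by an ab initio profile are an error.
#'
#' @param set A [profile_set()].
#' @param dataset A `mutation_dataset`.
#' @return List of character vectors, one per record.
#' @export
variant_model_index <- function(set, dataset) {
  ann <- set$annotations
  idx <- vector("list", nrow(dataset))
  bad <- character(0)
  for (i in seq_len(nrow(dataset))) {
    pid <- dataset$protein_id[[i]]
    pos <- dataset$position[[i]]
    ab <- set$ab_initio[[pid]]
    if (is.null(ab) || is.na(ab$residue_map[as.character(pos)])) {
      bad <- c(bad, paste0(pid, ":", dataset$substitution[[i]]))
      next
    }
    cover <- ann$model_id[ann$protein_id == pid & ann$start <= pos &
                          ann$end >= pos]
    idx[[i]] <- c(ab$model_id, cover)
  }
  if (length(bad) > 0L) {
    stop("variant(s) not resolvable to any model: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...", call. = FALSE)
  }
  idx
}

#' Count training substitutions mapping onto each model
#'
#' Tallies, per model, how many training substitutions fall on its
#' pathogenic side (`d_count`) and neutral side (`n_count`) under the given
#' weighting scheme. A variant increments the counts of every model covering
#' its position (ab initio plus any annotated domains).
#'
#' @param dataset A `mutation_dataset`.
#' @param scheme A [weight_scheme()].
#' @param model_index Per-record covering model ids, from
#'   [variant_model_index()].
#' @return Data.frame with columns `model_id`, `d_count`, `n_count`, one row
#'   per model that received at least one mapped substitution, sorted by
#'   `model_id`.
#' @export
count_mappings <- function(dataset, scheme, model_index) {
  stopifnot(inherits(scheme, "weight_scheme"),
            length(model_index) == nrow(dataset))
  side <- pathogenic_side(dataset, scheme)
  reps <- lengths(model_index)
  ids <- unlist(model_index, use.names = FALSE)
  side_rep <- rep(side, reps)
  d <- tapply(side_rep, ids, sum)
  n <- tapply(!side_rep, ids, sum)
  out <- data.frame(model_id = names(d),
                    d_count = as.integer(d),
                    n_count = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Turn mapped counts into pathogenicity weights
#'
#' The weights are the relative frequencies within each model's mapped
#' substitutions: `Wd = d/(d+n)` and `Wn = n/(d+n)`. A model with no mapped
#' training substitutions gets `Wd = Wn = 0`, so the weighted score degrades
#' gracefully to the pure conservation ratio.
#'
#' @param counts Data.frame with columns `model_id`, `d_count`, `n_count`
#'   (as from [count_mappings()]), or a single-model list with those fields.
#' @return The input with columns `Wd`, `Wn` appended.
#' @export
weights_from_counts <- function(counts) {
  if (!is.data.frame(counts)) counts <- as.data.frame(counts)
  if (any(counts$d_count < 0L) || any(counts$n_count < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- counts$d_count + counts$n_count
  counts$Wd <- ifelse(tot > 0L, counts$d_count / tot, 0)
  counts$Wn <- ifelse(tot > 0L, counts$n_count / tot, 0)
  counts
}

#' Remove one variant's contribution from a model's counts
#'
#' Leave-one-out adjustment: before scoring a training variant, its own unit
#' contribution is removed from whichever count it incremented under the
#' scheme, for each model it maps onto. Attempting to decrement a count that
#' is already zero is an error (the variant cannot have been counted).
#'
#' @param counts Counts data.frame (columns `model_id`, `d_count`,
#'   `n_count`).
#' @param record One-row `mutation_dataset` (the variant being scored).
#' @param scheme A [weight_scheme()].
#' @param model_ids Models the variant maps onto; defaults to every model in
#'   `counts`... typically the covering set from [variant_model_index()].
#' @return Adjusted counts data.frame.
#' @export
loo_adjust <- function(counts, record, scheme, model_ids) {
  stopifnot(inherits(scheme, "weight_scheme"))
  side <- pathogenic_side(record, scheme)
  col <- if (side) "d_count" else "n_count"
  rows <- match(model_ids, counts$model_id)
  if (anyNA(rows)) {
    stop("model(s) not present in counts: ",
         paste(model_ids[is.na(rows)], collapse = ", "), call. = FALSE)
  }
  if (any(counts[[col]][rows] < 1L)) {
    stop("cannot remove variant from model with zero ", col,
         " (variant was not counted)", call. = FALSE)
  }
  counts[[col]][rows] <- counts[[col]][rows] - 1L
  counts
}
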