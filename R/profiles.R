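#' Read a domain annotation table
#'
#' Domain annotations map residue ranges of a protein onto a domain profile.
#' The table is TSV with columns `protein_id`, `model_id`, `source`,
#' `start`, `end`, `model_start` (all positions 1-based, `start`/`end`
#' inclusive on the protein). The residue-to-state mapping is the ungapped
#' offset map: residue `r` in `[start, end]` corresponds to match state
#' `model_start + (r - start)`.
#'
#' @param path File path, connection, or data.frame already in this shape.
#' @return A validated data.frame of annotations.
#' @export
read_domain_annotations <- function(path) {
  ann <- if (is.data.frame(path)) path
         else utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_id", "model_id", "source", "start", "end",
                "model_start")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[required]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann$model_start <- as.integer(ann$model_start)
  bad <- which(is.na(ann$start) | is.na(ann$end) | is.na(ann$model_start) |
               ann$start < 1L | ann$end < ann$start | ann$model_start < 1L)
  if (length(bad) > 0L) {
    stop("invalid annotation row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ann$source %in% setdiff(profile_sources(), "ab_initio"))) {
    stop("annotation source must be one of superfamily, pfam_a, pfam_b",
         call. = FALSE)
  }
  ann
}

#' Bundle profiles and annotations into a profile set
#'
#' A `profile_set` holds one full-length ab initio profile per protein
#' (keyed by protein id) plus a library of domain profiles shared across
#' proteins, tied together by a domain annotation table. It is the profile
#' argument expected by [pathmm()] and the scoring functions.
#'
#' @param ab_initio Named list of [profile_hmm()] objects, one per protein;
#'   names are protein ids. Each must have source `"ab_initio"` and a
#'   residue map covering the protein.
#' @param domains Named list of domain [profile_hmm()] objects keyed by
#'   model id (may be empty).
#' @param annotations Annotation table as from [read_domain_annotations()],
#'   or `NULL` for none.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(ab_initio, domains = list(), annotations = NULL) {
  if (length(ab_initio) == 0L || is.null(names(ab_initio))) {
    stop("ab_initio must be a non-empty named list of profiles",
         call. = FALSE)
  }
  for (id in names(ab_initio)) {
    p <- ab_initio[[id]]
    if (!inherits(p, "profile_hmm") || p$source != "ab_initio") {
      stop("ab_initio[['", id, "']] must be a profile_hmm with source ",
           "'ab_initio'", call. = FALSE)
    }
  }
  if (length(domains) > 0L) {
    if (is.null(names(domains)) ||
        !all(vapply(domains, inherits, logical(1L), "profile_hmm"))) {
      stop("domains must be a named list of profile_hmm objects",
           call. = FALSE)
    }
  }
  if (is.null(annotations)) {
    annotations <- data.frame(protein_id = character(), model_id = character(),
                              source = character(), start = integer(),
                              end = integer(), model_start = integer(),
                              stringsAsFactors = FALSE)
  } else {
    annotations <- read_domain_annotations(annotations)
    unknown <- setdiff(annotations$model_id, names(domains))
    if (length(unknown) > 0L) {
      stop("annotations reference unknown domain model(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    over <- annotations$model_start +
      (annotations$end - annotations$start)
    lens <- vapply(domains[annotations$model_id], `[[`, integer(1L), "length")
    if (any(over > lens)) {
      stop("annotation row(s) ", paste(which(over > lens), collapse = ", "),
           " extend beyond their domain model", call. = FALSE)
    }
  }
  structure(list(ab_initio = ab_initio, domains = domains,
                 annotations = annotations),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set> ", length(x$ab_initio), " proteins, ",
      length(x$domains), " domain models, ", nrow(x$annotations),
      " annotations\n", sep = "")
  invisible(x)
}

#' Candidate models covering a residue
#'
#' Every residue covered by the protein's ab initio model always yields the
#' ab initio candidate; in addition, one candidate is produced for each
#' domain model annotated over the residue. A candidate pairs a model with
#' the match state its residue map assigns to the queried position.
#'
#' @param ab_initio The protein's full-length [profile_hmm()].
#' @param domain_models List of domain [profile_hmm()] objects whose
#'   `residue_map` is expressed in the protein's residue coordinates (as
#'   built by [candidates_in_set()] from an annotation table).
#' @param residue 1-based residue position.
#' @return List of candidates, each a list with elements `model` and
#'   `state`; the ab initio candidate comes first.
#' @export
candidates_for_residue <- function(ab_initio, domain_models = list(),
                                   residue) {
  key <- as.character(residue)
  state <- ab_initio$residue_map[key]
  if (is.na(state)) {
    stop("residue ", residue, " is not covered by the ab initio model '",
         ab_initio$model_id, "'", call. = FALSE)
  }
  out <- list(list(model = ab_initio, state = unname(state)))
  for (dm in domain_models) {
    s <- dm$residue_map[key]
    if (!is.na(s)) out[[length(out) + 1L]] <- list(model = dm,
                                                   state = unname(s))
  }
  out
}

#' Candidate models for a residue of a protein in a profile set
#'
#' Convenience wrapper around [candidates_for_residue()]: looks up the
#' protein's ab initio profile and instantiates residue maps for every
#' domain model annotated over the residue.
#'
#' @param set A [profile_set()].
#' @param protein_id Protein identifier.
#' @param residue 1-based residue position.
#' @return List of candidates as in [candidates_for_residue()].
#' @export
candidates_in_set <- function(set, protein_id, residue) {
  ab <- set$ab_initio[[protein_id]]
  if (is.null(ab)) {
    stop("no ab initio profile for protein '", protein_id, "'",
         call. = FALSE)
  }
  ann <- set$annotations
  ann <- ann[ann$protein_id == protein_id & ann$start <= residue &
             ann$end >= residue, , drop = FALSE]
  dms <- vector("list", nrow(ann))
  if (nrow(ann) > 0L) {
    for (j in seq_len(nrow(ann))) {
      dm <- set$domains[[ann$model_id[[j]]]]
      pos <- ann$start[[j]]:ann$end[[j]]
      dm$residue_map <- stats::setNames(
        ann$model_start[[j]] + (pos - ann$start[[j]]), pos)
      dms[[j]] <- dm
    }
  }
  candidates_for_residue(ab, dms, residue)
}

#' Select the most informative covering model
#'
#' Given candidate models covering one residue, returns the candidate whose
#' covering match-state emission distribution has the largest
#' Kullback-Leibler divergence from the background — i.e. the model that is
#' most informative about this particular position. Exact ties are broken by
#' annotation source priority `pfam_a > superfamily > pfam_b > ab_initio`,
#' then by model id, so selection is deterministic and independent of
#' candidate order.
#'
#' @param candidates Non-empty list of candidates from
#'   [candidates_for_residue()].
#' @param background Background composition, see [aa_background()].
#' @return The winning candidate, with its divergence attached as element
#'   `informativeness` (nats).
#' @export
select_informative_model <- function(candidates,
                                     background = aa_background()) {
  if (length(candidates) == 0L) {
    stop("no candidate models to select from", call. = FALSE)
  }
  kl <- vapply(candidates, function(cand) {
    kl_divergence(cand$model$emissions[cand$state, ], background)
  }, numeric(1L))
  best <- max(kl)
  tied <- which(kl >= best - 1e-12)
  if (length(tied) > 1L) {
    pri <- vapply(candidates[tied], function(cand) {
      source_priority(cand$model$source)
    }, numeric(1L))
    ids <- vapply(candidates[tied], function(cand) cand$model$model_id,
                  character(1L))
    tied <- tied[order(pri, ids)]
  }
  winner <- candidates[[tied[[1L]]]]
  winner$informativeness <- kl[[tied[[1L]]]]
  winner
}
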