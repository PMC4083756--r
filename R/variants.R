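#' The 17 root disease concepts
#'
#' Closed vocabulary of root disease concepts used to tag inherited
#' disease-causing mutations; arbitrary strings are rejected so that labels
#' cannot silently fragment.
#'
#' @return Character vector of the 17 concept names.
#' @export
disease_concepts <- function() {
  c("blood", "blood_coagulation", "developmental", "digestive",
    "ear_nose_throat", "endocrine", "eye", "genitourinary", "heart",
    "immune", "metabolic", "musculoskeletal", "nervous_system",
    "psychiatric", "reproductive", "respiratory", "skin")
}

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
          Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
          Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
          Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Parse an amino-acid substitution token
#'
#' Accepts one-letter tokens like `"R175H"`, optionally prefixed `"p."`, and
#' HGVS three-letter tokens like `"p.Arg175His"` (normalized to the
#' one-letter form). Input is case-insensitive; output is canonical upper
#' case.
#'
#' @param token Substitution string.
#' @return List with elements `wildtype`, `position`, `mutant`.
#' @export
#' @examples
#' parse_substitution("R175H")
#' parse_substitution("p.Arg175His")
parse_substitution <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  raw <- sub("^[pP]\\.", "", trimws(token))
  m1 <- regmatches(raw, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", raw))[[1L]]
  m3 <- regmatches(raw,
                   regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", raw))[[1L]]
  if (length(m1) == 4L) {
    wt <- toupper(m1[[2L]]); mut <- toupper(m1[[4L]]); pos <- m1[[3L]]
  } else if (length(m3) == 4L) {
    three <- function(x) {
      x <- paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, 3L)))
      aa <- .AA3[[x]] %||% NA_character_
      if (is.na(aa)) stop("unknown three-letter amino-acid code '", x, "'",
                          call. = FALSE)
      aa
    }
    wt <- three(m3[[2L]]); mut <- three(m3[[4L]]); pos <- m3[[3L]]
  } else {
    stop("malformed substitution token '", token, "'", call. = FALSE)
  }
  if (!(wt %in% amino_acids()) || !(mut %in% amino_acids())) {
    stop("non-canonical amino acid in '", token, "'", call. = FALSE)
  }
  if (wt == mut) {
    stop("synonymous substitution '", token, "' (wild-type equals mutant)",
         call. = FALSE)
  }
  position <- as.integer(pos)
  if (is.na(position) || position < 1L) {
    stop("invalid residue position in '", token, "'", call. = FALSE)
  }
  list(wildtype = wt, position = position, mutant = mut)
}

#' Construct a validated mutation dataset
#'
#' A mutation dataset is a data.frame of amino-acid substitutions with a
#' pathogenicity label and disease-concept tags, satisfying:
#' no duplicate (protein, substitution) pairs; `label` in
#' `{"disease", "neutral"}`; neutral records carry no concepts; disease
#' records carry at least one concept from [disease_concepts()].
#'
#' @param df Data.frame with columns `protein_id`, `substitution` (e.g.
#'   `"R175H"`), `label`, `concepts` (semicolon-separated, empty for
#'   neutral records).
#' @return The validated data.frame with parsed columns `wildtype`,
#'   `position`, `mutant` added, of class `mutation_dataset`.
#' @export
mutation_dataset <- function(df) {
  required <- c("protein_id", "substitution", "label", "concepts")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$concepts[is.na(df$concepts)] <- ""
  n <- nrow(df)
  problems <- character(0)
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    parsed[[i]] <- tryCatch(parse_substitution(df$substitution[[i]]),
                            error = function(e) conditionMessage(e))
    if (is.character(parsed[[i]])) {
      problems <- c(problems, paste0("row ", i, ": ", parsed[[i]]))
    }
  }
  bad_label <- which(!(df$label %in% c("disease", "neutral")))
  if (length(bad_label) > 0L) {
    problems <- c(problems, paste0("row ", bad_label,
                                   ": label must be 'disease' or 'neutral'"))
  }
  concept_list <- strsplit(df$concepts, ";", fixed = TRUE)
  concept_list <- lapply(concept_list, function(x) x[nzchar(x)])
  for (i in seq_len(n)) {
    cs <- concept_list[[i]]
    unknown <- setdiff(cs, disease_concepts())
    if (length(unknown) > 0L) {
      problems <- c(problems, paste0("row ", i, ": unknown concept(s) ",
                                     paste(unknown, collapse = ", ")))
    }
    if (identical(df$label[[i]], "neutral") && length(cs) > 0L) {
      problems <- c(problems, paste0("row ", i,
                                     ": neutral record carries concepts"))
    }
    if (identical(df$label[[i]], "disease") && length(cs) == 0L) {
      problems <- c(problems, paste0("row ", i,
                                     ": disease record has no concept"))
    }
  }
  key <- paste(df$protein_id,
               toupper(sub("^[pP]\\.", "", df$substitution)))
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    problems <- c(problems, paste0("row ", dup,
                                   ": duplicate (protein, substitution)"))
  }
  if (length(problems) > 0L) {
    stop("invalid variant table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  ok <- parsed
  df$wildtype <- vapply(ok, `[[`, character(1L), "wildtype")
  df$position <- vapply(ok, `[[`, integer(1L), "position")
  df$mutant <- vapply(ok, `[[`, character(1L), "mutant")
  df$substitution <- paste0(df$wildtype, df$position, df$mutant)
  df$concepts <- vapply(concept_list, paste, character(1L), collapse = ";")
  rownames(df) <- NULL
  class(df) <- c("mutation_dataset", "data.frame")
  df
}

#' Read a variant table
#'
#' Reads a TSV with columns `protein_id`, `substitution`, `label`,
#' `concepts` (semicolon-separated disease concepts, empty for neutral
#' records) and validates it via [mutation_dataset()]; validation failures
#' report all offending row numbers.
#'
#' @param path File path or connection.
#' @return A `mutation_dataset`.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  mutation_dataset(df)
}

#' Write a variant table
#'
#' @param dataset A `mutation_dataset`.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(dataset, path) {
  out <- as.data.frame(dataset)[c("protein_id", "substitution", "label",
                                  "concepts")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split concept tags into a list column on demand.
concept_tags <- function(dataset) {
  lapply(strsplit(dataset$concepts, ";", fixed = TRUE),
         function(x) x[nzchar(x)])
}

# Does each record carry the concept?
has_concept <- function(dataset, concept) {
  vapply(concept_tags(dataset), function(cs) concept %in% cs, logical(1L))
}

#' Split a dataset into concept positives and everything else
#'
#' Under disease-specific evaluation the positives for a concept are the
#' disease records tagged with it; every other record — mutations causing
#' other diseases as well as neutral polymorphisms — is treated as a
#' negative. The two parts partition the dataset.
#'
#' @param dataset A `mutation_dataset`.
#' @param concept One of [disease_concepts()].
#' @return List with elements `positives` and `negatives`, both
#'   `mutation_dataset` subsets.
#' @export
concept_split <- function(dataset, concept) {
  concept <- match.arg(concept, disease_concepts())
  pos <- has_concept(dataset, concept) & dataset$label == "disease"
  list(positives = dataset[pos, , drop = FALSE],
       negatives = dataset[!pos, , drop = FALSE])
}

#' Check recorded wild-type residues against protein sequences
#'
#' Optional consistency check: for each record whose protein appears in
#' `sequences`, verify that the sequence at the recorded position equals the
#' recorded wild-type residue.
#'
#' @param dataset A `mutation_dataset`.
#' @param sequences Named character vector of protein sequences.
#' @param action `"warn"` (default) or `"error"` on mismatch.
#' @return Logical vector, `TRUE` where consistent (or unknown protein /
#'   out-of-range position), invisibly.
#' @export
check_wildtype <- function(dataset, sequences, action = c("warn", "error")) {
  action <- match.arg(action)
  ok <- rep(TRUE, nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    pid <- dataset$protein_id[[i]]
    seq <- if (pid %in% names(sequences)) sequences[[pid]] else
      NA_character_
    if (is.na(seq) || nchar(seq) < dataset$position[[i]]) next
    ok[[i]] <- substr(seq, dataset$position[[i]], dataset$position[[i]]) ==
      dataset$wildtype[[i]]
  }
  if (any(!ok)) {
    msg <- paste0(sum(!ok), " record(s) disagree with the protein sequence",
                  " at the stated position (rows ",
                  paste(utils::head(which(!ok), 10L), collapse = ", "), ")")
    if (action == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
  }
  invisible(ok)
}
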