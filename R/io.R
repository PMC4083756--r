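#' Load a directory of HMMER3 profiles into a profile set
#'
#' Reads every `*.hmm` file under `dir` and assembles a [profile_set()]:
#' profiles whose model id appears in the annotation table become domain
#' models (with the source recorded there); all others are taken as
#' full-length ab initio profiles keyed by their model id (= protein id).
#' This is the on-disk layout written by [write_fixture()].
#'
#' @param dir Directory containing `*.hmm` files.
#' @param annotations Annotation table (path or data.frame), or `NULL`.
#' @return A [profile_set()].
#' @export
load_profile_dir <- function(dir, annotations = NULL) {
  files <- list.files(dir, pattern = "\\.hmm$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .hmm files found under ", dir, call. = FALSE)
  }
  ann <- if (!is.null(annotations)) read_domain_annotations(annotations)
  ab_initio <- list()
  domains <- list()
  for (f in files) {
    hmm <- read_hmmer3_profile(f)
    if (!is.null(ann) && hmm$model_id %in% ann$model_id) {
      src <- unique(ann$source[ann$model_id == hmm$model_id])
      if (length(src) != 1L) {
        stop("conflicting sources annotated for model ", hmm$model_id,
             call. = FALSE)
      }
      hmm$source <- src
      domains[[hmm$model_id]] <- hmm
    } else {
      ab_initio[[hmm$model_id]] <- hmm
    }
  }
  profile_set(ab_initio, domains, ann)
}

#' Write a fitted weights table
#'
#' TSV with columns `model_id`, `source`, `d_count`, `n_count`, `Wd`, `Wn`
#' in ascending model-id order, so reruns on identical inputs are
#' byte-identical.
#'
#' @param fit A fitted [pathmm()] model (or its [coef.pathmm()] table).
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_weights_table <- function(fit, path) {
  w <- if (inherits(fit, "pathmm")) coef(fit) else fit
  w <- w[order(w$model_id), , drop = FALSE]
  utils::write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scored-variant table
#'
#' Scored variants sorted ascending by score (most damaging first), floats
#' at 6 significant digits, fixed column order — the ranking output of the
#' pipeline.
#'
#' @param scored Output of [predict.pathmm()] / [score_variants()].
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scored, path) {
  cols <- c("protein_id", "substitution", "model_id", "source", "state",
            "Pw", "Pm", "Wd", "Wn", "informativeness", "score",
            "prediction", "warning")
  out <- scored[order(scored$score), cols, drop = FALSE]
  for (col in c("Pw", "Pm", "Wd", "Wn", "informativeness", "score")) {
    out[[col]] <- signif(out[[col]], 6L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
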