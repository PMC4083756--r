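#' Published reference benchmark table
#'
#' Confusion matrices and class-normalized statistics published for four
#' prediction algorithms (SIFT, PolyPhen-2, generic inherited-disease
#' FATHMM, and the disease-specific weighting scheme) on four disease
#' concepts, shipped with the package as a plain-text fixture. The `auc`
#' column is the published value only: it cannot be recomputed from the
#' counts because the underlying per-variant scores were never published.
#'
#' @return Data.frame with columns `concept`, `algorithm`, `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `precision`, `specificity`, `sensitivity`,
#'   `npv`, `mcc`, `auc`.
#' @export
reference_benchmarks <- function() {
  path <- system.file("extdata", "reference_benchmarks.tsv",
                      package = "pathmm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the reference statistics from their confusion matrices
#'
#' For every row of [reference_benchmarks()], recomputes the six
#' class-normalized statistics from the published raw counts with
#' [normalized_stats()] and compares them, after half-up rounding to 2
#' decimal places, with the published values.
#'
#' @return Data.frame with one row per (concept, algorithm, statistic):
#'   `published`, `recomputed` (rounded), and logical `agree`.
#' @export
#' @examples
#' chk <- check_reference_benchmarks()
#' all(chk$agree)
check_reference_benchmarks <- function() {
  ref <- reference_benchmarks()
  stat_names <- c("accuracy", "precision", "specificity", "sensitivity",
                  "npv", "mcc")
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    cm <- confusion_matrix(ref$tp[[i]], ref$fp[[i]], ref$tn[[i]],
                           ref$fn[[i]])
    rec <- round_half_up(normalized_stats(cm), 2L)
    data.frame(concept = ref$concept[[i]], algorithm = ref$algorithm[[i]],
               statistic = stat_names,
               published = unlist(ref[i, stat_names], use.names = FALSE),
               recomputed = unname(rec[stat_names]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$agree <- out$published == out$recomputed
  out
}

#' Round half away from zero
#'
#' Display rounding used in benchmark tables (0.005 rounds to 0.01), as
#' opposed to R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}
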