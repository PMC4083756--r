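#' Construct a profile hidden Markov model
#'
#' A lightweight container for the part of a profile HMM this package needs:
#' per-match-state amino-acid emission probabilities and a mapping from
#' protein residue positions onto match states. Insert states and transition
#' probabilities play no role in per-site conservation scoring and are not
#' retained.
#'
#' @param model_id Model identifier (the `NAME` field of a HMMER3 file).
#' @param source One of `"ab_initio"`, `"superfamily"`, `"pfam_a"`,
#'   `"pfam_b"`: the annotation source the model came from. Used for
#'   deterministic tie-breaking during model selection.
#' @param emissions Numeric matrix, one row per match state, 20 columns named
#'   by [amino_acids()]; each row a probability distribution (sum 1 within
#'   1e-6). Entries are floored at 1e-9 and the row renormalized, so
#'   log-ratios are always finite.
#' @param residue_map Named integer vector mapping 1-based protein residue
#'   positions (names) to 1-based match-state indices (values). Must be
#'   injective and map into `[1, nrow(emissions)]`. Defaults to the identity
#'   map, appropriate for a full-length ab initio model.
#' @return An object of class `profile_hmm` with elements `model_id`,
#'   `source`, `length`, `emissions`, `residue_map`.
#' @seealso [read_hmmer3_profile()], [candidates_for_residue()]
#' @export
profile_hmm <- function(model_id, source, emissions, residue_map = NULL) {
  source <- match.arg(source, profile_sources())
  if (!is.matrix(emissions) || ncol(emissions) != 20L) {
    stop("emissions must be a matrix with 20 columns", call. = FALSE)
  }
  if (is.null(colnames(emissions))) {
    colnames(emissions) <- amino_acids()
  } else {
    if (!setequal(colnames(emissions), amino_acids())) {
      stop("emission columns must be the 20 canonical amino acids",
           call. = FALSE)
    }
    emissions <- emissions[, amino_acids(), drop = FALSE]
  }
  if (any(emissions < 0)) stop("negative emission probability", call. = FALSE)
  sums <- rowSums(emissions)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("emission row(s) ", paste(which(abs(sums - 1) > 1e-6), collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  emissions <- pmax(emissions, 1e-9)
  emissions <- emissions / rowSums(emissions)
  L <- nrow(emissions)
  if (L < 1L) stop("model must have at least one match state", call. = FALSE)
  if (is.null(residue_map)) {
    residue_map <- stats::setNames(seq_len(L), seq_len(L))
  }
  residue_map <- check_residue_map(residue_map, L)
  structure(
    list(model_id = as.character(model_id), source = source, length = L,
         emissions = emissions, residue_map = residue_map),
    class = "profile_hmm"
  )
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$model_id, " (", x$source, "), ",
      x$length, " match states, covers ", length(x$residue_map),
      " residues\n", sep = "")
  invisible(x)
}

#' Recognised profile annotation sources
#'
#' In decreasing tie-break priority during model selection:
#' `pfam_a`, `superfamily`, `pfam_b`, `ab_initio`.
#' @return Character vector of the four source labels.
#' @export
profile_sources <- function() {
  c("ab_initio", "superfamily", "pfam_a", "pfam_b")
}

# Tie-break rank: lower = preferred.
source_priority <- function(source) {
  match(source, c("pfam_a", "superfamily", "pfam_b", "ab_initio"))
}

check_residue_map <- function(map, length) {
  if (is.null(names(map)) || anyNA(suppressWarnings(as.integer(names(map))))) {
    stop("residue_map must be named by 1-based residue positions",
         call. = FALSE)
  }
  map <- stats::setNames(as.integer(map), names(map))
  if (anyNA(map) || any(map < 1L) || any(map > length)) {
    stop("residue_map values must lie in [1, ", length, "]", call. = FALSE)
  }
  if (anyDuplicated(map)) {
    stop("residue_map must be injective", call. = FALSE)
  }
  if (any(as.integer(names(map)) < 1L)) {
    stop("residue positions must be >= 1", call. = FALSE)
  }
  map
}

#' Read a HMMER3 ASCII profile
#'
#' Parses one profile in the `HMMER3/f` ASCII dialect (as written by
#' `hmmbuild`). Match-state emission fields are stored as negative natural-log
#' probabilities; they are converted with `exp(-x)`, floored at 1e-9 and each
#' row renormalized. Insert-state emissions, transition lines and the
#' `COMPO` line are parsed past and ignored. The special field `*`
#' (probability zero) is accepted.
#'
#' @param path Path to a file, a connection, or a character vector of lines.
#' @param source Annotation source label for the resulting model (the file
#'   format does not record one); see [profile_sources()].
#' @param model_id Override for the model identifier; default is the file's
#'   `NAME` field.
#' @return A [profile_hmm()] with an identity residue map.
#' @export
#' @examples
#' hmm <- read_hmmer3_profile(
#'   system.file("extdata", "toy.hmm", package = "pathmm"))
#' hmm$length
read_hmmer3_profile <- function(path, source = "ab_initio", model_id = NULL) {
  lines <- if (is.character(path) && length(path) > 1L) path
           else readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "HMMER3/f")) {
    stop("malformed header at line 1: expected 'HMMER3/f'", call. = FALSE)
  }
  name <- NULL
  leng <- NULL
  i <- 2L
  n <- length(lines)
  while (i <= n) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(tok) == 0L) { i <- i + 1L; next }
    key <- tok[[1L]]
    if (key == "NAME") name <- tok[[2L]]
    if (key == "LENG") {
      leng <- suppressWarnings(as.integer(tok[[2L]]))
      if (is.na(leng) || leng < 1L) {
        stop("invalid LENG at line ", i, call. = FALSE)
      }
    }
    if (key == "ALPH" && tolower(tok[[2L]]) != "amino") {
      stop("unsupported alphabet '", tok[[2L]], "' at line ", i,
           " (only 'amino' profiles are supported)", call. = FALSE)
    }
    if (key == "HMM") break
    i <- i + 1L
  }
  if (i > n) stop("malformed profile: no 'HMM' section found", call. = FALSE)
  if (is.null(leng)) stop("malformed profile: missing LENG header",
                          call. = FALSE)
  if (is.null(name)) name <- "unnamed"

  # Body: skip the two header lines, COMPO and node-0 insert/transition
  # lines; collect one match-emission line per node, in order.
  emissions <- matrix(NA_real_, nrow = leng, ncol = 20L,
                      dimnames = list(NULL, amino_acids()))
  expected <- 1L
  i <- i + 1L
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "//") break
    tok <- strsplit(line, "\\s+")[[1L]]
    if (length(tok) > 0L && tok[[1L]] == as.character(expected)) {
      if (length(tok) < 21L) {
        stop("truncated match-emission line at line ", i, call. = FALSE)
      }
      vals <- tok[2:21]
      num <- suppressWarnings(as.numeric(vals))
      num[vals == "*"] <- Inf
      if (anyNA(num)) {
        stop("non-numeric emission field at line ", i, call. = FALSE)
      }
      emissions[expected, ] <- exp(-num)
      expected <- expected + 1L
    }
    i <- i + 1L
  }
  if (expected - 1L != leng) {
    stop("LENG header says ", leng, " match states but ", expected - 1L,
         " emission line(s) found", call. = FALSE)
  }
  sums <- rowSums(emissions)
  if (any(abs(sums - 1) > 1e-2)) {
    stop("emission row(s) ", paste(which(abs(sums - 1) > 1e-2), collapse = ", "),
         " are far from a probability distribution", call. = FALSE)
  }
  emissions <- emissions / sums
  profile_hmm(model_id = model_id %||% name, source = source,
              emissions = emissions)
}

#' Write a profile as HMMER3 ASCII
#'
#' Serializes a [profile_hmm()] in the `HMMER3/f` dialect. Match emissions
#' are written as negative natural-log probabilities at full precision so
#' that [read_hmmer3_profile()] round-trips them to within 1e-9; insert
#' emissions are written as the uniform distribution and transitions as
#' uninformative placeholders (both are ignored on read).
#'
#' @param hmm A [profile_hmm()].
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_hmmer3_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  fmt <- function(p) {
    v <- -log(p)
    vapply(v, function(x) if (is.infinite(x)) "*" else sprintf("%.12e", x),
           character(1L))
  }
  ins <- paste(rep(sprintf("%.5f", log(20)), 20L), collapse = "  ")
  trans <- paste(rep("0.00000", 7L), collapse = "  ")
  out <- c(
    "HMMER3/f [pathmm]",
    paste0("NAME  ", hmm$model_id),
    paste0("LENG  ", hmm$length),
    "ALPH  amino",
    paste0("HMM  ", paste(amino_acids(), collapse = "  ")),
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d"
  )
  body <- character(3L * hmm$length)
  for (k in seq_len(hmm$length)) {
    body[3L * k - 2L] <- paste0(format(k, width = 7L), "   ",
                                paste(fmt(hmm$emissions[k, ]), collapse = "  "))
    body[3L * k - 1L] <- paste0("          ", ins)
    body[3L * k] <- paste0("          ", trans)
  }
  writeLines(c(out, body, "//"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
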