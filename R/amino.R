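#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the one-letter code, in HMMER's
#' alphabetical order (`A C D E ... Y`). All emission vectors and background
#' compositions in this package are indexed by this alphabet; degenerate
#' symbols (B, Z, X, U, O) are rejected everywhere.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Swiss-Prot/TrEMBL average amino-acid composition (UniProtKB release
# statistics, percent frequencies), used as the default background for
# Kullback-Leibler informativeness.
.SWISSPROT_COMPOSITION <- c(
  A = 8.25, C = 1.37, D = 5.46, E = 6.74, F = 3.86,
  G = 7.08, H = 2.27, I = 5.93, K = 5.84, L = 9.66,
  M = 2.42, N = 4.06, P = 4.71, Q = 3.93, R = 5.53,
  S = 6.56, T = 5.34, V = 6.87, W = 1.09, Y = 2.92
)

#' Background amino-acid composition
#'
#' Returns a background distribution over the 20 canonical amino acids, used
#' as the reference for Kullback-Leibler informativeness of profile match
#' states. The default is the Swiss-Prot/TrEMBL average composition;
#' `"uniform"` gives 0.05 for every residue.
#'
#' @param type `"swissprot"` (default) or `"uniform"`.
#' @return Named numeric vector of length 20 summing to 1, strictly positive.
#' @export
#' @examples
#' sum(aa_background())
#' aa_background("uniform")[["W"]]
aa_background <- function(type = c("swissprot", "uniform")) {
  type <- match.arg(type)
  q <- switch(type,
    swissprot = .SWISSPROT_COMPOSITION / sum(.SWISSPROT_COMPOSITION),
    uniform = stats::setNames(rep(1 / 20, 20), amino_acids())
  )
  q[amino_acids()]
}

# Validate a probability vector over the canonical alphabet.
# strict_positive is required for backgrounds (finite KL).
check_aa_distribution <- function(p, strict_positive = FALSE,
                                  what = "distribution") {
  if (!is.numeric(p) || length(p) != 20L) {
    stop(what, " must be a numeric vector of length 20", call. = FALSE)
  }
  if (!is.null(names(p))) {
    if (!setequal(names(p), amino_acids())) {
      stop(what, " names must be the 20 canonical amino acids", call. = FALSE)
    }
    p <- p[amino_acids()]
  } else {
    names(p) <- amino_acids()
  }
  if (any(p < 0)) stop(what, " has negative entries", call. = FALSE)
  if (strict_positive && any(p <= 0)) {
    stop(what, " must be strictly positive", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  p
}

#' Kullback-Leibler divergence of an emission distribution from a background
#'
#' Measures the informativeness (conservation) of a match-state emission
#' distribution relative to a background amino-acid composition, in nats:
#' \deqn{D(p \| q) = \sum_i p_i \ln(p_i / q_i)} with \eqn{0 \ln(0/q) = 0}.
#' A fully conserved position against a uniform background scores
#' \eqn{\ln 20 \approx 3.0} nats; a position emitting the background scores 0.
#'
#' @param dist Named numeric vector over [amino_acids()], non-negative,
#'   summing to 1.
#' @param background Strictly positive background composition, as from
#'   [aa_background()].
#' @return Non-negative divergence in nats.
#' @export
#' @examples
#' kl_divergence(aa_background("uniform"), aa_background("uniform"))
kl_divergence <- function(dist, background = aa_background()) {
  p <- check_aa_distribution(dist, what = "dist")
  q <- check_aa_distribution(background, strict_positive = TRUE,
                             what = "background")
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}
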