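# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and direct formula evaluation.

# KL divergence by direct summation
kl_brute <- function(p, q) {
  tot <- 0
  for (i in seq_along(p)) {
    if (p[[i]] > 0) tot <- tot + p[[i]] * log(p[[i]] / q[[i]])
  }
  tot
}

# AUC as the pairwise Mann-Whitney concordance count (lower score =
# positive), ties counted one half
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct evaluation of the weighted score formula
eq1_direct <- function(Pw, Pm, Wd, Wn) {
  log((max(1 - Pw, 1e-9) * (Wn + 1)) / (max(1 - Pm, 1e-9) * (Wd + 1)))
}

# Random emission distribution over the 20 amino acids
random_dist <- function(alpha = 1) {
  x <- rgamma(20, shape = alpha)
  x <- x / sum(x)
  stats::setNames(x, amino_acids())
}

# A profile whose every state has the given emission rows (list of vectors)
profile_from_rows <- function(id, source, rows) {
  em <- do.call(rbind, rows)
  colnames(em) <- amino_acids()
  profile_hmm(id, source, em)
}

# Point-mass-ish distribution on one residue (floored so it is valid)
point_dist <- function(aa, p = 1) {
  x <- stats::setNames(rep((1 - p) / 19, 20), amino_acids())
  x[[aa]] <- p
  x
}

uniform_dist <- function() {
  stats::setNames(rep(0.05, 20), amino_acids())
}

# Tiny two-protein fixture with one shared pfam_a domain used by the
# weighting and scoring tests. Protein A: length 12, domain "dom1" over
# residues 4..9 (model states 1..6); protein B: length 10, same domain over
# residues 2..7. The domain's state emissions are peaked on fixed residues
# so Pw/Pm are predictable.
tiny_set <- function() {
  dom_rows <- lapply(c("A", "C", "D", "E", "F", "G"),
                     function(aa) point_dist(aa, 0.9))
  dom <- profile_from_rows("dom1", "pfam_a", dom_rows)
  abA <- profile_from_rows("protA", "ab_initio",
                           replicate(12, uniform_dist(), simplify = FALSE))
  abB <- profile_from_rows("protB", "ab_initio",
                           replicate(10, uniform_dist(), simplify = FALSE))
  ann <- data.frame(
    protein_id = c("protA", "protB"), model_id = "dom1", source = "pfam_a",
    start = c(4L, 2L), end = c(9L, 7L), model_start = 1L,
    stringsAsFactors = FALSE)
  profile_set(list(protA = abA, protB = abB), list(dom1 = dom), ann)
}

# Variant table builder
variants_df <- function(...) {
  rows <- list(...)
  mutation_dataset(do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], substitution = r[[2]], label = r[[3]],
               concepts = r[[4]], stringsAsFactors = FALSE)
  })))
}

# Random small training fixture over tiny_set() for weighting properties
random_tiny_dataset <- function(n = 12) {
  prot <- sample(c("protA", "protB"), n, replace = TRUE)
  pos <- ifelse(prot == "protA", sample(1:12, n, replace = TRUE),
                sample(1:10, n, replace = TRUE))
  aa <- amino_acids()
  rows <- lapply(seq_len(n), function(i) {
    wtmut <- sample(aa, 2)
    lab <- sample(c("disease", "neutral"), 1)
    con <- if (lab == "disease") {
      paste(sample(c("metabolic", "skin", "endocrine"),
                   sample(1:2, 1)), collapse = ";")
    } else ""
    data.frame(protein_id = prot[[i]],
               substitution = paste0(wtmut[[1]], pos[[i]], wtmut[[2]]),
               label = lab, concepts = con, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[!duplicated(paste(df$protein_id, df$substitution)), ]
  mutation_dataset(df)
}
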