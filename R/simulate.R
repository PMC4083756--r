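#' Configuration for the synthetic benchmark generator
#'
#' Describes a fully seeded synthetic study: profile HMMs for a set of
#' proteins, shared domain families tied to disease concepts, and a
#' concept-labelled mutation dataset with a planted disease-specific signal.
#' Identical configurations produce bit-identical output.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_proteins Number of proteins.
#' @param protein_length Integer range `c(min, max)` of protein lengths.
#' @param n_domains Integer range of domain instances per protein (the first
#'   instance is always drawn from the protein's concept family).
#' @param domain_length Integer range of domain family lengths.
#' @param sharpness Conservation sharpness of ab initio backbone emissions:
#'   states are drawn from a symmetric Dirichlet with per-residue
#'   concentration `20 / sharpness`, so larger values give more conserved
#'   (peakier) positions — `sharpness = 20` is the flat Dirichlet and the
#'   point-mass limit is approached as sharpness grows.
#' @param domain_sharpness Sharpness of domain family emissions; domains are
#'   sampled more conserved than backbones, which is what makes
#'   informativeness-based model selection prefer them.
#' @param concepts Disease concepts in play (subset of
#'   [disease_concepts()]); proteins are assigned to concepts round-robin as
#'   that concept's susceptible set.
#' @param focal_concept The concept whose mutations form the
#'   "disease-specific" class; defaults to `concepts[1]`.
#' @param families_per_concept Shared domain families per concept.
#' @param n_background_families Concept-free domain families.
#' @param n_variants Counts `c(concept, other, neutral)`: focal-concept
#'   mutations, other-disease mutations (split across the remaining
#'   concepts) and neutral polymorphisms.
#' @param weight_bias Probability that a disease mutation is planted inside
#'   a susceptible domain of its concept; with probability `1 - weight_bias`
#'   its location is unconstrained. `0` disables the planted weight signal
#'   entirely (the balanced-weights condition).
#' @param conservation_bias When `TRUE` (default), disease mutations prefer
#'   conserved (high-divergence) positions and neutral polymorphisms prefer
#'   diverse positions; when `FALSE` all classes are placed uniformly, so
#'   only the mutant-residue choice separates them.
#' @param background Background composition (generation and scoring).
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_proteins = 600L,
                           protein_length = c(110L, 150L),
                           n_domains = c(2L, 3L),
                           domain_length = c(25L, 40L),
                           sharpness = 40, domain_sharpness = 100,
                           concepts = c("metabolic", "musculoskeletal",
                                        "skin"),
                           focal_concept = concepts[[1L]],
                           families_per_concept = 2L,
                           n_background_families = 4L,
                           n_variants = c(concept = 200L, other = 200L,
                                          neutral = 200L),
                           weight_bias = 0.9,
                           conservation_bias = TRUE,
                           background = aa_background("uniform")) {
  concepts <- vapply(concepts, match.arg, character(1L), disease_concepts())
  focal_concept <- match.arg(focal_concept, concepts)
  if (length(concepts) < 2L) {
    stop("need at least two concepts (one focal, one or more 'other')",
         call. = FALSE)
  }
  if (length(n_variants) != 3L) {
    stop("n_variants must give three counts: concept, other, neutral",
         call. = FALSE)
  }
  names(n_variants) <- c("concept", "other", "neutral")
  stopifnot(weight_bias >= 0, weight_bias <= 1, sharpness > 0,
            domain_sharpness > 0, n_proteins >= length(concepts))
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length),
         n_domains = as.integer(n_domains),
         domain_length = as.integer(domain_length),
         sharpness = sharpness, domain_sharpness = domain_sharpness,
         concepts = unname(concepts), focal_concept = focal_concept,
         families_per_concept = as.integer(families_per_concept),
         n_background_families = as.integer(n_background_families),
         n_variants = stats::setNames(as.integer(n_variants),
                                      names(n_variants)),
         weight_bias = weight_bias,
         conservation_bias = isTRUE(conservation_bias),
         background = background),
    class = "fixture_config"
  )
}

sample_range <- function(range) {
  if (range[[1L]] == range[[2L]]) range[[1L]]
  else sample(range[[1L]]:range[[2L]], 1L)
}

# Emission matrix of n states from a symmetric Dirichlet with per-residue
# concentration 20/sharpness.
sample_emissions <- function(n, sharpness) {
  alpha <- rep(20 / sharpness, 20L)
  em <- t(vapply(seq_len(n), function(i) rdirichlet1(alpha), numeric(20L)))
  colnames(em) <- amino_acids()
  em <- pmax(em, 1e-9)
  em / rowSums(em)
}

#' Generate synthetic profiles, domain annotations and sequences
#'
#' Builds one full-length ab initio profile per protein plus a library of
#' shared domain families: each disease concept owns a few families, and
#' every protein carries at least one instance of its assigned concept's
#' family (its "susceptible" domain) plus optional background-family
#' instances, packed without overlap. Backbone emissions over annotated
#' regions are resampled around the family emissions, so domain and backbone
#' agree on the consensus residue while the (sharper) family wins
#' informativeness-based selection. Consensus sequences are the per-position
#' highest-emission residues.
#'
#' @param config A [fixture_config()].
#' @return List: `profiles` (a [profile_set()]), `sequences` (named
#'   character), `protein_truth` (protein to concept), `family_truth`
#'   (domain family to concept; background families have concept `NA`).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  restore <- local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  # shared domain families
  fam_ids <- character(0)
  fam_concept <- character(0)
  fam_source <- character(0)
  for (con in config$concepts) {
    for (j in seq_len(config$families_per_concept)) {
      fam_ids <- c(fam_ids, sprintf("fam_%s_%d", con, j))
      fam_concept <- c(fam_concept, con)
      fam_source <- c(fam_source, "pfam_a")
    }
  }
  bg_sources <- rep(c("superfamily", "pfam_b"),
                    length.out = config$n_background_families)
  for (j in seq_len(config$n_background_families)) {
    fam_ids <- c(fam_ids, sprintf("fam_bg_%d", j))
    fam_concept <- c(fam_concept, NA_character_)
    fam_source <- c(fam_source, bg_sources[[j]])
  }
  domains <- list()
  for (j in seq_along(fam_ids)) {
    flen <- sample_range(config$domain_length)
    domains[[fam_ids[[j]]]] <- profile_hmm(
      fam_ids[[j]], fam_source[[j]],
      sample_emissions(flen, config$domain_sharpness))
  }

  protein_ids <- sprintf("P%03d", seq_len(config$n_proteins))
  protein_concept <- config$concepts[
    (seq_len(config$n_proteins) - 1L) %% length(config$concepts) + 1L]
  ab_initio <- list()
  ann_rows <- list()
  sequences <- character(0)
  for (i in seq_len(config$n_proteins)) {
    pid <- protein_ids[[i]]
    L <- sample_range(config$protein_length)
    em <- sample_emissions(L, config$sharpness)
    nd <- sample_range(config$n_domains)
    # first instance: the protein's concept family; rest: background
    own <- fam_ids[!is.na(fam_concept) & fam_concept == protein_concept[[i]]]
    fams <- character(0)
    own_fam <- character(0)
    if (nd >= 1L) {
      own_fam <- sample(own, 1L)
      fams <- own_fam
      if (nd > 1L && config$n_background_families > 0L) {
        bg <- fam_ids[is.na(fam_concept)]
        fams <- c(fams, sample(bg, min(nd - 1L, length(bg))))
      }
    }
    # non-overlapping placement: distribute the free slack at random into
    # the gaps before/between/after the domains, in random order; optional
    # (background) instances beyond the required first one are dropped when
    # they cannot fit
    if (length(fams) > 0L) {
      fams <- sample(fams)
      flens <- vapply(domains[fams], `[[`, integer(1L), "length")
      while (sum(flens) > L && length(fams) > 1L) {
        drop <- which(!(fams %in% own_fam))[1L]
        if (is.na(drop)) break
        keep <- setdiff(seq_along(fams), drop)
        fams <- fams[keep]
        flens <- flens[keep]
      }
      slack <- L - sum(flens)
      if (slack < 0L) {
        stop("infeasible domain packing for protein ", pid,
             " (length ", L, ", domains total ", sum(flens), ")",
             call. = FALSE)
      }
      cuts <- sort(sample.int(slack + 1L, length(fams), replace = TRUE)) - 1L
      gaps <- diff(c(0L, cuts))
      start <- 0L
      for (j in seq_along(fams)) {
        start <- start + gaps[[j]] + 1L
        fid <- fams[[j]]
        flen <- flens[[j]]
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          protein_id = pid, model_id = fid,
          source = domains[[fid]]$source,
          start = start, end = start + flen - 1L, model_start = 1L,
          stringsAsFactors = FALSE)
        # backbone emissions over the instance: correlated with the family
        # but flattened toward the background, as a model trained on fewer
        # homologs would be — the sharper family then wins informativeness
        # selection at covered positions
        fam_em <- domains[[fid]]$emissions
        q_bg <- config$background
        for (s in seq_len(flen)) {
          em[start + s - 1L, ] <-
            rdirichlet1((0.5 * fam_em[s, ] + 0.5 * q_bg) * 30 + 0.05)
        }
        start <- start + flen - 1L
      }
    }
    em <- pmax(em, 1e-9)
    em <- em / rowSums(em)
    ab_initio[[pid]] <- profile_hmm(pid, "ab_initio", em)
    sequences[[pid]] <- paste(amino_acids()[max.col(em)], collapse = "")
  }
  annotations <- if (length(ann_rows) > 0L) do.call(rbind, ann_rows)
                 else NULL
  list(profiles = profile_set(ab_initio, domains, annotations),
       sequences = sequences,
       protein_truth = data.frame(protein_id = protein_ids,
                                  concept = protein_concept,
                                  stringsAsFactors = FALSE),
       family_truth = data.frame(model_id = fam_ids, concept = fam_concept,
                                 stringsAsFactors = FALSE))
}

#' Generate a concept-labelled mutation dataset over synthetic profiles
#'
#' Plants the disease-specific signal: each focal-concept mutation falls,
#' with probability `weight_bias`, inside a susceptible domain instance of
#' the focal concept (any protein carrying one); other-disease mutations do
#' the same within their own concepts' disjoint susceptible domains; neutral
#' polymorphisms are placed uniformly across proteins. With
#' `conservation_bias` on, disease mutations prefer conserved positions
#' (sampling weight proportional to squared informativeness) and neutral
#' ones prefer diverse positions; disease mutants are drawn from the ten
#' least probable residues at the site while neutral mutants are drawn in
#' proportion to the emission probabilities, so neutral changes look like
#' plausible polymorphisms. Class counts match the configuration exactly and
#' the result always satisfies the `mutation_dataset` invariants.
#'
#' @param config A [fixture_config()].
#' @param sim Output of [simulate_profiles()] for the same config.
#' @return A `mutation_dataset`.
#' @export
simulate_mutations <- function(config, sim) {
  stopifnot(inherits(config, "fixture_config"))
  restore <- local_seed(config$seed + 1L)
  on.exit(restore(), add = TRUE)
  set <- sim$profiles
  ann <- set$annotations

  # per-protein, per-position view of the model the scorer would select:
  # the most informative covering model's emissions and divergence.
  # Vectorized: backbone KL per row, then overlay family states where the
  # (sharper) family wins.
  q <- check_aa_distribution(config$background, strict_positive = TRUE,
                             what = "background")
  row_kl <- function(em) {
    rowSums(em * (log(em) - matrix(log(q), nrow(em), 20L, byrow = TRUE)))
  }
  fam_kl <- lapply(set$domains, function(d) row_kl(d$emissions))
  slot_tab <- list()
  for (pid in names(set$ab_initio)) {
    em <- set$ab_initio[[pid]]$emissions
    kl <- row_kl(em)
    rows <- ann[ann$protein_id == pid, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      span <- rows$start[[j]]:rows$end[[j]]
      states <- rows$model_start[[j]] + (span - rows$start[[j]])
      fk <- fam_kl[[rows$model_id[[j]]]][states]
      win <- fk >= kl[span]
      kl[span][win] <- fk[win]
      em[span[win], ] <- set$domains[[rows$model_id[[j]]]]$emissions[
        states[win], , drop = FALSE]
    }
    slot_tab[[pid]] <- list(kl = kl, em = em)
  }
  all_slots <- do.call(rbind, lapply(names(slot_tab), function(pid) {
    data.frame(protein_id = pid,
               position = seq_along(slot_tab[[pid]]$kl),
               kl = slot_tab[[pid]]$kl, stringsAsFactors = FALSE)
  }))

  # susceptible slots per concept: positions inside that concept's family
  # instances
  fam_of <- stats::setNames(sim$family_truth$concept,
                            sim$family_truth$model_id)
  concept_slots <- lapply(config$concepts, function(con) {
    rows <- ann[!is.na(fam_of[ann$model_id]) &
                fam_of[ann$model_id] == con, , drop = FALSE]
    if (nrow(rows) == 0L) return(all_slots[0, ])
    do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
      pos <- rows$start[[j]]:rows$end[[j]]
      data.frame(protein_id = rows$protein_id[[j]], position = pos,
                 kl = slot_tab[[rows$protein_id[[j]]]]$kl[pos],
                 stringsAsFactors = FALSE)
    }))
  })
  names(concept_slots) <- config$concepts

  seen <- new.env(parent = emptyenv())
  draw_one <- function(pool, kl_weight, mutant_rule, wt_rule) {
    for (try in seq_len(1000L)) {
      w <- kl_weight(pool$kl)
      j <- sample.int(nrow(pool), 1L, prob = w)
      pid <- pool$protein_id[[j]]
      pos <- pool$position[[j]]
      em <- slot_tab[[pid]]$em[pos, ]
      wt <- wt_rule(em)
      mut <- mutant_rule(em, wt)
      key <- paste0(pid, "|", wt, pos, mut)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        return(data.frame(protein_id = pid,
                          substitution = paste0(wt, pos, mut),
                          stringsAsFactors = FALSE))
      }
    }
    stop("requested variant count exceeds available positions",
         call. = FALSE)
  }
  # disease mutations strike the consensus (dominant) residue; neutral
  # polymorphisms arise wherever the wild-type itself is weakly constrained
  consensus_wt <- function(em) names(em)[which.max(em)]
  sampled_wt <- function(em) sample(names(em), 1L, prob = em)
  rare_mutant <- function(em, wt) {
    low <- names(sort(em))[1:10]
    low <- setdiff(low, wt)
    sample(low, 1L)
  }
  plausible_mutant <- function(em, wt) {
    others <- setdiff(names(em), wt)
    sample(others, 1L, prob = em[others])
  }
  w_conserved <- if (config$conservation_bias) function(kl) kl^2 + 1e-6
                 else function(kl) rep(1, length(kl))
  w_diverse <- if (config$conservation_bias) function(kl) exp(-2 * kl)
               else function(kl) rep(1, length(kl))

  draw_disease <- function(con) {
    targeted <- config$weight_bias > 0 &&
      stats::runif(1L) < config$weight_bias &&
      nrow(concept_slots[[con]]) > 0L
    pool <- if (targeted) concept_slots[[con]] else all_slots
    row <- draw_one(pool, w_conserved, rare_mutant, consensus_wt)
    row$label <- "disease"
    row$concepts <- con
    row
  }
  rows <- list()
  for (i in seq_len(config$n_variants[["concept"]])) {
    rows[[length(rows) + 1L]] <- draw_disease(config$focal_concept)
  }
  others <- setdiff(config$concepts, config$focal_concept)
  other_assign <- rep(others, length.out = config$n_variants[["other"]])
  for (con in other_assign) {
    rows[[length(rows) + 1L]] <- draw_disease(con)
  }
  for (i in seq_len(config$n_variants[["neutral"]])) {
    row <- draw_one(all_slots, w_diverse, plausible_mutant, sampled_wt)
    row$label <- "neutral"
    row$concepts <- ""
    rows[[length(rows) + 1L]] <- row
  }
  mutation_dataset(do.call(rbind, rows))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_profiles()] then
#' [simulate_mutations()].
#'
#' @param config A [fixture_config()].
#' @return List: `config`, `profiles`, `variants`, `sequences`,
#'   `protein_truth`, `family_truth`.
#' @export
#' @examples
#' sim <- simulate_dataset(fixture_config(seed = 42, n_proteins = 6,
#'                                        n_variants = c(20, 20, 20)))
#' table(sim$variants$label)
simulate_dataset <- function(config = fixture_config()) {
  sim <- simulate_profiles(config)
  variants <- simulate_mutations(config, sim)
  c(list(config = config, variants = variants), sim)
}

#' Write a synthetic study to disk
#'
#' Emits `profiles/<id>.hmm` (HMMER3 ASCII; ab initio profiles named by
#' protein, domain families by model id), `annotations.tsv`,
#' `proteins.fasta`, `variants.tsv` and `truth.tsv` (the planted
#' protein/family-to-concept assignment) under `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  set <- sim$profiles
  for (pid in names(set$ab_initio)) {
    write_hmmer3_profile(set$ab_initio[[pid]],
                         file.path(dir, "profiles", paste0(pid, ".hmm")))
  }
  for (mid in names(set$domains)) {
    write_hmmer3_profile(set$domains[[mid]],
                         file.path(dir, "profiles", paste0(mid, ".hmm")))
  }
  utils::write.table(set$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fasta <- unlist(lapply(names(sim$sequences), function(pid) {
    c(paste0(">", pid), sim$sequences[[pid]])
  }))
  writeLines(fasta, file.path(dir, "proteins.fasta"))
  write_variant_table(sim$variants, file.path(dir, "variants.tsv"))
  truth <- rbind(
    data.frame(kind = "protein", id = sim$protein_truth$protein_id,
               concept = sim$protein_truth$concept,
               stringsAsFactors = FALSE),
    data.frame(kind = "family", id = sim$family_truth$model_id,
               concept = sim$family_truth$concept, stringsAsFactors = FALSE))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
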